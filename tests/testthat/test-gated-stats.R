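# Mixed models, Satterthwaite df, the family gate, t-tests and power.

test_that("treatment_families validates the partition", {
  expect_s3_class(treatment_families(), "treatment_families")
  expect_error(treatment_families(list(a = c("control", "X"))), "control")
  expect_error(treatment_families(list(a = "X", b = "X")), "disjoint")
  expect_error(treatment_families(list("X")), "named")
})

test_that("null construction yields near-zero coefficients", {
  des <- explant_design(n_litters = 3, slices_per_litter = 2,
                        cells_per_slice = 8,
                        multipliers = lapply(default_multipliers(),
                                             function(v) v * 0 + 1),
                        sigma_litter = 0, sigma_slice = 0,
                        sigma_cell = 0.01)   # tiny jitter keeps lmer happy
  ex <- make_explant_experiment(des, seed = 10)
  fit <- fit_migration_model(annotate_migration(ex$records), "lateral")
  eff <- treatment_effects(fit)
  expect_lt(max(abs(eff$estimate_log)), 0.02)
})

test_that("Satterthwaite Wald matches the paired t-test oracle exactly", {
  withr::with_seed(42, {
    n <- 8
    dat <- data.frame(
      litter = rep(sprintf("L%d", 1:n), each = 2),
      slice = sprintf("S%d", 1:(2 * n)),
      treatment = rep(c("control", "TFB-TBOA"), n),
      lateral = exp(rep(rnorm(n, 5, 0.3), each = 2) +
                      rnorm(2 * n, 0, 0.2) + rep(c(0, 0.5), n)))
  })
  fit <- fit_migration_model(dat, "lateral")
  eff <- treatment_effects(fit)
  tt <- t.test(log(dat$lateral[dat$treatment == "TFB-TBOA"]),
               log(dat$lateral[dat$treatment == "control"]), paired = TRUE)
  expect_equal(eff$t, unname(tt$statistic), tolerance = 1e-6)
  expect_equal(eff$df, unname(tt$parameter), tolerance = 1e-3)
  expect_equal(eff$p, tt$p.value, tolerance = 1e-6)
  # family F on the single contrast is t^2 with the same denominator df
  g <- family_gate(fit, treatment_families(list(transporter = "TFB-TBOA")))
  expect_equal(g$families$F, unname(tt$statistic)^2, tolerance = 1e-6)
  expect_equal(g$families$df2, unname(tt$parameter), tolerance = 1e-3)
})

test_that("planted lateral and radial multipliers are recovered", {
  des <- explant_design(n_litters = 10, slices_per_litter = 2,
                        cells_per_slice = 15)
  ex <- make_explant_experiment(des, seed = 77)
  ann <- annotate_migration(ex$records)

  lat <- treatment_effects(fit_migration_model(ann, "lateral"))
  est_tbo <- lat[lat$treatment == "TFB-TBOA", ]
  expect_lt(abs(est_tbo$estimate_log - log(1.62)), 4 * est_tbo$se)

  rad <- treatment_effects(fit_migration_model(ann, "radial"))
  est_nbqx <- rad[rad$treatment == "NBQX", ]
  expect_lt(abs(est_nbqx$estimate_log - log(0.5)), 4 * est_nbqx$se)
  # untouched treatment stays near 1
  est_cnqx <- rad[rad$treatment == "CNQX", ]
  expect_lt(abs(est_cnqx$estimate_log), 4 * est_cnqx$se)
})

test_that("variance components are recovered at moderate litter counts", {
  des <- explant_design(n_litters = 25, slices_per_litter = 2,
                        cells_per_slice = 15)
  ex <- make_explant_experiment(des, seed = 13)
  fit <- fit_migration_model(annotate_migration(ex$records), "lateral")
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  sd_by <- setNames(vc$sdcor, vc$grp)
  expect_lt(abs(sd_by[["litter"]] - des$sigma_litter), 0.07)
  expect_lt(abs(sd_by[["litter:slice"]] - des$sigma_slice), 0.04)
  expect_lt(abs(sd_by[["Residual"]] - des$sigma_cell), 0.02)
})

test_that("family gate opens only where an effect is planted", {
  des <- explant_design(n_litters = 8, slices_per_litter = 2,
                        cells_per_slice = 12)
  ex <- make_explant_experiment(des, seed = 19)
  fit <- fit_migration_model(annotate_migration(ex$records), "lateral")
  g <- family_gate(fit)
  fam <- g$families
  expect_true(fam$gate_open[fam$family == "transporter"])
  # Wald rows exist only for open gates
  expect_true(all(g$wald$family %in% fam$family[fam$gate_open]))
  closed <- fam$family[!fam$gate_open]
  expect_false(any(g$wald$family %in% closed))
  expect_true(all(g$wald$ratio > 0))
  expect_true(all(fam$p >= 0 & fam$p <= 1))

  # alpha = 1 opens every gate: the gated Wald set is a subset of ungated
  g_all <- family_gate(fit, alpha = 0.999999)
  expect_true(all(g$wald$treatment %in% g_all$wald$treatment))
  expect_gte(nrow(g_all$wald), nrow(g$wald))

  # absent family member: warning, family skipped when fully absent
  fams <- treatment_families(list(ghost = "nonexistent",
                                  transporter = "TFB-TBOA"))
  expect_warning(g2 <- family_gate(fit, fams), "absent")
  expect_identical(g2$families$family, "transporter")
})

test_that("LRT fallback route gives comparable gate decisions", {
  des <- explant_design(n_litters = 8, slices_per_litter = 2,
                        cells_per_slice = 12)
  ex <- make_explant_experiment(des, seed = 19)
  fit <- fit_migration_model(annotate_migration(ex$records), "lateral")
  g_sw <- family_gate(fit)
  g_lrt <- family_gate(fit, df_method = "lrt")
  expect_identical(g_lrt$families$method,
                   rep("lrt", nrow(g_lrt$families)))
  expect_identical(g_sw$families$gate_open, g_lrt$families$gate_open)
})

test_that("count model recovers planted folds", {
  des <- explant_design(n_litters = 12, slices_per_litter = 3,
                        cells_per_slice = 1)
  ex <- make_explant_experiment(des, seed = 23)
  fo <- treatment_effects(fit_count_model(ex$counts, "n_outside"))
  est10 <- fo[fo$treatment == "TFB-TBOA", ]
  expect_lt(abs(est10$estimate_log - log(10)), 4 * est10$se)
  fc <- treatment_effects(fit_count_model(ex$counts, "n_cortex"))
  est6 <- fc[fc$treatment == "TFB-TBOA", ]
  expect_lt(abs(est6$estimate_log - log(6)), 4 * est6$se)
  # null treatment: fold ~ 1
  est1 <- fo[fo$treatment == "D-AP5", ]
  expect_lt(abs(est1$estimate_log), 4 * est1$se)
})

test_that("two_group_ttest matches hand and permutation oracles", {
  same <- two_group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  tb <- two_group_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tb$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(tb$p_value, 0.02131164, tolerance = 1e-6)

  withr::with_seed(55, { x <- rnorm(8); y <- rnorm(8, 0.5) })
  p_param <- two_group_ttest(x, y)$p_value
  p_perm <- oracle_perm_t_p(x, y)
  expect_lt(abs(p_param - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 4000) +
              0.01)

  expect_error(two_group_ttest(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_error(two_group_ttest(1, c(1, 2)), "n >= 2")
  expect_error(two_group_ttest(c(1, 2), c(1, 2, 3), paired = TRUE),
               "equal length")
})

test_that("paired-t power: identities, inversion, monotonicity, MC", {
  expect_equal(paired_t_power(5, 0), 0.05, tolerance = 1e-10)

  d80 <- paired_t_detectable_effect(5)
  expect_equal(paired_t_power(5, d80), 0.8, tolerance = 1e-6)

  # monotone: power increases with n and d; detectable effect shrinks in n
  expect_true(all(diff(sapply(c(3, 5, 10, 30),
                              paired_t_power, d = 1)) > 0))
  expect_true(all(diff(sapply(c(0.5, 1, 1.5, 2),
                              function(d) paired_t_power(5, d))) > 0))
  expect_true(all(diff(sapply(c(3, 5, 10, 50),
                              paired_t_detectable_effect)) < 0))

  # large-n normal approximation
  expect_equal(paired_t_detectable_effect(1000),
               (qnorm(0.975) + qnorm(0.8)) / sqrt(1000), tolerance = 0.01)

  # Monte-Carlo oracle at the design point n = 5, d = 1.7
  mc <- oracle_mc_paired_power(5, 1.7)
  expect_lt(abs(paired_t_power(5, 1.7) - mc),
            3 * sqrt(mc * (1 - mc) / 4000))

  expect_error(paired_t_detectable_effect(5, alpha = 0.05, power = 0.04),
               "power")
})
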