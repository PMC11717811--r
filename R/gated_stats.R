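#' Inhibitor families for the gated testing procedure
#'
#' The gatekeeping structure compares control first to each *family* of
#' inhibitors; only when a family-level F-test rejects are its individual
#' members compared to control. Default families: NMDA-receptor antagonists
#' (D-AP5, MK801), AMPA/KA-receptor antagonists (CNQX, NBQX), their pairwise
#' combinations (MK801+NBQX, D-AP5+CNQX), and the glutamate-transporter
#' blocker (TFB-TBOA). Families must partition the non-control treatments;
#' control belongs to no family.
#'
#' @param families named list: family name -> treatment labels.
#' @return Validated family list (class `treatment_families`).
#' @export
treatment_families <- function(families = list(
  NMDAR = c("D-AP5", "MK801"),
  `AMPAR/KAR` = c("CNQX", "NBQX"),
  combinations = c("MK801+NBQX", "D-AP5+CNQX"),
  transporter = "TFB-TBOA")) {
  if (!is.list(families) || is.null(names(families)) ||
      any(names(families) == ""))
    stop("`families` must be a named list", call. = FALSE)
  all_members <- unlist(families, use.names = FALSE)
  if ("control" %in% all_members)
    stop("control may not belong to any family", call. = FALSE)
  if (anyDuplicated(all_members))
    stop("families must be disjoint", call. = FALSE)
  structure(families, class = "treatment_families")
}

#' Fit the log-scale migration mixed model
#'
#' Fits `log(outcome) ~ treatment + (1 | litter / slice)`: treatment
#' indicators against control as fixed effects and random intercepts for
#' litter and slice-within-litter, matching a design with repeated measures
#' on slices from the same animal/litter. If the fit is singular the slice
#' random effect is dropped, then the litter effect (plain linear model);
#' each fallback is recorded in the returned object.
#'
#' @param records per-cell migration table with `litter`, `slice`,
#'   `treatment` and outcome columns (run [annotate_migration()] first, or
#'   supply `x1,y1,x2,y2` and it is called automatically).
#' @param outcome `"net"`, `"lateral"`, `"radial"` or `"cc_to_ctx"`. For
#'   `cc_to_ctx`, cells on the white-matter side (non-positive distance) are
#'   excluded with a warning, since only migration within the cortex counts.
#' @return A `migration_fit` object: the fitted model, the analysis data,
#'   the outcome name and any fallbacks applied.
#' @export
fit_migration_model <- function(records,
                                outcome = c("net", "lateral", "radial",
                                            "cc_to_ctx")) {
  outcome <- match.arg(outcome)
  if (!(outcome %in% names(records)) &&
      all(c("x1", "y1", "x2", "y2") %in% names(records)))
    records <- annotate_migration(records)
  need <- c("litter", "slice", "treatment", outcome)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- records[[outcome]]
  if (outcome == "cc_to_ctx") {
    drop_n <- sum(!is.finite(y) | y <= 0)
    if (drop_n > 0) {
      warning(sprintf(
        "dropping %d cell(s) not on the cortex side for cc_to_ctx", drop_n),
        call. = FALSE)
      records <- records[is.finite(y) & y > 0, ]
      y <- records[[outcome]]
    }
  }
  if (any(!is.finite(y) | y <= 0))
    stop("outcome values must be positive (log scale)", call. = FALSE)
  if (length(unique(records$litter)) < 2L)
    stop("need >= 2 litters", call. = FALSE)
  if (!("control" %in% records$treatment))
    stop("records must contain control cells", call. = FALSE)
  dat <- data.frame(
    y = log(y),
    treatment = stats::relevel(factor(records$treatment), ref = "control"),
    litter = factor(records$litter),
    slice = factor(records$slice))
  fit_gated_lmm_(dat, y ~ treatment + (1 | litter) + (1 | litter:slice),
                 outcome = outcome, response_scale = "log")
}

#' Fit the per-slice migrated-count model
#'
#' Counts summarized per slice are modelled as
#' `log(count + 1) ~ treatment + (1 | litter)` (litter the sole random
#' effect). Back-transformed coefficients estimate treated:control fold
#' changes.
#'
#' @param counts per-slice table with `litter`, `treatment` and the count
#'   column.
#' @param response count column: `"n_outside"` (default) or `"n_cortex"`.
#' @return A `migration_fit` object.
#' @export
fit_count_model <- function(counts, response = "n_outside") {
  need <- c("litter", "treatment", response)
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  y <- counts[[response]]
  if (any(!is.finite(y) | y < 0))
    stop("counts must be finite and >= 0", call. = FALSE)
  zero_groups <- tapply(y, counts$treatment, function(v) all(v == 0))
  if (any(zero_groups))
    warning("all-zero counts for: ",
            paste(names(zero_groups)[zero_groups], collapse = ", "),
            "; estimate at boundary", call. = FALSE)
  if (length(unique(counts$litter)) < 2L)
    stop("need >= 2 litters", call. = FALSE)
  if (!("control" %in% counts$treatment))
    stop("counts must contain control slices", call. = FALSE)
  dat <- data.frame(
    y = log(y + 1),
    treatment = stats::relevel(factor(counts$treatment), ref = "control"),
    litter = factor(counts$litter))
  fit_gated_lmm_(dat, y ~ treatment + (1 | litter),
                 outcome = response, response_scale = "log1p")
}

# shared fitting core: drop slice-within-litter first, then litter, when a
# fit is singular or inadmissible (e.g. one observation per slice)
fit_gated_lmm_ <- function(dat, formula, outcome, response_scale) {
  fallback <- character()
  notes <- character()
  try_lmer <- function(f) withCallingHandlers(
    tryCatch(suppressMessages(lme4::lmer(f, data = dat, REML = TRUE)),
             error = function(e) NULL),
    warning = function(w) {
      # convergence chatter is recorded on the fit, not re-raised
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  model <- try_lmer(formula)
  has_slice <- "slice" %in% all.vars(formula)
  if (has_slice && (is.null(model) || lme4::isSingular(model))) {
    fallback <- c(fallback,
                  if (is.null(model))
                    "slice random effect inadmissible: dropped"
                  else "singular fit: dropped slice random effect")
    model <- try_lmer(y ~ treatment + (1 | litter))
  }
  if (is.null(model) || lme4::isSingular(model)) {
    fallback <- c(fallback, "singular fit: dropped litter random effect")
    model <- stats::lm(y ~ treatment, data = dat)
  }
  structure(list(model = model, data = dat, outcome = outcome,
                 response_scale = response_scale, fallback = fallback,
                 notes = notes),
            class = "migration_fit")
}

#' @export
print.migration_fit <- function(x, ...) {
  cat(sprintf("<migration_fit> outcome: %s (%s scale), %d obs\n",
              x$outcome, x$response_scale, nrow(x$data)))
  if (length(x$fallback)) cat(" fallback:", x$fallback, sep = "\n  ")
  print(treatment_effects(x))
  invisible(x)
}

#' Per-treatment Wald effects with back-transformed ratios
#'
#' Treatment-versus-control coefficients on the log scale with standard
#' errors, Satterthwaite degrees of freedom, two-sided p-values, and
#' back-transformed ratios (`exp(coef)`, i.e. treated/control fold change)
#' with confidence intervals.
#'
#' @param fit a `migration_fit`.
#' @param conf_level confidence level (default 0.95).
#' @return data.frame with one row per non-control treatment.
#' @export
treatment_effects <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "migration_fit"))
  model <- fit$model
  if (inherits(model, "merMod")) {
    beta <- lme4::fixef(model)
    sw <- sw_prepare_(model)
    if (isTRUE(sw$ok)) {
      V <- sw$V0
      dfs <- vapply(seq_along(beta), function(j) {
        cc <- numeric(length(beta)); cc[j] <- 1
        sw_df_contrast_(sw, cc)
      }, 0)
    } else {
      V <- as.matrix(vcov(model))
      dfs <- rep(Inf, length(beta))  # normal approximation fallback
    }
  } else {
    beta <- coef(model)
    V <- vcov(model)
    dfs <- rep(stats::df.residual(model), length(beta))
  }
  keep <- grep("^treatment", names(beta))
  se <- sqrt(diag(V))[keep]
  est <- beta[keep]
  df <- dfs[keep]
  tval <- est / se
  pval <- 2 * pt(-abs(tval), df)
  crit <- qt(1 - (1 - conf_level) / 2, df)
  data.frame(treatment = sub("^treatment", "", names(beta)[keep]),
             estimate_log = unname(est), se = unname(se), df = unname(df),
             t = unname(tval), p = unname(pval),
             ratio = unname(exp(est)),
             ratio_lo = unname(exp(est - crit * se)),
             ratio_hi = unname(exp(est + crit * se)),
             row.names = NULL)
}

#' Family-gated F-then-Wald testing
#'
#' For each inhibitor family, tests the joint null that all member
#' coefficients are zero with an F-test (Satterthwaite-type denominator
#' degrees of freedom; likelihood-ratio chi-square fallback when the
#' approximation fails). A family's gate opens when its F-test p-value is
#' below `alpha`; per-member Wald comparisons against control are reported
#' only behind open gates. No multiplicity correction is applied beyond the
#' gate itself.
#'
#' @param fit a `migration_fit` from [fit_migration_model()] or
#'   [fit_count_model()].
#' @param families a [treatment_families()] list; members absent from the
#'   data cause the family to be skipped with a warning.
#' @param alpha gate significance level (default 0.05).
#' @param df_method `"satterthwaite"` (default) or `"lrt"` to force the
#'   likelihood-ratio route.
#' @return A `gated_result`: `$families` (per-family F, df pair, p,
#'   gate_open, method) and `$wald` (per-inhibitor estimates, only for open
#'   gates). `$effects` carries the full ungated effect table for
#'   diagnostics; the gated inference is `$wald`.
#' @export
family_gate <- function(fit, families = treatment_families(),
                        alpha = 0.05,
                        df_method = c("satterthwaite", "lrt")) {
  stopifnot(inherits(fit, "migration_fit"))
  df_method <- match.arg(df_method)
  check_number_(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (!inherits(families, "treatment_families"))
    families <- treatment_families(families)
  model <- fit$model
  is_mer <- inherits(model, "merMod")
  beta <- if (is_mer) lme4::fixef(model) else coef(model)
  coef_names <- names(beta)
  present <- levels(fit$data$treatment)

  sw <- NULL
  if (is_mer && df_method == "satterthwaite") {
    sw <- sw_prepare_(model)
    if (!isTRUE(sw$ok)) sw <- NULL
  }
  all_effects <- treatment_effects(fit)

  fam_rows <- list()
  wald_rows <- list()
  for (fam in names(families)) {
    members <- intersect(families[[fam]], present)
    missing <- setdiff(families[[fam]], present)
    if (length(missing))
      warning(sprintf("family '%s': member(s) %s absent from data%s", fam,
                      paste(missing, collapse = ", "),
                      if (length(members)) "" else "; family skipped"),
              call. = FALSE)
    if (length(members) == 0L) next
    idx <- match(paste0("treatment", members), coef_names)
    L <- matrix(0, length(idx), length(beta))
    L[cbind(seq_along(idx), idx)] <- 1
    if (!is_mer) {
      # plain linear model: classical F with residual df
      V <- vcov(model)
      Q <- L %*% V %*% t(L)
      Lb <- drop(L %*% beta)
      Fstat <- drop(crossprod(Lb, solve(Q, Lb))) / nrow(L)
      res <- list(F = Fstat, df1 = nrow(L),
                  df2 = stats::df.residual(model))
      method <- "classical"
    } else if (!is.null(sw)) {
      res <- sw_ftest_(sw, L)
      method <- "satterthwaite"
      if (is.na(res$df2)) res <- NULL
    } else res <- NULL
    if (is.null(res)) {
      lr <- lrt_family_(fit, members)
      res <- list(F = lr$chisq / lr$df, df1 = lr$df, df2 = Inf)
      method <- "lrt"
    }
    p <- pf(res$F, res$df1, res$df2, lower.tail = FALSE)
    open <- is.finite(p) && p < alpha
    fam_rows[[fam]] <- data.frame(family = fam,
                                  members = paste(members, collapse = ","),
                                  F = res$F, df1 = res$df1, df2 = res$df2,
                                  p = p, gate_open = open, method = method)
    if (open)
      wald_rows[[fam]] <- cbind(family = fam,
                                all_effects[all_effects$treatment %in%
                                              members, ])
  }
  structure(list(outcome = fit$outcome, alpha = alpha,
                 families = do.call(rbind, c(fam_rows,
                                             make.row.names = FALSE)),
                 wald = if (length(wald_rows))
                   do.call(rbind, c(wald_rows, make.row.names = FALSE))
                 else NULL,
                 effects = all_effects,
                 fallback = fit$fallback),
            class = "gated_result")
}

#' @export
print.gated_result <- function(x, ...) {
  cat(sprintf("<gated_result> outcome: %s, alpha = %g\n", x$outcome,
              x$alpha))
  print(x$families)
  if (!is.null(x$wald)) {
    cat("Wald comparisons behind open gates:\n")
    print(x$wald)
  } else cat("No gates open: no per-inhibitor comparisons.\n")
  invisible(x)
}

# likelihood-ratio test: ML refit with family members collapsed to control
lrt_family_ <- function(fit, members) {
  dat <- fit$data
  full <- suppressMessages(
    lme4::lmer(stats::formula(fit$model), data = dat, REML = FALSE))
  dat_red <- dat
  tr <- as.character(dat_red$treatment)
  tr[tr %in% members] <- "control"
  dat_red$treatment <- stats::relevel(factor(tr), ref = "control")
  red <- suppressMessages(
    lme4::lmer(stats::formula(fit$model), data = dat_red, REML = FALSE))
  chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
  list(chisq = chisq, df = length(members),
       p = pchisq(chisq, length(members), lower.tail = FALSE))
}
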