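# Generators: determinism, noise-free limits, ground-truth bookkeeping.

test_that("make_coloc_image handles degenerate and seeded cases", {
  # vacuous case
  out0 <- make_coloc_image(coloc_truth(0, 0.5), seed = 1)
  expect_identical(mask_labels(out0$mask), integer(0))
  expect_identical(nrow(out0$truth), 0L)
  expect_true(all(out0$mask$grid == 0L))

  # degenerate probability: all flags set
  out1 <- make_coloc_image(coloc_truth(50, 1.0), seed = 2)
  expect_true(all(out1$truth$flagged))
  expect_identical(sort(mask_labels(out1$mask)), 1:50)

  # seeded regeneration is exact (flag count is one fixed binomial draw)
  tr <- coloc_truth(200, 0.3)
  a <- make_coloc_image(tr, seed = 7)
  b <- make_coloc_image(tr, seed = 7)
  expect_identical(a$mask$grid, b$mask$grid)
  expect_identical(a$truth, b$truth)
  expect_identical(a$marker, b$marker)
  expect_gt(sum(a$truth$flagged), 0)

  # capacity error when the cells cannot fit
  expect_error(
    make_coloc_image(coloc_truth(100, 0.5), seed = 1,
                     image_size = c(40L, 40L), max_tries = 20L),
    "too small")
})

test_that("nuclei are concentric and labelled like their cells", {
  out <- make_coloc_image(coloc_truth(30, 0.5), seed = 3)
  expect_identical(sort(mask_labels(out$nuclei)), sort(mask_labels(out$mask)))
  # every nucleus pixel lies inside its cell
  nz <- out$nuclei$grid > 0L
  expect_true(all(out$mask$grid[nz] == out$nuclei$grid[nz]))
})

test_that("make_timelapse: exact arithmetic, shapes, CLT recovery", {
  # sd 0: every consecutive displacement is exactly v * dt = 20 um
  tl <- make_timelapse(4, mean_speed_um_h = 40, sd_speed = 0,
                       interval_min = 30, n_frames = 5, seed = 1)
  for (tr in split(tl$tracks, tl$tracks$cell_id)) {
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    expect_equal(steps, rep(20, 4), tolerance = 1e-12)
  }

  tiny <- make_timelapse(1, n_frames = 2, seed = 1)
  expect_identical(nrow(tiny$tracks), 2L)

  expect_error(make_timelapse(10, sd_speed = -1, seed = 1), "sd_speed")

  # CLT bound on the stored truth speeds
  big <- make_timelapse(500, mean_speed_um_h = 39, sd_speed = 10, seed = 42)
  expect_lt(abs(mean(big$truth$speed_um_h) - 39), 3 * 10 / sqrt(500))
  expect_identical(big$truth,
                   make_timelapse(500, 39, 10, seed = 42)$truth)
})

test_that("make_explant_experiment: noise-free limit and structure", {
  des0 <- explant_design(n_litters = 2, slices_per_litter = 1,
                         cells_per_slice = 3,
                         treatments = c("control", "TFB-TBOA"),
                         multipliers = list(control = c(1, 1, 1, 1),
                                            `TFB-TBOA` = c(1, 1, 1, 1)),
                         sigma_litter = 0, sigma_slice = 0, sigma_cell = 0,
                         sigma_count_slice = 0)
  ex0 <- make_explant_experiment(des0, seed = 1)
  ann <- annotate_migration(ex0$records)
  expect_equal(ann$lateral, rep(des0$baseline_lateral_um, nrow(ann)))
  expect_equal(ann$radial, rep(des0$baseline_radial_um, nrow(ann)))

  # slice nested in litter: each slice id maps to exactly one litter
  des <- explant_design(n_litters = 3, slices_per_litter = 2,
                        cells_per_slice = 5)
  ex <- make_explant_experiment(des, seed = 2)
  nest <- unique(ex$records[c("slice", "litter")])
  expect_identical(anyDuplicated(nest$slice), 0L)
  expect_setequal(unique(ex$records$treatment), des$treatments)

  # regeneration with the same seed is byte-identical
  expect_identical(ex, make_explant_experiment(des, seed = 2))
  expect_false(identical(ex$records,
                         make_explant_experiment(des, seed = 3)$records))
})

test_that("explant count-fold plants the stated ratio", {
  # tenfold count multiplier: treated/control mean ratio ~ 10 at large n
  des <- explant_design(n_litters = 20, slices_per_litter = 4,
                        cells_per_slice = 1,
                        treatments = c("control", "TFB-TBOA"),
                        baseline_count = 200)
  ex <- make_explant_experiment(des, seed = 5)
  m <- tapply(ex$counts$n_outside, ex$counts$treatment, mean)
  ratio <- unname(m["TFB-TBOA"] / m["control"])
  # slice overdispersion dominates: sd of the ratio ~ 10 * 0.25 * sqrt(2/80)
  expect_lt(abs(ratio - 10), 3 * 10 * 0.25 * sqrt(2 / 80))
})

test_that("explant_design validates parameters", {
  expect_error(explant_design(n_litters = 1), "n_litters")
  expect_error(
    explant_design(treatments = c("control", "X"),
                   multipliers = list(control = c(1, 1, 1, 1),
                                      X = c(1, 1, 1, 1),
                                      bogus = c(2, 1, 1, 1))),
    "unknown treatment")
  expect_error(
    explant_design(treatments = c("control", "X"),
                   multipliers = list(control = c(2, 1, 1, 1),
                                      X = c(1, 1, 1, 1))),
    "control multipliers")
  expect_error(explant_design(sigma_cell = -0.1), "sigma_cell")
})

test_that("make_count_matrix plants exactly the stated QC failures", {
  # zero planted failures: everything survives
  mc0 <- make_count_matrix(20, 1000, planted = c(), seed = 1,
                           max_features = 900)
  expect_true(all(mc0$truth$survive))

  # planted low-feature cells are exactly the failing ones
  mc <- make_count_matrix(40, 2000, planted = c(low_features = 5L),
                          seed = 2, max_features = 1900)
  expect_identical(sum(!mc$truth$survive), 5L)
  expect_setequal(mc$truth$planted[!mc$truth$survive], "low_features")

  # brute-force re-evaluation of the three rules agrees with the truth
  mc2 <- make_count_matrix(60, 6000,
                           planted = c(low_features = 4L,
                                       high_features = 3L,
                                       high_mito = 5L), seed = 3)
  m <- as.matrix(mc2$matrix)
  nf <- colSums(m > 0)
  mito <- colSums(m[startsWith(rownames(m), "mt-"), ]) / colSums(m)
  survive <- nf >= 200 & nf <= 5000 & mito <= 0.25
  expect_identical(unname(survive), mc2$truth$survive)

  expect_error(make_count_matrix(10, 0, seed = 1), "n_genes")
  expect_error(make_count_matrix(3, 1000, planted = c(low_features = 5L),
                                 seed = 1, max_features = 900), "planted")
})
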