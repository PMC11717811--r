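# Migration geometry: distances, speed, the white-matter curve, counting.

test_that("net and axis distances satisfy the stated identities", {
  expect_equal(net_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(net_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(axis_distance(c(0, 0), c(3, 4), "lateral_x"), 3)
  expect_equal(axis_distance(c(0, 0), c(3, 4), "radial_y"), 4)

  withr::with_seed(31, {
    p1 <- matrix(rnorm(200, 0, 100), ncol = 2)
    p2 <- matrix(rnorm(200, 0, 100), ncol = 2)
  })
  # symmetry and the Pythagorean identity on random pairs
  expect_equal(axis_distance(p1, p2, "lateral_x"),
               axis_distance(p2, p1, "lateral_x"))
  expect_equal(net_distance(p1, p2),
               sqrt((p2[, 1] - p1[, 1])^2 + (p2[, 2] - p1[, 2])^2))
  expect_equal(net_distance(p1, p2)^2,
               axis_distance(p1, p2, "lateral_x")^2 +
                 axis_distance(p1, p2, "radial_y")^2)
})

test_that("migration_speed is d/t with a guarded domain", {
  expect_equal(migration_speed(100, 2), 50)
  expect_equal(migration_speed(0, 1), 0)
  expect_error(migration_speed(10, 0), "t")
  expect_error(migration_speed(10, -1), "t")
})

test_that("speed recovery on synthetic time-lapse matches the truth", {
  tl <- make_timelapse(200, mean_speed_um_h = 39, sd_speed = 10, seed = 8)
  est <- track_speeds(tl$tracks)
  # constant-velocity straight tracks: estimator equals the truth exactly
  expect_equal(est$speed_um_h, tl$truth$speed_um_h, tolerance = 1e-10)
})

test_that("smooth_white_matter_curve interpolates and smooths", {
  seg <- smooth_white_matter_curve(cbind(c(0, 100), c(0, 0)))
  expect_true(all(abs(seg$samples[, "y"]) < 1e-12))
  expect_true(all(diff(seg$samples[, "x"]) <= 1 + 1e-9))

  pts <- cbind(seq(0, 100, 25), 2 * seq(0, 100, 25))   # collinear
  cv <- smooth_white_matter_curve(pts, smoothing = 0)
  expect_equal(cv$fun(pts[, 1]), pts[, 2], tolerance = 1e-9)

  # noisy sine: smoothing recovers the generating curve within a bound
  withr::with_seed(41, {
    x <- seq(0, 300, by = 10)
    y <- 40 * sin(x / 60) + rnorm(length(x), 0, 2)
  })
  sm <- smooth_white_matter_curve(cbind(x, y), smoothing = 0.6)
  xs <- seq(10, 290, by = 5)
  expect_lt(max(abs(sm$fun(xs) - 40 * sin(xs / 60))), 6)

  expect_warning(smooth_white_matter_curve(rbind(c(0, 0), c(0, 2),
                                                 c(10, 1))), "duplicate")
  expect_error(smooth_white_matter_curve(rbind(c(1, 1))), "2 points")
})

test_that("distance_to_curve: sign convention and closed forms", {
  horiz <- smooth_white_matter_curve(cbind(c(0, 100), c(0, 0)))
  expect_equal(distance_to_curve(c(10, 25), horiz), 25)
  expect_equal(distance_to_curve(c(50, -30), horiz), -30)
  expect_lt(abs(distance_to_curve(c(42, 0), horiz)), 1e-9)

  diag45 <- smooth_white_matter_curve(cbind(0:10 * 10, 0:10 * 10))
  expect_equal(distance_to_curve(c(0, 10), diag45), 10 / sqrt(2),
               tolerance = 1e-6)

  # horizontal curve: |distance| equals |dy| within sampling tolerance
  withr::with_seed(42, cells <- cbind(runif(50, 0, 100),
                                      runif(50, -80, 80)))
  d <- distance_to_curve(cells, horiz)
  expect_lt(max(abs(d - cells[, 2])), 0.5)

  # orientation flag flips the sign
  flipped <- smooth_white_matter_curve(cbind(c(0, 100), c(0, 0)),
                                       orientation = "down")
  expect_equal(distance_to_curve(c(10, 25), flipped), -25)
})

test_that("count_migrated counts planted blobs with ROI exclusion", {
  img <- matrix(0, 120, 120)
  put <- function(im, r, c) { im[r:(r + 4), c:(c + 4)] <- 1; im }
  outside <- list(c(5, 5), c(5, 100), c(100, 5), c(100, 100), c(60, 5),
                  c(5, 60), c(110, 60))
  for (p in outside) img <- put(img, p[1], p[2])
  img <- put(img, 58, 58); img <- put(img, 64, 70)   # 2 inside the ROI
  res <- count_migrated(img, implant_center_um = c(62, 62),
                        implant_radius_um = 25, min_area_px = 10,
                        method = "fixed", fixed_threshold = 0.5)
  expect_identical(res$n_outside, 7L)

  expect_identical(count_migrated(matrix(0, 10, 10), c(5, 5), 2,
                                  method = "fixed",
                                  fixed_threshold = 0.5)$n_outside, 0L)
  expect_warning(count_migrated(img, c(62, 62), 0, min_area_px = 10,
                                method = "fixed", fixed_threshold = 0.5),
                 "zero-radius")

  # cortex mask splits the outside count
  cortex <- row(img) <= 40
  res2 <- count_migrated(img, c(62, 62), 25, cortex_mask = cortex,
                         min_area_px = 10, method = "fixed",
                         fixed_threshold = 0.5)
  expect_identical(res2$n_cortex, 3L)   # blobs with centroid row <= 40
  expect_lte(res2$n_cortex, res2$n_outside)
})

test_that("count_migrated is invariant to scene+ROI translation", {
  withr::with_seed(43, {
    img <- matrix(0, 90, 90)
    for (k in 1:6) {
      r <- sample(5:70, 1); c <- sample(5:70, 1)
      img[r:(r + 3), c:(c + 3)] <- 1
    }
  })
  base <- count_migrated(img, c(40, 40), 15, min_area_px = 5,
                         method = "fixed", fixed_threshold = 0.5)
  shifted <- apply_translation(img, 7, 9)
  moved <- count_migrated(shifted, c(40 + 9, 40 + 7), 15, min_area_px = 5,
                          method = "fixed", fixed_threshold = 0.5)
  expect_identical(moved$n_outside, base$n_outside)
})

test_that("count-fold recovery on paired synthetic scenes", {
  make_scene <- function(n_blobs, seed) {
    withr::with_seed(seed, {
      img <- matrix(0, 256, 256)
      placed <- 0; centers <- matrix(numeric(0), 0, 2)
      while (placed < n_blobs) {
        r <- sample(5:250, 1); c <- sample(5:250, 1)
        if (nrow(centers) == 0 ||
            min(abs(centers[, 1] - r) + abs(centers[, 2] - c)) > 8) {
          img[r:(r + 2), c:(c + 2)] <- 1
          centers <- rbind(centers, c(r, c)); placed <- placed + 1
        }
      }
      img
    })
  }
  withr::with_seed(44, {
    n_ctrl <- rpois(1, 20); n_trt <- rpois(1, 200)
  })
  ctrl <- count_migrated(make_scene(n_ctrl, 1), c(-100, -100), 10,
                         min_area_px = 5, method = "fixed",
                         fixed_threshold = 0.5)
  trt <- count_migrated(make_scene(n_trt, 2), c(-100, -100), 10,
                        min_area_px = 5, method = "fixed",
                        fixed_threshold = 0.5)
  expect_identical(ctrl$n_outside, n_ctrl)
  expect_identical(trt$n_outside, n_trt)
})

test_that("annotate_migration derives consistent columns", {
  des <- explant_design(n_litters = 2, slices_per_litter = 1,
                        cells_per_slice = 10)
  ex <- make_explant_experiment(des, seed = 6)
  curve <- smooth_white_matter_curve(cbind(c(-2000, 2000), c(150, 150)))
  ann <- annotate_migration(ex$records, curve = curve)
  expect_equal(ann$net^2, ann$lateral^2 + ann$radial^2)
  expect_equal(ann$speed, ann$net / ann$t_h)
  expect_equal(ann$cc_to_ctx, ann$y2 - 150, tolerance = 0.5)
  expect_error(annotate_migration(data.frame(x1 = 1)), "x1, y1")
})
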