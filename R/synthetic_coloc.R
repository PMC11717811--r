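#' Ground-truth specification for a synthetic colocalization image
#'
#' Describes a two-channel scene: `n_cells` reporter-positive cells of which
#' a fraction truly express the marker, with the marker localized to the
#' membrane ring, the cytoplasm, or the nucleus. Emulates the quantities
#' behind reporter/marker percent-positive measurements.
#'
#' @param n_cells number of cells (>= 0).
#' @param true_positive_fraction probability a cell truly expresses the
#'   marker.
#' @param marker_pattern `"membrane"`, `"cytoplasmic"` or `"nuclear"`.
#' @param pixel_size_um pixel size (default 0.5 um/px, a typical 40x
#'   confocal sampling).
#' @return A `coloc_truth` object.
#' @export
coloc_truth <- function(n_cells, true_positive_fraction,
                        marker_pattern = c("membrane", "cytoplasmic",
                                           "nuclear"),
                        pixel_size_um = 0.5) {
  marker_pattern <- match.arg(marker_pattern)
  check_number_(n_cells, "n_cells", lower = 0, integer = TRUE)
  check_number_(true_positive_fraction, "true_positive_fraction",
                lower = 0, upper = 1)
  check_number_(pixel_size_um, "pixel_size_um", lower = 0,
                strict_lower = TRUE)
  structure(list(n_cells = as.integer(n_cells),
                 true_positive_fraction = true_positive_fraction,
                 marker_pattern = marker_pattern,
                 pixel_size_um = pixel_size_um),
            class = "coloc_truth")
}

#' Generate a synthetic two-channel colocalization image
#'
#' Renders `n_cells` non-overlapping axis-aligned ellipses (the reporter
#' label mask), draws per-cell truth flags `Bernoulli(true_positive_fraction)`
#' and paints marker signal only on flagged cells: over the membrane ring
#' (dilate(2) minus erode(2) of the cell, disk element) for the membrane
#' pattern, over the whole cell for the cytoplasmic pattern, or over the
#' nucleus (concentric half-axes ellipse) for the nuclear pattern, plus
#' Gaussian background noise. A nucleus label mask is always emitted so the
#' DAPI scoring path can be exercised. Deterministic given `seed`;
#' non-overlap is enforced by rejection sampling with bounded retries.
#'
#' @param truth a [coloc_truth()].
#' @param seed integer seed.
#' @param image_size `(rows, cols)` in px.
#' @param axis_range_px range of ellipse semi-axes in px.
#' @param signal,noise_sd marker foreground level and background noise SD.
#' @param max_tries placement attempts per cell before a capacity error.
#' @return List: `mask` (cell [label_mask()], labels exactly `1..n_cells`),
#'   `nuclei` (nucleus label mask), `marker` (numeric matrix), `truth`
#'   (data.frame: label, cx, cy, a, b, flagged).
#' @export
make_coloc_image <- function(truth, seed, image_size = c(384L, 384L),
                             axis_range_px = c(3, 6), signal = 1,
                             noise_sd = 0.08, max_tries = 200L) {
  if (!inherits(truth, "coloc_truth"))
    stop("`truth` must be a coloc_truth", call. = FALSE)
  nr <- as.integer(image_size[1]); nc <- as.integer(image_size[2])
  n <- truth$n_cells
  with_seed_(seed, {
    grid <- matrix(0L, nr, nc)
    nuc <- matrix(0L, nr, nc)
    marker <- matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    flags <- if (n > 0) rbinom(n, 1L, truth$true_positive_fraction) == 1L
    else logical(0)
    cx <- cy <- aa <- bb <- numeric(n)
    margin <- 3  # keeps neighbouring donuts from merging
    rmax <- axis_range_px[2]
    placed <- 0L
    if (n > 0) for (k in 1:n) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        a <- runif(1, axis_range_px[1], axis_range_px[2])
        b <- runif(1, axis_range_px[1], axis_range_px[2])
        x <- runif(1, rmax + margin + 1, nc - rmax - margin)
        y <- runif(1, rmax + margin + 1, nr - rmax - margin)
        if (placed == 0L ||
            all(sqrt((cx[seq_len(placed)] - x)^2 +
                       (cy[seq_len(placed)] - y)^2) >
                pmax(aa[seq_len(placed)], bb[seq_len(placed)]) +
                max(a, b) + margin)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf(
          "could not place cell %d of %d after %d tries: image too small",
          k, n, max_tries), call. = FALSE)
      placed <- placed + 1L
      cx[k] <- x; cy[k] <- y; aa[k] <- a; bb[k] <- b
      win_r <- max(1, floor(y - b)):min(nr, ceiling(y + b))
      win_c <- max(1, floor(x - a)):min(nc, ceiling(x + a))
      dyw <- (win_r - y) / b
      dxw <- (win_c - x) / a
      inside <- outer(dyw^2, dxw^2, `+`) <= 1
      sub <- grid[win_r, win_c, drop = FALSE]
      sub[inside] <- k
      grid[win_r, win_c] <- sub
      nin <- outer((2 * dyw)^2, (2 * dxw)^2, `+`) <= 1  # half-axes nucleus
      subn <- nuc[win_r, win_c, drop = FALSE]
      subn[nin] <- k
      nuc[win_r, win_c] <- subn
      if (flags[k]) {
        # render signal in a window 2 px beyond the cell so the ring fits
        wr <- max(1, floor(y - b) - 2L):min(nr, ceiling(y + b) + 2L)
        wc <- max(1, floor(x - a) - 2L):min(nc, ceiling(x + a) + 2L)
        cellw <- grid[wr, wc, drop = FALSE] == k
        sig_px <- switch(truth$marker_pattern,
                         cytoplasmic = cellw,
                         membrane = binary_dilate(cellw, 2L) &
                           !binary_erode(cellw, 2L),
                         nuclear = nuc[wr, wc, drop = FALSE] == k)
        mw <- marker[wr, wc, drop = FALSE]
        mw[sig_px] <- mw[sig_px] + signal
        marker[wr, wc] <- mw
      }
    }
    list(mask = label_mask(grid, truth$pixel_size_um),
         nuclei = label_mask(nuc, truth$pixel_size_um),
         marker = marker,
         truth = data.frame(label = seq_len(n), cx = cx, cy = cy,
                            a = aa, b = bb, flagged = flags))
  })
}
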