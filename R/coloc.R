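#' Binarize a marker channel
#'
#' Thresholds a fluorescence channel into a logical marker mask. `"otsu"`
#' picks the threshold maximizing between-class variance over a 256-bin
#' histogram; `"fixed"` uses the supplied value. Pixels with intensity
#' greater than or equal to the threshold are TRUE.
#'
#' @param image numeric matrix, finite-valued.
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold threshold value, required for `method = "fixed"`.
#' @return Logical matrix of the same shape. A constant image with
#'   `method = "otsu"` yields an all-FALSE mask with a warning.
#' @export
binarize_channel <- function(image, method = c("otsu", "fixed"),
                             fixed_threshold = NULL) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image) || any(!is.finite(image)))
    stop("`image` must be a finite numeric matrix", call. = FALSE)
  if (method == "fixed") {
    check_number_(fixed_threshold, "fixed_threshold")
    return(image >= fixed_threshold)
  }
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: Otsu threshold undefined, returning all-FALSE",
            call. = FALSE)
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  image >= otsu_threshold(image)
}

# Otsu's method on a 256-bin histogram; returns a cut in intensity units.
# The threshold is placed at the lower edge of the first bin of the upper
# class so that ">= threshold" reproduces the histogram split.
otsu_threshold <- function(image, n_bins = 256L) {
  rng <- range(image)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(image, breaks,
                                        rightmost.closed = TRUE),
                           nbins = n_bins))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(n_bins))
  n <- w[n_bins]; mu_t <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (mu_t * w0[valid] - n * mu[-n_bins][valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  breaks[k + 1L]
}

#' Donut (membrane ring) outlines from a cell label mask
#'
#' For every labelled cell, builds the ring
#' `dilate(cell, r_out) \ erode(cell, r_in)` with a disk (default) or square
#' structuring element, the region used to score membrane-localized markers.
#' Ring pixels never cover any cell's eroded interior, and pixels claimed by
#' several rings are assigned to the nearest cell (minimum Euclidean distance
#' to the cell's own pixels; ties go to the smaller label).
#'
#' A label whose interior vanishes under erosion still gets a ring (the full
#' dilation). Output labels are a subset of input labels.
#'
#' @param mask [label_mask()] or integer label matrix.
#' @param r_in,r_out inner / outer radii in pixels (>= 0, not both 0);
#'   defaults 2 px each.
#' @param se structuring element: `"disk"` (Euclidean) or `"square"`
#'   (Chebyshev).
#' @return A [label_mask()] of rings carrying the input pixel size.
#' @export
donut_outline <- function(mask, r_in = 2L, r_out = 2L,
                          se = c("disk", "square")) {
  se <- match.arg(se)
  check_number_(r_in, "r_in", lower = 0, integer = TRUE)
  check_number_(r_out, "r_out", lower = 0, integer = TRUE)
  if (r_in == 0 && r_out == 0)
    stop("`r_in` and `r_out` must not both be 0", call. = FALSE)
  g <- mask_grid(mask)
  px <- mask_pixel_size(mask)
  nr <- nrow(g); nc <- ncol(g)
  out <- matrix(0L, nr, nc)
  labs <- mask_labels(g)
  if (length(labs) == 0L) return(label_mask(out, px))

  # work per label on its bounding box (padded by the radii) for speed;
  # pixel indices are lifted back to the full grid
  cell_idx <- split(which(g > 0L), g[g > 0L])[as.character(labs)]
  pad <- max(r_in, r_out)
  win_of <- function(i) {
    p <- cell_idx[[i]]
    rs <- ((p - 1L) %% nr) + 1L
    cs <- ((p - 1L) %/% nr) + 1L
    list(r = max(1L, min(rs) - pad):min(nr, max(rs) + pad),
         c = max(1L, min(cs) - pad):min(nc, max(cs) + pad))
  }

  # global union of eroded interiors: rings never intrude into any cell core
  eroded_any <- matrix(FALSE, nr, nc)
  for (i in seq_along(labs)) {
    w <- win_of(i)
    er <- binary_erode(g[w$r, w$c, drop = FALSE] == labs[i], r_in, se)
    eroded_any[w$r, w$c] <- eroded_any[w$r, w$c] | er
  }

  claims <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    w <- win_of(i)
    ring <- binary_dilate(g[w$r, w$c, drop = FALSE] == labs[i], r_out, se) &
      !eroded_any[w$r, w$c, drop = FALSE]
    local <- which(ring)
    lr <- ((local - 1L) %% length(w$r)) + 1L
    lc <- ((local - 1L) %/% length(w$r)) + 1L
    claims[[i]] <- (w$c[lc] - 1L) * nr + w$r[lr]
  }
  all_idx <- unlist(claims)
  owner <- rep.int(seq_along(labs), lengths(claims))
  dup_idx <- unique(all_idx[duplicated(all_idx)])
  uncontested <- !(all_idx %in% dup_idx)
  out[all_idx[uncontested]] <- labs[owner[uncontested]]

  # contested pixels: nearest cell wins (squared pixel distance, then label)
  for (p in dup_idx) {
    cand <- owner[all_idx == p]
    pr <- ((p - 1L) %% nr) + 1L
    pc <- ((p - 1L) %/% nr) + 1L
    best <- cand[1L]; best_d <- Inf
    for (i in cand) {
      cp <- cell_idx[[i]]
      d2 <- min((((cp - 1L) %% nr) + 1L - pr)^2 +
                  (((cp - 1L) %/% nr) + 1L - pc)^2)
      if (d2 < best_d || (d2 == best_d && labs[i] < labs[best])) {
        best <- i; best_d <- d2
      }
    }
    out[p] <- labs[best]
  }
  label_mask(out, px)
}

#' Per-cell overlap fraction with a binarized marker
#'
#' For every label in the scored region mask (whole cells, donut rings, or
#' nuclei), computes `fraction = |region AND marker| / |region|`.
#'
#' @param region [label_mask()] or integer matrix of scored regions.
#' @param marker logical matrix (from [binarize_channel()]), same shape.
#' @param region_kind label recorded in the output (`"whole"`, `"donut"`,
#'   `"nucleus"`, ...).
#' @param expected_labels optional labels that should have been scored;
#'   those absent from `region` (zero area) are dropped with a warning.
#' @return A cell score table: data.frame with columns `label`,
#'   `region_kind`, `area_px`, `overlap_px`, `fraction`.
#' @export
overlap_fraction <- function(region, marker, region_kind = "whole",
                             expected_labels = NULL) {
  g <- mask_grid(region)
  if (!is.matrix(marker) || !identical(dim(g), dim(marker)))
    stop("`region` and `marker` must have identical shapes", call. = FALSE)
  marker <- marker & !is.na(marker)
  labs <- mask_labels(g)
  if (!is.null(expected_labels)) {
    missing <- setdiff(expected_labels, labs)
    if (length(missing))
      warning(sprintf("excluding %d zero-area label(s): %s", length(missing),
                      paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(labs) == 0L)
    return(data.frame(label = integer(), region_kind = character(),
                      area_px = integer(), overlap_px = integer(),
                      fraction = numeric()))
  pos <- g > 0L
  area <- tabulate(g[pos], nbins = max(labs))
  ov <- tabulate(g[pos & marker], nbins = max(labs))
  data.frame(label = labs, region_kind = region_kind,
             area_px = area[labs], overlap_px = ov[labs],
             fraction = ov[labs] / area[labs])
}

#' Call cells positive by overlap threshold
#'
#' A cell is positive iff its overlap fraction is *strictly* greater than the
#' threshold (a fraction of exactly 0.6 is negative under the default).
#'
#' @param table cell score table from [overlap_fraction()].
#' @param threshold overlap threshold in `[0, 1]`; default 0.6.
#' @return The table with a logical `positive` column appended.
#' @export
classify_positive <- function(table, threshold = 0.6) {
  check_number_(threshold, "threshold", lower = 0, upper = 1)
  if (!is.data.frame(table) || is.null(table$fraction))
    stop("`table` must contain a `fraction` column", call. = FALSE)
  table$positive <- table$fraction > threshold
  table
}

#' Percent positive cells
#'
#' `100 * positives / scored cells`, the reporter-denominated percentage the
#' colocalization assay reports.
#'
#' @param table classified cell score table (see [classify_positive()]).
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive <- function(table) {
  if (!is.data.frame(table) || is.null(table$positive))
    stop("`table` must contain a `positive` column", call. = FALSE)
  if (nrow(table) == 0L)
    stop("percent_positive is undefined for an empty table", call. = FALSE)
  100 * mean(table$positive)
}

#' Rigid translation registration by cross-correlation
#'
#' Estimates the integer `(dy, dx)` displacement of `moving` relative to
#' `fixed` by locating the peak of their FFT cross-correlation, i.e. the
#' offset such that `moving` looks like `fixed` shifted by `(dy, dx)`.
#' Shifting `moving` by `(-dy, -dx)` best aligns the pair. This replaces
#' elastic alignment for same-stage acquisitions.
#'
#' @param moving,fixed numeric matrices of identical shape.
#' @return Integer vector `c(dy, dx)`; `c(0, 0)` with a warning when either
#'   image is constant.
#' @export
register_translation <- function(moving, fixed) {
  if (!is.matrix(moving) || !identical(dim(moving), dim(fixed)))
    stop("`moving` and `fixed` must be matrices of identical shape",
         call. = FALSE)
  if (sd(moving) == 0 || sd(fixed) == 0) {
    warning("constant image(s): returning zero offset", call. = FALSE)
    return(c(dy = 0L, dx = 0L))
  }
  f1 <- fft(moving - mean(moving))
  f2 <- fft(fixed - mean(fixed))
  cc <- Re(fft(f1 * Conj(f2), inverse = TRUE))
  peak <- which.max(cc) - 1L
  nr <- nrow(moving); nc <- ncol(moving)
  dy <- peak %% nr
  dx <- peak %/% nr
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  c(dy = as.integer(dy), dx = as.integer(dx))
}

#' Apply an integer translation to an image
#'
#' @param image matrix.
#' @param dy,dx integer shift (rows down, columns right); vacated pixels get
#'   `fill`.
#' @return Shifted matrix.
#' @export
apply_translation <- function(image, dy, dx, fill = 0) {
  shift_matrix(image, as.integer(dy), as.integer(dx), fill = fill)
}

#' Score a nuclear marker via the DAPI path
#'
#' Nuclei are segmented separately (DAPI); a nucleus counts as
#' reporter-positive when its overlap fraction with the binarized reporter
#' exceeds `threshold`, and, among reporter-positive nuclei, marker
#' positivity is scored the same way. The returned percentage uses
#' reporter-positive nuclei as denominator.
#'
#' @param dapi_mask [label_mask()] of nuclei.
#' @param reporter,marker logical matrices aligned with `dapi_mask` (apply
#'   [register_translation()] upstream if acquisitions were separate).
#' @param threshold overlap threshold (default 0.6, strict).
#' @return List with `table` (per-nucleus scores for reporter-positive
#'   nuclei, marker positivity called) and `percent_positive`.
#' @export
score_nuclear_marker <- function(dapi_mask, reporter, marker,
                                 threshold = 0.6) {
  rep_tab <- classify_positive(
    overlap_fraction(dapi_mask, reporter, region_kind = "nucleus"),
    threshold)
  keep <- rep_tab$label[rep_tab$positive]
  if (length(keep) == 0L)
    stop("no reporter-positive nuclei: percentage undefined", call. = FALSE)
  g <- mask_grid(dapi_mask)
  g[!(g %in% keep)] <- 0L
  tab <- classify_positive(
    overlap_fraction(g, marker, region_kind = "nucleus"), threshold)
  list(table = tab, percent_positive = percent_positive(tab))
}

#' Full colocalization scoring pipeline
#'
#' Binarizes the marker channel and scores per-cell positivity with the
#' region appropriate to the marker's localization: whole cell for
#' cytoplasmic markers, donut ring ([donut_outline()]) for membrane markers,
#' and the DAPI/nucleus path ([score_nuclear_marker()]) for nuclear markers.
#'
#' @param mask reporter-cell [label_mask()].
#' @param marker_image raw marker channel (numeric matrix).
#' @param pattern `"membrane"`, `"cytoplasmic"` or `"nuclear"`.
#' @param threshold overlap threshold (strict, default 0.6).
#' @param nuclei nucleus [label_mask()], required for `pattern = "nuclear"`.
#' @param r_in,r_out donut radii (membrane pattern).
#' @param method,fixed_threshold binarization, see [binarize_channel()].
#' @return List with `table`, `percent_positive`, `region_kind`,
#'   `threshold`, `n_cells`.
#' @export
score_coloc <- function(mask, marker_image,
                        pattern = c("cytoplasmic", "membrane", "nuclear"),
                        threshold = 0.6, nuclei = NULL,
                        r_in = 2L, r_out = 2L,
                        method = "otsu", fixed_threshold = NULL) {
  pattern <- match.arg(pattern)
  marker <- binarize_channel(marker_image, method, fixed_threshold)
  if (pattern == "nuclear") {
    if (is.null(nuclei))
      stop("`nuclei` mask required for the nuclear pattern", call. = FALSE)
    reporter <- mask_grid(mask) > 0L
    res <- score_nuclear_marker(nuclei, reporter, marker, threshold)
    tab <- res$table
  } else {
    region <- if (pattern == "membrane")
      donut_outline(mask, r_in = r_in, r_out = r_out) else mask
    tab <- classify_positive(
      overlap_fraction(region, marker,
                       region_kind = if (pattern == "membrane") "donut"
                       else "whole",
                       expected_labels = mask_labels(mask)),
      threshold)
  }
  list(table = tab, percent_positive = percent_positive(tab),
       region_kind = unique(tab$region_kind), threshold = threshold,
       n_cells = nrow(tab))
}
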