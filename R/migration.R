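#' Migration distances and speed
#'
#' Displacement of a migrated cell relative to the implant-site center:
#' net Euclidean distance `d = sqrt((x2-x1)^2 + (y2-y1)^2)`, its absolute
#' X component (lateral migration, parallel to the corpus callosum) and
#' absolute Y component (radial migration, toward the cortex), and the
#' migration rate `v = d / t`. Printed-formula semantics make the axis
#' components absolute values, so direction along an axis is not preserved.
#'
#' @param p1,p2 numeric length-2 points `(x, y)` in micrometers, or two-column
#'   matrices of points.
#' @return `net_distance()`: Euclidean distance(s) in um.
#' @examples
#' net_distance(c(0, 0), c(3, 4))   # 5
#' axis_distance(c(0, 0), c(3, 4), "lateral_x")  # 3
#' migration_speed(100, 2)          # 50 um/h
#' @export
net_distance <- function(p1, p2) {
  p1 <- to_points_(p1); p2 <- to_points_(p2)
  sqrt((p2[, 1] - p1[, 1])^2 + (p2[, 2] - p1[, 2])^2)
}

#' @rdname net_distance
#' @param axis `"lateral_x"` (X component) or `"radial_y"` (Y component).
#' @return `axis_distance()`: absolute displacement along the axis, in um.
#' @export
axis_distance <- function(p1, p2, axis = c("lateral_x", "radial_y")) {
  axis <- match.arg(axis)
  p1 <- to_points_(p1); p2 <- to_points_(p2)
  j <- if (axis == "lateral_x") 1L else 2L
  abs(p2[, j] - p1[, j])
}

#' @rdname net_distance
#' @param d distance(s) in um.
#' @param t duration in hours, > 0.
#' @return `migration_speed()`: speed in um/h.
#' @export
migration_speed <- function(d, t) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("`d` must be finite and >= 0", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("`t` must be > 0", call. = FALSE)
  d / t
}

to_points_ <- function(p) {
  if (is.null(dim(p))) {
    if (length(p) != 2L) stop("points must be (x, y)", call. = FALSE)
    p <- matrix(p, 1L, 2L)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2L || !is.numeric(p) || any(!is.finite(p)))
    stop("points must be finite (x, y) pairs", call. = FALSE)
  p
}

#' Annotate migration records with derived distances
#'
#' Takes a table of cell endpoints (columns `x1, y1, x2, y2` in um, optional
#' `t_h` duration in hours) and appends `net`, `lateral`, `radial` (um),
#' `speed` (um/h, when `t_h` present) and, when a white-matter curve is
#' supplied, the signed `cc_to_ctx` distance (positive on the cortex side;
#' only positive values count as corpus-callosum-to-cortex migration).
#'
#' @param records data.frame with endpoint columns; identifier columns
#'   (`cell_id`, `litter`, `slice`, `treatment`) pass through untouched.
#' @param curve optional [smooth_white_matter_curve()] model.
#' @return `records` with derived columns appended; the identity
#'   `net^2 = lateral^2 + radial^2` holds to machine precision.
#' @export
annotate_migration <- function(records, curve = NULL) {
  need <- c("x1", "y1", "x2", "y2")
  if (!all(need %in% names(records)))
    stop("records need columns x1, y1, x2, y2", call. = FALSE)
  p1 <- cbind(records$x1, records$y1)
  p2 <- cbind(records$x2, records$y2)
  records$net <- net_distance(p1, p2)
  records$lateral <- axis_distance(p1, p2, "lateral_x")
  records$radial <- axis_distance(p1, p2, "radial_y")
  if (!is.null(records$t_h)) records$speed <- migration_speed(records$net,
                                                              records$t_h)
  if (!is.null(curve))
    records$cc_to_ctx <- distance_to_curve(p2, curve)
  records
}

#' Count migrated cells outside the implant site
#'
#' Binarizes a reporter channel, labels 8-connected components, filters out
#' components below `min_area_px`, and counts components whose centroid lies
#' outside the implant region of interest; when a cortex mask is given, also
#' counts those whose centroid falls inside the cortex. Component centroids
#' are converted to micrometers with pixel (0,0) at coordinate (0,0) um
#' (column index = X, row index = Y).
#'
#' @param image reporter channel (numeric matrix) *or* an already-binarized
#'   logical matrix.
#' @param implant_center_um implant-site center `(x, y)` in um.
#' @param implant_radius_um implant exclusion radius in um; default 500
#'   (half the 1 mm explant punch). Radius 0 warns and excludes nothing.
#' @param cortex_mask optional logical matrix marking cortex pixels.
#' @param pixel_size_um um per pixel.
#' @param min_area_px minimum component area in px (default 20).
#' @param method,fixed_threshold binarization (see [binarize_channel()]);
#'   ignored when `image` is logical.
#' @return List with `n_outside`, `n_cortex` (NA without a cortex mask) and
#'   `components` (per-component label, area, centroid, classification).
#' @export
count_migrated <- function(image, implant_center_um,
                           implant_radius_um = 500,
                           cortex_mask = NULL, pixel_size_um = 1,
                           min_area_px = 20L,
                           method = "otsu", fixed_threshold = NULL) {
  check_number_(implant_radius_um, "implant_radius_um", lower = 0)
  check_number_(min_area_px, "min_area_px", lower = 0, integer = TRUE)
  check_number_(pixel_size_um, "pixel_size_um", lower = 0,
                strict_lower = TRUE)
  if (implant_radius_um == 0)
    warning("zero-radius implant ROI: nothing excluded", call. = FALSE)
  if (!is.null(cortex_mask) && !identical(dim(image), dim(cortex_mask)))
    stop("`image` and `cortex_mask` must have the same shape", call. = FALSE)
  bin <- if (is.logical(image)) image
  else binarize_channel(image, method, fixed_threshold)
  lab <- label_components(bin)
  labs <- mask_labels(lab)
  empty <- data.frame(label = integer(), area_px = integer(),
                      x_um = numeric(), y_um = numeric(),
                      outside_implant = logical(), in_cortex = logical())
  if (length(labs) == 0L)
    return(list(n_outside = 0L,
                n_cortex = if (is.null(cortex_mask)) NA_integer_ else 0L,
                components = empty))
  idx <- which(lab > 0L)
  lv <- lab[idx]
  nr <- nrow(lab)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(lv, nbins = max(labs))[labs]
  cy <- tapply(rows, lv, mean)[as.character(labs)]
  cx <- tapply(cols, lv, mean)[as.character(labs)]
  keep <- area >= min_area_px
  comp <- data.frame(label = labs[keep], area_px = area[keep],
                     x_um = (cx[keep] - 1) * pixel_size_um,
                     y_um = (cy[keep] - 1) * pixel_size_um)
  d_impl <- sqrt((comp$x_um - implant_center_um[1])^2 +
                   (comp$y_um - implant_center_um[2])^2)
  comp$outside_implant <- d_impl >= implant_radius_um
  if (!is.null(cortex_mask)) {
    ri <- pmin(pmax(round(comp$y_um / pixel_size_um) + 1, 1), nrow(lab))
    ci <- pmin(pmax(round(comp$x_um / pixel_size_um) + 1, 1), ncol(lab))
    comp$in_cortex <- cortex_mask[cbind(ri, ci)] & comp$outside_implant
  } else comp$in_cortex <- NA
  rownames(comp) <- NULL
  list(n_outside = sum(comp$outside_implant),
       n_cortex = if (is.null(cortex_mask)) NA_integer_
       else sum(comp$in_cortex),
       components = comp)
}
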