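#' Smooth curve through operator-marked white-matter points
#'
#' Fits a smooth planar curve y(x) through ordered points marked along the
#' white-matter tracts (corpus callosum) of a coronal slice, the reference
#' line for corpus-callosum-to-cortex (CC-to-CTX) migration distances.
#' With `smoothing = 0` (or fewer than 4 points) the curve interpolates the
#' points exactly (natural cubic spline; straight segment for 2 points);
#' otherwise a cubic smoothing spline with `spar = smoothing` is used.
#' The fitted curve is sampled as a polyline with vertex spacing at most
#' `spacing_um`.
#'
#' @param points two-column matrix/data.frame of `(x, y)` in um, >= 2 rows.
#'   Points are sorted by x; duplicated x values are averaged with a warning.
#' @param smoothing smoothing parameter in `[0, 1.5]` (`spar` scale); 0 =
#'   exact interpolation.
#' @param spacing_um maximum polyline vertex spacing (default 1 um).
#' @param orientation `"up"` when the cortex lies toward increasing y (slices
#'   are imaged cortex-up); `"down"` flips the sign convention.
#' @return A `wm_curve` object: control points, the sampled polyline
#'   (`$samples`), and the cortex-side sign.
#' @export
smooth_white_matter_curve <- function(points, smoothing = 0,
                                      spacing_um = 1,
                                      orientation = c("up", "down")) {
  orientation <- match.arg(orientation)
  check_number_(smoothing, "smoothing", lower = 0, upper = 1.5)
  check_number_(spacing_um, "spacing_um", lower = 0, strict_lower = TRUE)
  p <- to_points_(points)
  if (nrow(p) < 2L) stop("need at least 2 points", call. = FALSE)
  p <- p[order(p[, 1]), , drop = FALSE]
  if (anyDuplicated(p[, 1])) {
    warning("duplicate x values averaged", call. = FALSE)
    y <- tapply(p[, 2], p[, 1], mean)
    p <- cbind(as.numeric(names(y)), as.numeric(y))
    if (nrow(p) < 2L)
      stop("need at least 2 distinct x values", call. = FALSE)
  }
  n <- nrow(p)
  if (smoothing == 0 || n < 4L) {
    f <- if (n == 2L) {
      slope <- (p[2, 2] - p[1, 2]) / (p[2, 1] - p[1, 1])
      function(x) p[1, 2] + slope * (x - p[1, 1])
    } else splinefun(p[, 1], p[, 2], method = "natural")
    if (smoothing > 0 && n < 4L)
      warning("fewer than 4 points: smoothing ignored, interpolating",
              call. = FALSE)
  } else {
    ss <- smooth.spline(p[, 1], p[, 2], spar = smoothing)
    f <- function(x) predict(ss, x)$y
  }
  # refine sampling until consecutive polyline vertices are <= spacing_um
  dx <- spacing_um / 2
  for (it in 1:8) {
    xs <- seq(p[1, 1], p[n, 1], by = dx)
    if (xs[length(xs)] < p[n, 1]) xs <- c(xs, p[n, 1])
    ys <- f(xs)
    seg <- sqrt(diff(xs)^2 + diff(ys)^2)
    if (all(seg <= spacing_um)) break
    dx <- dx / 2
  }
  structure(list(points = p, smoothing = smoothing, fun = f,
                 samples = cbind(x = xs, y = ys),
                 cortex_sign = if (orientation == "up") 1 else -1,
                 spacing_um = spacing_um),
            class = "wm_curve")
}

#' @export
print.wm_curve <- function(x, ...) {
  cat(sprintf("<wm_curve> %d control points, smoothing %g, %d samples\n",
              nrow(x$points), x$smoothing, nrow(x$samples)))
  invisible(x)
}

#' Signed distance from cells to the white-matter curve
#'
#' Shortest Euclidean distance from each cell to the sampled curve polyline,
#' signed positive on the cortex side of the curve and negative otherwise.
#' Only positive values count as CC-to-CTX migration; cells on the
#' white-matter side are reported negative so callers can exclude them.
#'
#' @param cells `(x, y)` point or two-column matrix, in um.
#' @param curve a [smooth_white_matter_curve()] model.
#' @return Numeric vector of signed distances in um (|error| bounded by the
#'   polyline sampling spacing).
#' @export
distance_to_curve <- function(cells, curve) {
  if (!inherits(curve, "wm_curve"))
    stop("`curve` must be a wm_curve", call. = FALSE)
  p <- to_points_(cells)
  s <- curve$samples
  ax <- s[-nrow(s), 1]; ay <- s[-nrow(s), 2]
  bx <- s[-1, 1]; by <- s[-1, 2]
  ux <- bx - ax; uy <- by - ay
  len2 <- ux^2 + uy^2
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    tt <- ((p[i, 1] - ax) * ux + (p[i, 2] - ay) * uy) / len2
    tt <- pmin(pmax(tt, 0), 1)
    qx <- ax + tt * ux; qy <- ay + tt * uy
    d2 <- (p[i, 1] - qx)^2 + (p[i, 2] - qy)^2
    j <- which.min(d2)
    cross <- ux[j] * (p[i, 2] - ay[j]) - uy[j] * (p[i, 1] - ax[j])
    sgn <- if (cross == 0) 1 else sign(cross)
    out[i] <- sqrt(d2[j]) * sgn * curve$cortex_sign
  }
  out
}
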