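#' Generate synthetic time-lapse migration tracks
#'
#' Emulates confocal time-lapse imaging of SVZ-to-cortex migration: slices
#' imaged every `interval_min` minutes for `n_frames` frames, with per-cell
#' speeds drawn from `Normal(mean_speed_um_h, sd_speed)` truncated at zero
#' (truncation rather than resampling preserves seed determinism). Each cell
#' moves along a straight line at constant speed; the generating speed is
#' stored as ground truth. Defaults match imaging every 30 min for 2 h and
#' the reported migration speed distribution (39 +/- 10 um/h).
#'
#' @param n_cells number of cells.
#' @param mean_speed_um_h,sd_speed speed distribution parameters (um/h);
#'   `sd_speed` must be >= 0.
#' @param interval_min frame interval in minutes.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param field_um side of the square starting field (um).
#' @return List: `tracks` (data.frame cell_id, frame, t_h, x, y) and `truth`
#'   (data.frame cell_id, speed_um_h, heading_rad).
#' @export
make_timelapse <- function(n_cells, mean_speed_um_h = 39, sd_speed = 10,
                           interval_min = 30, n_frames = 5L, seed,
                           field_um = 1000) {
  check_number_(n_cells, "n_cells", lower = 1, integer = TRUE)
  check_number_(mean_speed_um_h, "mean_speed_um_h", lower = 0)
  if (!is.numeric(sd_speed) || length(sd_speed) != 1L || sd_speed < 0)
    stop("`sd_speed` must be >= 0", call. = FALSE)
  check_number_(interval_min, "interval_min", lower = 0, strict_lower = TRUE)
  check_number_(n_frames, "n_frames", lower = 2, integer = TRUE)
  with_seed_(seed, {
    speed <- pmax(rnorm(n_cells, mean_speed_um_h, sd_speed), 0)
    heading <- runif(n_cells, 0, 2 * pi)
    x0 <- runif(n_cells, 0, field_um)
    y0 <- runif(n_cells, 0, field_um)
    t_h <- (seq_len(n_frames) - 1L) * interval_min / 60
    tracks <- data.frame(
      cell_id = rep(seq_len(n_cells), each = n_frames),
      frame = rep(seq_len(n_frames), n_cells),
      t_h = rep(t_h, n_cells),
      x = rep(x0, each = n_frames) +
        rep(speed * cos(heading), each = n_frames) * rep(t_h, n_cells),
      y = rep(y0, each = n_frames) +
        rep(speed * sin(heading), each = n_frames) * rep(t_h, n_cells))
    list(tracks = tracks,
         truth = data.frame(cell_id = seq_len(n_cells),
                            speed_um_h = speed, heading_rad = heading))
  })
}

#' Per-cell speeds from a track table
#'
#' Net displacement between the first and last frame of each track divided
#' by the elapsed time (`v = d / t`), the estimator used on real time-lapse
#' data.
#'
#' @param tracks track data.frame (`cell_id`, `t_h`, `x`, `y`).
#' @return data.frame with `cell_id`, `d_um`, `t_h`, `speed_um_h`.
#' @export
track_speeds <- function(tracks) {
  need <- c("cell_id", "t_h", "x", "y")
  if (!all(need %in% names(tracks)))
    stop("tracks need columns cell_id, t_h, x, y", call. = FALSE)
  out <- do.call(rbind, lapply(split(tracks, tracks$cell_id), function(tr) {
    tr <- tr[order(tr$t_h), ]
    n <- nrow(tr)
    d <- net_distance(c(tr$x[1], tr$y[1]), c(tr$x[n], tr$y[n]))
    el <- tr$t_h[n] - tr$t_h[1]
    data.frame(cell_id = tr$cell_id[1], d_um = d, t_h = el,
               speed_um_h = migration_speed(d, el))
  }))
  rownames(out) <- NULL
  out[order(out$cell_id), ]
}
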