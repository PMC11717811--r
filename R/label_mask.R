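#' Label mask container
#'
#' A 2-D integer grid in which 0 is background and each positive integer `k`
#' marks the pixels of cell `k` (the usual output of a segmentation tool,
#' one label per cell), together with the physical pixel size in micrometers.
#' Coordinates are 0-based `(row, column)`; the row index is Y and the column
#' index is X.
#'
#' @param grid integer matrix, non-negative; 0 = background.
#' @param pixel_size_um positive pixel edge length in micrometers.
#' @return An object of class `label_mask` with elements `grid` and
#'   `pixel_size_um`.
#' @examples
#' m <- label_mask(matrix(c(0, 1, 1, 0), 2, 2), pixel_size_um = 0.5)
#' mask_labels(m)
#' @export
label_mask <- function(grid, pixel_size_um = 1) {
  if (!is.matrix(grid) || !is.numeric(grid))
    stop("`grid` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid != round(grid)))
    stop("`grid` must contain finite non-negative integers", call. = FALSE)
  check_number_(pixel_size_um, "pixel_size_um", lower = 0, strict_lower = TRUE)
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, pixel_size_um = as.numeric(pixel_size_um)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %g um/px, %d labels\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_um,
              length(mask_labels(x))))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$grid)

#' Labels present in a mask
#'
#' @param mask a [label_mask()] or plain integer matrix.
#' @return Sorted integer vector of the positive labels present.
#' @export
mask_labels <- function(mask) {
  g <- mask_grid(mask)
  u <- sort(unique(as.vector(g)))
  u[u > 0L]
}

# internal: accept label_mask or bare matrix
mask_grid <- function(mask) {
  if (inherits(mask, "label_mask")) mask$grid
  else if (is.matrix(mask)) mask
  else stop("expected a label_mask or a matrix", call. = FALSE)
}

mask_pixel_size <- function(mask, default = 1) {
  if (inherits(mask, "label_mask")) mask$pixel_size_um else default
}

#' Read and write images as plain-text TSV
#'
#' Images and label masks are exchanged as tab-separated numeric matrices
#' (one row per pixel row). Label masks additionally carry a JSON sidecar
#' `<path>.json` holding the pixel size. A plain-text representation is used
#' because the deliverable is text-only and no TIFF reader is available in
#' the supported dependency set; the in-memory contract is unchanged.
#'
#' @param x matrix or [label_mask()] to write.
#' @param path file path.
#' @return `read_image_tsv()` returns a numeric matrix; `read_mask_tsv()`
#'   returns a [label_mask()]; the writers return `path` invisibly.
#' @export
write_image_tsv <- function(x, path) {
  g <- if (inherits(x, "label_mask")) x$grid else x
  utils::write.table(g, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  if (inherits(x, "label_mask"))
    jsonlite::write_json(list(pixel_size_um = x$pixel_size_um),
                         paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image_tsv
#' @export
read_image_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' @rdname write_image_tsv
#' @export
read_mask_tsv <- function(path) {
  g <- read_image_tsv(path)
  px <- 1
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$pixel_size_um)) px <- as.numeric(meta$pixel_size_um)
  }
  dimnames(g) <- NULL
  label_mask(g, pixel_size_um = px)
}
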