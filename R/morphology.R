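# Binary morphology on logical matrices, via vectorised shifts.
# Grids in this domain are small (<= ~1024^2) and sparse, so OR/AND over the
# structuring-element offsets is fast enough without compiled code.

# offsets of a disk (Euclidean) or square (Chebyshev) structuring element
se_offsets <- function(r, se = c("disk", "square")) {
  se <- match.arg(se)
  r <- as.integer(r)
  if (r < 0L) stop("structuring element radius must be >= 0", call. = FALSE)
  d <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- if (se == "disk") d$dy^2 + d$dx^2 <= r^2 else rep(TRUE, nrow(d))
  as.matrix(d[keep, , drop = FALSE])
}

# shift a matrix by (dy, dx), padding with `fill`
shift_matrix <- function(m, dy, dx, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1L, 1L + dy):min(nr, nr + dy)
  sc <- max(1L, 1L + dx):min(nc, nc + dx)
  if (length(sr) < 1L || length(sc) < 1L || dy >= nr || dy <= -nr ||
      dx >= nc || dx <= -nc) return(out)
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

binary_dilate <- function(m, r, se = "disk") {
  offs <- se_offsets(r, se)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_matrix(m, offs[i, 1L], offs[i, 2L], fill = FALSE)
  out
}

# erosion with background padding: border pixels erode away
binary_erode <- function(m, r, se = "disk") {
  offs <- se_offsets(r, se)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_matrix(m, offs[i, 1L], offs[i, 2L], fill = FALSE)
    if (!any(out)) break
  }
  out
}

#' Connected-component labelling
#'
#' Labels the connected components of a logical matrix using 8-connectivity
#' (edge- and corner-adjacent pixels belong to the same component). Components
#' are numbered 1..k in order of their first pixel in column-major order.
#'
#' @param bin logical matrix (TRUE = foreground).
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(bin) {
  if (!is.matrix(bin)) stop("`bin` must be a matrix", call. = FALSE)
  bin <- bin & !is.na(bin)
  nr <- nrow(bin); nc <- ncol(bin)
  fg <- which(bin)
  out <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(out)
  id <- integer(nr * nc)
  id[fg] <- seq_along(fg)
  r <- ((fg - 1L) %% nr) + 1L
  cc <- ((fg - 1L) %/% nr) + 1L
  edges <- vector("list", 4L)
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (j in seq_along(offs)) {
    r2 <- r + offs[[j]][1L]; c2 <- cc + offs[[j]][2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    sel <- bin[nb]
    edges[[j]] <- rbind(id[fg[ok][sel]], id[nb[sel]])
  }
  ed <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(ed)) g <- igraph::add_edges(g, as.vector(ed))
  memb <- igraph::components(g)$membership
  # renumber by first occurrence in column-major order
  memb <- match(memb, unique(memb))
  out[fg] <- as.integer(memb)
  out
}
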