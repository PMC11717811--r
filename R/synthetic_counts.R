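#' Generate a sparse count matrix with planted QC failures
#'
#' Builds a genes-by-cells sparse count matrix in which designated cells
#' violate exactly one of the three cell-level QC rules (fewer than
#' `min_features` detected features; more than `max_features`; mitochondrial
#' fraction greater than `max_mito`) while all other cells pass comfortably.
#' Gene names start with `n_mito_genes` mitochondrial genes named with the
#' `mito_prefix`. The truth table records which cells must survive the QC
#' gate. Deterministic given `seed`.
#'
#' @param n_cells,n_genes matrix dimensions; `n_genes` must be >= 1 and
#'   large enough to plant high-feature failures (> `max_features`).
#' @param planted named integer vector with any of `low_features`,
#'   `high_features`, `high_mito`; total must be <= `n_cells`.
#' @param seed integer seed.
#' @param min_features,max_features,max_mito the QC rule constants the
#'   plants are built against.
#' @param n_mito_genes,mito_prefix mitochondrial gene block.
#' @return List: `matrix` (dgCMatrix, genes x cells), `truth` (data.frame
#'   barcode, planted, survive).
#' @export
make_count_matrix <- function(n_cells = 100L, n_genes = 6000L,
                              planted = c(low_features = 0L,
                                          high_features = 0L,
                                          high_mito = 0L),
                              seed,
                              min_features = 200L, max_features = 5000L,
                              max_mito = 0.25,
                              n_mito_genes = 13L, mito_prefix = "mt-") {
  check_number_(n_cells, "n_cells", lower = 1, integer = TRUE)
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("`n_genes` must be >= 1", call. = FALSE)
  modes <- c("low_features", "high_features", "high_mito")
  pl <- setNames(integer(3), modes)
  if (length(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% modes))
      stop("`planted` names must be among: ",
           paste(modes, collapse = ", "), call. = FALSE)
    pl[names(planted)] <- as.integer(planted)
  }
  if (any(pl < 0) || sum(pl) > n_cells)
    stop("planted failure counts must be >= 0 and sum to <= n_cells",
         call. = FALSE)
  if (pl["high_features"] > 0 && n_genes <= max_features + 100)
    stop("n_genes too small to plant high-feature failures", call. = FALSE)
  n_mito_genes <- min(n_mito_genes, n_genes)
  genes <- c(paste0(mito_prefix, seq_len(n_mito_genes)),
             sprintf("gene%05d", seq_len(n_genes - n_mito_genes)))
  barcodes <- sprintf("cell%04d", seq_len(n_cells))

  with_seed_(seed, {
    mode_per_cell <- rep("none", n_cells)
    fail_cells <- sample(n_cells, sum(pl))
    mode_per_cell[fail_cells] <- rep(modes, pl)
    non_mito <- setdiff(seq_len(n_genes), seq_len(n_mito_genes))
    ii <- jj <- xx <- vector("list", n_cells)
    upper_ok <- min(max_features, n_genes)
    if (upper_ok < min_features)
      stop("n_genes too small for any cell to pass the feature rules",
           call. = FALSE)
    none_rng <- seq(min_features, min(upper_ok, max(min_features, 1200L)))
    pick1 <- function(v) v[sample.int(length(v), 1L)]  # no 1:x surprise
    for (j in seq_len(n_cells)) {
      mode <- mode_per_cell[j]
      n_expr <- switch(mode,
        none = pick1(none_rng),
        low_features = pick1(seq_len(min_features - 1L)),
        high_features = pick1(seq(max_features + 1L,
                                  min(n_genes, max_features + 400L))),
        high_mito = pick1(none_rng))
      # mito share: comfortable for passing cells, > max_mito for plants
      n_mito_expr <- if (mode == "high_mito") n_mito_genes
      else min(n_mito_genes, max(1L, round(0.03 * n_expr)))
      n_mito_expr <- min(n_mito_expr, n_expr)
      g <- c(sample(seq_len(n_mito_genes), n_mito_expr),
             sample(non_mito, n_expr - n_mito_expr))
      cnt <- rpois(n_expr, 2) + 1L
      if (mode == "high_mito") {
        tot_other <- sum(cnt[-seq_len(n_mito_expr)])
        # lift mito counts to a 30-60% fraction (strictly > 25%)
        target <- runif(1, 0.30, 0.60)
        need <- ceiling(target / (1 - target) * tot_other)
        cnt[seq_len(n_mito_expr)] <-
          stats::rmultinom(1, need, rep(1, n_mito_expr))[, 1] + 1L
      }
      ii[[j]] <- g; jj[[j]] <- rep(j, n_expr); xx[[j]] <- cnt
    }
    m <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                              x = unlist(xx), dims = c(n_genes, n_cells),
                              dimnames = list(genes, barcodes))
    truth <- data.frame(barcode = barcodes, planted = mode_per_cell,
                        survive = mode_per_cell == "none")
    list(matrix = m, truth = truth)
  })
}
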