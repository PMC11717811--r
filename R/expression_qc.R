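#' Cell-level quality-control gate
#'
#' Excludes cells expressing fewer than `min_features` or more than
#' `max_features` unique features, or with greater than `max_mito`
#' mitochondrial fraction. All three exclusions are strict, so cells at
#' exactly 200 features, exactly 5000 features, or exactly 25% mitochondrial
#' content are kept.
#'
#' @param m genes-by-cells count matrix (dense or `Matrix` sparse) with
#'   gene and cell names.
#' @param min_features,max_features detected-feature bounds (defaults
#'   200 / 5000).
#' @param max_mito maximum mitochondrial count fraction (default 0.25).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (default `"mt-"`).
#' @return List: `matrix` (surviving cells), `report` (per-cell barcode,
#'   n_features, total_counts, mito_frac, one logical column per failure
#'   mode, `keep`), `summary` (counts per failure mode). Errors if no cell
#'   survives.
#' @export
qc_filter <- function(m, min_features = 200L, max_features = 5000L,
                      max_mito = 0.25, mito_prefix = "mt-") {
  m <- as_count_matrix_(m)
  if (ncol(m) == 0L || nrow(m) == 0L)
    stop("`m` must be non-empty", call. = FALSE)
  n_features <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  is_mito <- startsWith(rownames(m), mito_prefix)
  mito <- if (any(is_mito)) Matrix::colSums(m[is_mito, , drop = FALSE])
  else numeric(ncol(m))
  mito_frac <- ifelse(total > 0, mito / total, 0)
  low <- n_features < min_features
  high <- n_features > max_features
  himito <- mito_frac > max_mito
  keep <- !(low | high | himito)
  if (!any(keep))
    stop("no cells survive QC", call. = FALSE)
  report <- data.frame(barcode = colnames(m), n_features = n_features,
                       total_counts = as.numeric(total),
                       mito_frac = mito_frac,
                       low_features = low, high_features = high,
                       high_mito = himito, keep = keep,
                       row.names = NULL)
  list(matrix = m[, keep, drop = FALSE], report = report,
       summary = c(n_input = ncol(m), n_kept = sum(keep),
                   low_features = sum(low), high_features = sum(high),
                   high_mito = sum(himito)))
}

#' Library-size log-normalization
#'
#' Divides each cell's counts by its total, scales by `scale_factor`
#' (default 10,000) and log-transforms with a pseudocount of one:
#' `x = ln(1 + count / total * scale_factor)`. Per cell the identity
#' `sum(exp(x) - 1) = scale_factor` holds exactly.
#'
#' @param m genes-by-cells count matrix; every cell total must be > 0
#'   (apply [qc_filter()] first).
#' @param scale_factor scaling factor (default 1e4).
#' @return Matrix of the same class and shape with normalized log values.
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  check_number_(scale_factor, "scale_factor", lower = 0, strict_lower = TRUE)
  m <- as_count_matrix_(m)
  total <- Matrix::colSums(m)
  if (any(total <= 0)) {
    bad <- colnames(m)[which(total <= 0)[1]]
    stop(sprintf("cell '%s' has zero total count; run qc_filter first",
                 bad), call. = FALSE)
  }
  if (is(m, "sparseMatrix")) {
    m <- as(m, "CsparseMatrix")
    per_col <- diff(m@p)
    m@x <- log1p(m@x / rep.int(total, per_col) * scale_factor)
    m
  } else {
    log1p(sweep(m, 2L, total, "/") * scale_factor)
  }
}

#' Per-cluster marker statistics
#'
#' For each gene, compares the target cluster against all other cells:
#' log2 fold-difference `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`
#' on the de-logged normalized values, the fraction of expressing cells in
#' and out of the cluster, a two-sided Wilcoxon rank-sum p-value (exact for
#' small tie-free groups, normal approximation otherwise), and a Bonferroni
#' adjustment `min(1, p * n_genes)`. A gene with identical values everywhere
#' gets p = 1 rather than an error.
#'
#' @param normed log-normalized matrix from [lognormalize()].
#' @param clusters cluster label per cell (length `ncol(normed)`).
#' @param target the cluster to characterize.
#' @return data.frame (one row per gene): `gene`, `log2_fc`, `pct_in`,
#'   `pct_out`, `p`, `p_adj`, ordered as in the input matrix.
#' @export
marker_stats <- function(normed, clusters, target) {
  normed <- as_count_matrix_(normed, integer_ok = FALSE)
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(normed))
    stop("`clusters` must have one label per cell", call. = FALSE)
  if (length(unique(clusters)) < 2L)
    stop("need at least 2 clusters", call. = FALSE)
  target <- as.character(target)
  if (!(target %in% clusters))
    stop(sprintf("cluster '%s' not present", target), call. = FALSE)
  in_cl <- clusters == target
  if (sum(in_cl) < 2L || sum(!in_cl) < 2L)
    stop("each side of the comparison needs >= 2 cells", call. = FALSE)
  dm <- as.matrix(normed)
  n_genes <- nrow(dm)
  p <- log2fc <- pct_in <- pct_out <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    xi <- dm[g, in_cl]; xo <- dm[g, !in_cl]
    log2fc[g] <- log2((mean(expm1(xi)) + 1) / (mean(expm1(xo)) + 1))
    pct_in[g] <- mean(xi > 0)
    pct_out[g] <- mean(xo > 0)
    p[g] <- if (var(c(xi, xo)) == 0) 1
    else suppressWarnings(wilcox.test(xi, xo)$p.value)
  }
  data.frame(gene = rownames(dm), log2_fc = log2fc, pct_in = pct_in,
             pct_out = pct_out, p = p, p_adj = pmin(1, p * n_genes),
             row.names = NULL)
}

# internal: validate / coerce a genes-by-cells matrix
as_count_matrix_ <- function(m, integer_ok = TRUE) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!(is.matrix(m) || is(m, "Matrix")))
    stop("expected a matrix or Matrix", call. = FALSE)
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("gene%05d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("cell%04d", seq_len(ncol(m)))
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("gene and cell names must be unique", call. = FALSE)
  if (integer_ok && any(m < 0))
    stop("counts must be non-negative", call. = FALSE)
  m
}
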