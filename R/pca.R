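#' Truncated principal component decomposition
#'
#' Decomposes a gene-centered expression matrix into principal components and
#' keeps at most `max_pcs` of them, ordered by decreasing singular value.
#' Components beyond the numeric rank carry no signal and are never kept.
#' Gene centering makes every score vector sum to zero, so reconstructions
#' from any PC subset stay gene-centered.
#'
#' The decomposition is `X = t(components) %*% diag(singular_values) %*%
#' t(scores)` with `X` the genes x samples matrix, `components` PC x gene
#' loadings (orthonormal rows) and `scores` samples x PC coordinates
#' (orthonormal columns).
#'
#' @param m A centered log2-scale `expr_matrix` (row means ~0).
#' @param max_pcs Maximum number of components to retain (default 1000; the
#'   weaker components past this cutoff are dropped to bound computation).
#' @return An object of class `pc_decomposition` with fields `components`,
#'   `scores`, `singular_values`, `n_kept`, `gene_ids`, `sample_ids`.
#' @export
pca_truncate <- function(m, max_pcs = 1000) {
  stopifnot(inherits(m, "expr_matrix"))
  if (n_samples(m) < 3) stop("need at least 3 samples for PCA", call. = FALSE)
  if (max(abs(rowMeans(m$values))) > 1e-8) {
    stop("matrix is not gene-centered; run center_genes() first", call. = FALSE)
  }
  if (!is.numeric(max_pcs) || max_pcs < 1) {
    stop("`max_pcs` must be a positive integer", call. = FALSE)
  }
  s <- svd(m$values)
  tol <- max(dim(m$values)) * .Machine$double.eps * s$d[1]
  rank <- sum(s$d > tol)
  n_kept <- min(as.integer(max_pcs), rank)
  if (n_kept < 1) stop("matrix has numeric rank 0", call. = FALSE)
  idx <- seq_len(n_kept)
  structure(
    list(
      components = t(s$u[, idx, drop = FALSE]),
      scores = s$v[, idx, drop = FALSE],
      singular_values = s$d[idx],
      n_kept = n_kept,
      gene_ids = gene_ids(m),
      sample_ids = sample_ids(m)
    ),
    class = "pc_decomposition"
  )
}

#' @export
print.pc_decomposition <- function(x, ...) {
  cat(sprintf(
    "<pc_decomposition> %d PCs kept over %d genes x %d samples\n",
    x$n_kept, length(x$gene_ids), length(x$sample_ids)
  ))
  invisible(x)
}

#' Subsample principal components
#'
#' Draws `k = max(1, round(fraction * n_kept))` distinct PC indices uniformly
#' without replacement (e.g. 100 of 1000 kept PCs at the default 10%). Each
#' ensemble repetition examines a different random combination of components.
#' Uses the current RNG state, so results are deterministic under a set seed.
#'
#' @param d A `pc_decomposition`.
#' @param fraction Fraction of kept PCs to draw, in (0, 1].
#' @return Sorted integer vector of selected PC indices.
#' @export
subsample_pcs <- function(d, fraction = 0.1) {
  stopifnot(inherits(d, "pc_decomposition"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  }
  k <- max(1L, as.integer(round(fraction * d$n_kept)))
  if (k >= d$n_kept) return(seq_len(d$n_kept))
  sort(sample.int(d$n_kept, k, replace = FALSE))
}

#' Gene-gene Pearson correlation from a PC subset
#'
#' Reconstructs each gene's profile from the selected components only
#' (`loading * singular value * score`, summed over the subset) and returns
#' the Pearson correlation between the reconstructed profiles. Selecting all
#' kept PCs of a full-rank decomposition reproduces the ordinary Pearson
#' correlation of the input matrix.
#'
#' A gene whose reconstruction has zero variance under the subset has no
#' defined correlation; its row and column are set to `NA` and the gene ids
#' are attached as attribute `"degenerate"` with a warning.
#'
#' @param d A `pc_decomposition`.
#' @param selected Non-empty integer vector of kept-PC indices.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_from_pcs <- function(d, selected) {
  stopifnot(inherits(d, "pc_decomposition"))
  selected <- as.integer(selected)
  if (length(selected) == 0 || anyDuplicated(selected) ||
      any(selected < 1L | selected > d$n_kept)) {
    stop("`selected` must be distinct indices of kept PCs", call. = FALSE)
  }
  loadings <- t(d$components[selected, , drop = FALSE])   # genes x k
  recon <- loadings %*% (d$singular_values[selected] *
    t(d$scores[, selected, drop = FALSE]))                # genes x samples
  sds <- apply(recon, 1L, stats::sd)
  degenerate <- sds == 0
  corr <- suppressWarnings(stats::cor(t(recon)))
  if (any(degenerate)) {
    corr[degenerate, ] <- NA_real_
    corr[, degenerate] <- NA_real_
    warning(sprintf(
      "%d gene(s) have zero variance under the selected PCs; correlations flagged NA",
      sum(degenerate)
    ), call. = FALSE)
  }
  diag(corr) <- 1
  dimnames(corr) <- list(d$gene_ids, d$gene_ids)
  attr(corr, "degenerate") <- d$gene_ids[degenerate]
  corr
}
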