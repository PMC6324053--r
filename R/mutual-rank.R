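#' Mutual Rank from a correlation matrix
#'
#' For each ordered gene pair (a, b), `rank(a -> b)` is the 1-based position
#' of b when all other genes are sorted by descending correlation with a
#' (self excluded; ties get average ranks, so ranks may be fractional). The
#' Mutual Rank is the geometric mean `sqrt(rank(a->b) * rank(b->a))` — a
#' symmetric coexpression strength where smaller values mean stronger
#' coexpression and the best reciprocal pair scores exactly 1. Ranking on the
#' rank scale rather than raw correlation evens out per-gene differences in
#' correlation distributions.
#'
#' `NA` correlations (degenerate genes under a PC subset) propagate: pairs
#' involving such genes get `NA` Mutual Rank and other genes are ranked among
#' the valid correlates only.
#'
#' @param corr Symmetric correlation matrix with unit diagonal, >= 3 genes.
#' @return Symmetric Mutual Rank matrix; off-diagonal values in
#'   `[1, n_genes - 1]`; the diagonal holds the sentinel 0 ("self", excluded
#'   from every statistic).
#' @export
mutual_rank <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop("`corr` must be a square matrix", call. = FALSE)
  }
  n <- nrow(corr)
  if (n < 3) stop("Mutual Rank needs at least 3 genes", call. = FALSE)
  finite <- !is.na(corr)
  if (!isTRUE(all.equal(corr[finite], t(corr)[finite], tolerance = 1e-8))) {
    stop("`corr` must be symmetric", call. = FALSE)
  }
  x <- corr
  diag(x) <- Inf  # self always outranks; subtracting 1 yields ranks among others
  ranks <- t(apply(x, 1L, function(r) {
    rank(-r, ties.method = "average", na.last = "keep")
  })) - 1
  mr <- sqrt(ranks * t(ranks))
  diag(mr) <- 0
  dimnames(mr) <- dimnames(corr)
  mr
}

# Affine rank-to-probability map used for logit-space averaging.
# With the half-rank continuity shift the attainable MR range [1, n-1] maps
# strictly inside (0, 1), so the logit is finite and aggregation of identical
# matrices is an exact fixed point. shift = 0 reproduces the plain
# (MR-1)/(n-2) map and then requires epsilon clipping.
.mr_to_p <- function(mr, n_genes, shift) {
  (mr - 1 + shift) / (n_genes - 2 + 2 * shift)
}

.p_to_mr <- function(p, n_genes, shift) {
  1 - shift + p * (n_genes - 2 + 2 * shift)
}

.mr_to_logit <- function(mr, n_genes, shift) {
  p <- .mr_to_p(mr, n_genes, shift)
  if (shift <= 0) {
    eps <- 1 / (2 * (n_genes - 2))
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  stats::qlogis(p)
}

.logit_to_mr <- function(l, n_genes, shift) {
  .p_to_mr(stats::plogis(l), n_genes, shift)
}

#' Aggregate an ensemble of Mutual Rank matrices
#'
#' Each MR value is mapped to a probability-scale value
#' `p = (MR - 1 + shift) / (n_genes - 2 + 2 * shift)`, logit-transformed,
#' averaged entrywise across repetitions, inverse-logit transformed and mapped
#' back to the MR scale. The default half-rank `shift = 0.5` keeps the whole
#' attainable MR range strictly inside (0, 1), so no clipping is needed and an
#' ensemble of identical matrices aggregates to itself exactly; with
#' `shift = 0` the plain `(MR-1)/(n_genes-2)` map is used and boundary values
#' are clipped to `[eps, 1-eps]`, `eps = 1/(2(n_genes-2))`.
#'
#' `NA` entries (pairs degenerate in a repetition) are averaged over the
#' non-missing repetitions only.
#'
#' @param mr_list Non-empty list of MR matrices sharing gene set and order.
#' @param n_genes Number of genes defining the MR scale (defaults to the
#'   matrix dimension).
#' @param shift Continuity shift of the rank-to-probability map (default 0.5).
#' @return Aggregated symmetric MR matrix, diagonal sentinel 0.
#' @export
aggregate_mr <- function(mr_list, n_genes = NULL, shift = 0.5) {
  if (!is.list(mr_list) || length(mr_list) == 0) {
    stop("`mr_list` must be a non-empty list of MR matrices", call. = FALSE)
  }
  dims <- vapply(mr_list, function(m) dim(m), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1 ||
      dims[1, 1] != dims[2, 1]) {
    stop("all MR matrices must be square with identical shape", call. = FALSE)
  }
  if (is.null(n_genes)) n_genes <- dims[1, 1]
  acc <- matrix(0, n_genes, n_genes)
  cnt <- matrix(0L, n_genes, n_genes)
  for (mr in mr_list) {
    mr <- as.matrix(mr)
    diag(mr) <- NA_real_  # self sentinel never enters the average
    l <- .mr_to_logit(mr, n_genes, shift)
    ok <- !is.na(l)
    acc[ok] <- acc[ok] + l[ok]
    cnt <- cnt + ok
  }
  avg <- acc / cnt  # entries never observed become NaN -> NA
  avg[cnt == 0L] <- NA_real_
  out <- .logit_to_mr(avg, n_genes, shift)
  diag(out) <- 0
  dimnames(out) <- dimnames(mr_list[[1]])
  out
}
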