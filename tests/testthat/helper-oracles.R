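# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can serve as ground truth.

# O(n^2 log n) Mutual Rank by explicit per-gene sorting.
oracle_mutual_rank <- function(corr) {
  n <- nrow(corr)
  ranks <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) {
    others <- setdiff(seq_len(n), a)
    v <- corr[a, others]
    r <- rank(-v, ties.method = "average")
    ranks[a, others] <- r
  }
  mr <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b) mr[a, b] <- sqrt(ranks[a, b] * ranks[b, a])
    }
  }
  dimnames(mr) <- dimnames(corr)
  mr
}

# Scalar-chain logit aggregation: map, clip-free half-rank shift, logit,
# mean, back — computed entry by entry.
oracle_aggregate <- function(mr_list, n_genes, shift = 0.5) {
  out <- mr_list[[1]]
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      if (i == j) { out[i, j] <- 0; next }
      ps <- vapply(mr_list, function(m) {
        (m[i, j] - 1 + shift) / (n_genes - 2 + 2 * shift)
      }, 0)
      pbar <- stats::plogis(mean(stats::qlogis(ps)))
      out[i, j] <- 1 - shift + pbar * (n_genes - 2 + 2 * shift)
    }
  }
  out
}

# A random valid correlation matrix of n genes (positive definite, unit diag).
random_corr <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n * (n + 5)), n)
  stats::cor(t(x))
}

# Small centered log2-scale expression matrix.
random_centered <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
    dimnames = list(sprintf("g%03d", seq_len(n_genes)),
      sprintf("s%03d", seq_len(n_samples))))
  center_genes(expression_matrix(x, scale = "log2"))
}

# Naive complete-linkage agglomeration over a distance matrix; returns the
# sorted merge heights.
oracle_complete_linkage_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Spearman rank correlation from first principles (average ranks + Pearson).
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Desk-scale depth threshold for synthetic panels: the production threshold
# (2e6 counts over a ~20k-gene transcriptome, i.e. ~100 counts per gene)
# scaled to the panel's gene count.
panel_depth_threshold <- function(n_genes) 100 * n_genes
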