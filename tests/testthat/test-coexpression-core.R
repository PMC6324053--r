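test_that("pca_truncate finds the planted rank and matches a full SVD", {
  # rank-2 matrix: two orthogonal sample patterns, no noise
  s1 <- rep(c(1, -1), 10)
  s2 <- rep(c(1, 1, -1, -1), 5)
  x <- rbind(outer(c(1, 2, 3), s1), outer(c(1, -1), s2))
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:20)
  m <- center_genes(expression_matrix(x, scale = "log2"))
  d <- pca_truncate(m, max_pcs = 10)
  expect_equal(d$n_kept, 2)  # capped at the numeric rank
  expect_true(all(diff(d$singular_values) <= 0))

  m2 <- random_centered(50, 30, seed = 11)
  d2 <- pca_truncate(m2, max_pcs = 10)
  expect_equal(d2$n_kept, 10)
  full <- svd(m2$values)  # independent full decomposition
  expect_equal(d2$singular_values, full$d[1:10], tolerance = 1e-10)
  # orthonormal component rows
  expect_equal(tcrossprod(d2$components), diag(10), tolerance = 1e-8)
  expect_error(pca_truncate(random_centered(5, 3, 1), max_pcs = 0), "positive")
})

test_that("pca_truncate requires >= 3 samples and a centered matrix", {
  x <- matrix(rnorm(10), 5, 2,
    dimnames = list(paste0("g", 1:5), paste0("s", 1:2)))
  expect_error(pca_truncate(expression_matrix(x, scale = "log2")),
    "3 samples")
  y <- matrix(rnorm(20) + 5, 4, 5,
    dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  expect_error(pca_truncate(expression_matrix(y, scale = "log2")),
    "centered")
})

test_that("subsample_pcs draws round(fraction * n_kept) distinct indices", {
  d <- structure(list(n_kept = 1000L), class = "pc_decomposition")
  set.seed(1)
  sel <- subsample_pcs(d, 0.1)
  expect_length(sel, 100)            # 100 of 1000 at 10%
  expect_false(anyDuplicated(sel) > 0)
  expect_true(all(sel >= 1 & sel <= 1000))

  d20 <- structure(list(n_kept = 20L), class = "pc_decomposition")
  expect_identical(subsample_pcs(d20, 1), 1:20)   # fraction 1: everything
  set.seed(2)
  expect_length(subsample_pcs(d20, 0.001), 1)     # floor at one PC
  expect_error(subsample_pcs(d20, 0), "fraction")
})

test_that("subsampling is uniform over PCs", {
  d <- structure(list(n_kept = 20L), class = "pc_decomposition")
  set.seed(123)
  counts <- integer(20)
  n_draws <- 10000
  for (i in seq_len(n_draws)) {
    sel <- subsample_pcs(d, 0.1)  # 2 of 20 per draw
    counts[sel] <- counts[sel] + 1L
  }
  p_hat <- counts / n_draws
  se <- sqrt(0.1 * 0.9 / n_draws)
  expect_true(all(abs(p_hat - 0.1) < 3 * se * sqrt(2)))
})

test_that("correlation from all PCs equals plain Pearson correlation", {
  m <- random_centered(25, 15, seed = 21)
  d <- pca_truncate(m, max_pcs = 1000)
  corr <- correlation_from_pcs(d, seq_len(d$n_kept))
  expect_equal(unname(unclass(corr))[1:25, 1:25],
    unname(stats::cor(t(m$values))), tolerance = 1e-8)
  expect_equal(diag(corr), setNames(rep(1, 25), gene_ids(m)))
})

test_that("correlation from a PC subset matches reconstruct-then-correlate", {
  m <- random_centered(20, 12, seed = 22)
  d <- pca_truncate(m, max_pcs = 1000)
  sel <- c(1L, 2L, 3L)
  corr <- correlation_from_pcs(d, sel)
  # explicit reconstruction oracle
  recon <- t(d$components[sel, ]) %*% diag(d$singular_values[sel]) %*%
    t(d$scores[, sel])
  expect_equal(unname(unclass(corr)), unname(stats::cor(t(recon))),
    tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(abs(corr) <= 1 + 1e-12))
  expect_error(correlation_from_pcs(d, integer(0)), "distinct")
})

test_that("genes loading on a single selected PC correlate at +/-1", {
  # two patterns: g1,g2 follow PC1 with same/opposite sign
  s <- seq(-1, 1, length.out = 10)
  x <- rbind(g1 = 2 * s, g2 = -3 * s, g3 = rep(c(1, -1), 5))
  colnames(x) <- paste0("s", 1:10)
  d <- pca_truncate(center_genes(expression_matrix(x, scale = "log2")))
  corr <- correlation_from_pcs(d, 1L)
  expect_equal(abs(corr["g1", "g2"]), 1, tolerance = 1e-8)
})

test_that("mutual_rank matches the brute-force oracle on random matrices", {
  for (seed in 1:50) {
    n <- sample(12:30, 1)
    corr <- random_corr(n, seed)
    expect_equal(mutual_rank(corr), oracle_mutual_rank(corr),
      tolerance = 1e-12)
  }
})

test_that("mutual_rank identities: reciprocal best pair and rank arithmetic", {
  # construct: g1/g2 mutual best, plus fillers
  corr <- diag(4)
  corr[1, 2] <- corr[2, 1] <- 0.95
  corr[1, 3] <- corr[3, 1] <- 0.5
  corr[2, 3] <- corr[3, 2] <- 0.4
  corr[1, 4] <- corr[4, 1] <- 0.2
  corr[2, 4] <- corr[4, 2] <- 0.1
  corr[3, 4] <- corr[4, 3] <- 0.3
  mr <- mutual_rank(corr)
  expect_equal(mr[1, 2], 1)                    # sqrt(1 * 1)
  expect_equal(sqrt(2 * 8), 4)                 # geometric-mean arithmetic
  expect_equal(mr, t(mr))
  expect_equal(diag(mr), rep(0, 4))            # self sentinel
  off <- mr[upper.tri(mr)]
  expect_true(all(off >= 1 & off <= 3))        # 1 <= MR <= n - 1
  expect_error(mutual_rank(diag(2)), "3 genes")
})

test_that("aggregate_mr matches the scalar logit-chain oracle", {
  set.seed(33)
  n <- 10
  mr_list <- lapply(1:5, function(i) mutual_rank(random_corr(n, 100 + i)))
  agg <- aggregate_mr(mr_list)
  expect_equal(agg, oracle_aggregate(mr_list, n), tolerance = 1e-10)
  expect_equal(agg, t(agg))
})

test_that("aggregation fixed point and logit symmetry", {
  mr <- mutual_rank(random_corr(12, 7))
  agg <- aggregate_mr(list(mr, mr, mr))
  expect_equal(agg, mr, tolerance = 1e-8)  # identical ensembles are fixed

  # p-values 0.2 and 0.8 average to 0.5 -> midpoint of the MR scale
  n <- 12; shift <- 0.5; denom <- n - 2 + 2 * shift
  mr_at <- function(p) {
    m <- matrix(1 - shift + p * denom, n, n); diag(m) <- 0; m
  }
  agg2 <- aggregate_mr(list(mr_at(0.2), mr_at(0.8)), n_genes = n)
  expect_equal(agg2[1, 2], 1 - shift + 0.5 * denom, tolerance = 1e-10)
  expect_error(aggregate_mr(list(mr, mr[1:5, 1:5])), "shape")
})

test_that("aggregate_mr averages missing entries over non-missing reps", {
  mr1 <- mutual_rank(random_corr(8, 1))
  mr2 <- mr1
  mr2[1, 2] <- mr2[2, 1] <- NA
  agg <- aggregate_mr(list(mr1, mr2))
  expect_equal(agg[1, 2], mr1[1, 2], tolerance = 1e-10)
  expect_equal(agg[3, 4], mr1[3, 4], tolerance = 1e-10)
})

test_that("plain map (shift = 0) applies epsilon clipping", {
  n <- 12
  mr <- mutual_rank(random_corr(n, 9))
  agg <- aggregate_mr(list(mr), shift = 0)
  eps <- 1 / (2 * (n - 2))
  off <- agg[upper.tri(agg)]
  expect_true(all(off >= 1 + eps * (n - 2) - 1e-9))
  interior <- mr[upper.tri(mr)] > 1.5 & mr[upper.tri(mr)] < n - 1.5
  expect_equal(off[interior], mr[upper.tri(mr)][interior], tolerance = 1e-8)
})

test_that("degenerate ensemble (fraction 1, one rep) collapses to Pearson-MR", {
  m <- random_centered(30, 18, seed = 51)
  pl <- suppressWarnings(build_platform(m, max_pcs = 1000, fraction = 1,
    n_repetitions = 1, seed = 5))
  classic <- mutual_rank(stats::cor(t(m$values)))
  expect_equal(pl$mr, classic, tolerance = 1e-8)
})

test_that("build_platform is deterministic in its seed", {
  m <- random_centered(20, 15, seed = 61)
  p1 <- build_platform(m, max_pcs = 10, fraction = 0.4, n_repetitions = 8,
    seed = 99)
  p2 <- build_platform(m, max_pcs = 10, fraction = 0.4, n_repetitions = 8,
    seed = 99)
  p3 <- build_platform(m, max_pcs = 10, fraction = 0.4, n_repetitions = 8,
    seed = 100)
  expect_identical(p1$mr, p2$mr)
  expect_false(identical(p1$mr, p3$mr))
  expect_error(build_platform(m, n_repetitions = 0), "n_repetitions")
})

test_that("platform recovers planted modules and MR bounds hold", {
  spec <- module_spec(n_modules = 2, genes_per_module = 10,
    background_genes = 30, n_samples = 40, within_corr = 0.8, seed = 71)
  m <- preprocess_expression(simulate_expression(spec))
  pl <- build_platform(m, max_pcs = 40, fraction = 0.3, n_repetitions = 50,
    seed = 8)
  mods <- module_members(spec)
  within <- unlist(lapply(mods, function(g) {
    sm <- pl$mr[g, g]; sm[upper.tri(sm)]
  }))
  between <- pl$mr[mods[[1]], mods[[2]]]
  expect_lt(median(within), median(between))
  wt <- stats::wilcox.test(within, as.vector(between),
    alternative = "less")
  expect_lt(wt$p.value, 0.01)
  off <- pl$mr[upper.tri(pl$mr)]
  expect_true(all(off >= 1 - 1e-9 & off <= n_genes(m) - 1 + 1e-9))
})

test_that("stronger planted signal monotonically strengthens within-module MR", {
  means <- vapply(c(0.3, 0.6, 0.9), function(wc) {
    spec <- module_spec(n_modules = 2, genes_per_module = 8,
      background_genes = 20, n_samples = 40, within_corr = wc, seed = 81)
    m <- preprocess_expression(simulate_expression(spec))
    pl <- build_platform(m, max_pcs = 30, fraction = 0.5,
      n_repetitions = 20, seed = 4)
    mods <- module_members(spec)
    mean(unlist(lapply(mods, function(g) {
      sm <- pl$mr[g, g]; sm[upper.tri(sm)]
    })))
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("platform MR table round-trips through long TSV", {
  m <- random_centered(12, 10, seed = 91)
  pl <- build_platform(m, max_pcs = 8, fraction = 0.5, n_repetitions = 3,
    seed = 2)
  df <- tidy(pl)
  expect_equal(nrow(df), 12 * 11 / 2)
  expect_true(all(df$gene_a < df$gene_b))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_platform_tsv(pl, path)
  back <- read_platform_tsv(path)
  expect_equal(back$mr[pl$gene_ids, pl$gene_ids], pl$mr, tolerance = 1e-12)
})
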