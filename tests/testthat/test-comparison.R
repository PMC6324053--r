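# platforms over renamed copies of one id set, with identity ortholog maps
family_fixture <- function(n_modules = 3, shared_fraction = 1, seed = 101,
                           n_platforms = 2, reps = 10, fraction = 0.5,
                           genes_per_module = 10, background_genes = 30,
                           n_samples = 40) {
  spec <- module_spec(n_modules = n_modules,
    genes_per_module = genes_per_module,
    background_genes = background_genes, n_samples = n_samples, seed = seed)
  fam <- generate_platform_family(spec, n_platforms, shared_fraction)
  fam$platforms <- lapply(fam$expressions, function(e) {
    build_platform(center_genes(e), max_pcs = 40, fraction = fraction,
      n_repetitions = reps, seed = seed + 1)
  })
  fam
}

test_that("ortholog maps enforce one-to-one correspondence and round-trip", {
  expect_error(ortholog_map(data.frame(a = c("x", "x"), b = c("u", "v"))),
    "one-to-one")
  map <- ortholog_map(data.frame(a = c("x", "y"), b = c("u", "v")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_tsv(map, path)
  expect_equal(as.data.frame(read_ortholog_tsv(path)), as.data.frame(map))
})

test_that("common_pair_scores yields g(g-1)/2 pairs over the common genes", {
  fam <- family_fixture()
  tab <- common_pair_scores(fam$platforms, fam$maps)
  g <- length(fam$platforms[[1]]$gene_ids)
  expect_equal(nrow(tab), g * (g - 1) / 2)
  expect_true(all(tab$gene_a < tab$gene_b))

  # 180 common genes -> 16 110 pairs
  mr <- matrix(2, 180, 180,
    dimnames = list(sprintf("c%03d", 1:180), sprintf("c%03d", 1:180)))
  diag(mr) <- 0
  tab180 <- common_pair_scores(list(only = coex_platform(mr)), list())
  expect_equal(nrow(tab180), 16110)

  # restriction to a planted common core, against exhaustive enumeration
  keep <- fam$platforms[[2]]$gene_ids[1:10]
  sub2 <- coex_platform(fam$platforms[[2]]$mr[keep, keep])
  tab2 <- common_pair_scores(list(a = fam$platforms[[1]], b = sub2),
    fam$maps)
  common <- fam$maps[[1]]$gene_a[fam$maps[[1]]$gene_b %in% keep]
  expect_equal(nrow(tab2), choose(length(common), 2))
  expect_setequal(unique(c(tab2$gene_a, tab2$gene_b)), common)
  # MR columns are the platforms' values at the translated ids
  i <- 7
  expect_equal(tab2$a[i],
    fam$platforms[[1]]$mr[tab2$gene_a[i], tab2$gene_b[i]])
})

test_that("platform_similarity is rank-invariant with unit diagonal", {
  fam <- family_fixture()
  tab <- common_pair_scores(fam$platforms, fam$maps)
  sim <- platform_similarity(tab)
  expect_equal(diag(unclass(sim)), c(P1 = 1, P2 = 1))
  expect_equal(unclass(sim), t(unclass(sim)))
  expect_true(all(abs(sim) <= 1 + 1e-12))

  # strictly monotone transform leaves similarity at exactly 1
  tab2 <- tab
  tab2$P2 <- exp(tab$P1 / 10) + 5
  sim2 <- platform_similarity(tab2)
  expect_equal(sim2["P1", "P2"], 1)

  # agrees with a first-principles rank correlation
  expect_equal(sim["P1", "P2"], oracle_spearman(tab$P1, tab$P2),
    tolerance = 1e-10)
  tab$P2 <- 1
  expect_error(platform_similarity(tab), "constant")
})

test_that("complete-linkage clustering merges planted groups first", {
  sim <- matrix(0.1, 4, 4,
    dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  sim[1, 2] <- sim[2, 1] <- 0.9
  sim[3, 4] <- sim[4, 3] <- 0.9
  diag(sim) <- 1
  hc <- cluster_platforms(structure(sim, class = c("coex_similarity",
    "matrix")))
  first_two <- vapply(1:2, function(i) {
    paste(sort(abs(hc$merge[i, ])), collapse = "-")
  }, "")
  expect_setequal(first_two, c("1-2", "3-4"))
  expect_equal(hc$height[1:2], c(0.1, 0.1))
  nwk <- platform_newick(hc)
  expect_match(nwk, "^\\(.*\\);$")

  # identical platforms merge at distance 0
  sim2 <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc2 <- cluster_platforms(sim2)
  expect_equal(hc2$height, 0)

  # merge heights match an independent naive agglomeration
  set.seed(8)
  r <- matrix(runif(36, -0.5, 0.9), 6)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(paste0("q", 1:6), paste0("q", 1:6))
  hc3 <- cluster_platforms(r)
  expect_equal(sort(hc3$height),
    sort(oracle_complete_linkage_heights(1 - r)), tolerance = 1e-12)
})

test_that("coxsim_top1 extremes, symmetry and manual formula", {
  universe <- sprintf("u%03d", 1:500)
  la <- universe
  expect_equal(coxsim_top1(la, la, 0.01), 1)            # identical lists
  lb <- rev(universe)
  expect_equal(coxsim_top1(la, lb, 0.01), 0)            # disjoint top-5
  # top-5 overlap of 3 genes at hand-picked ranks
  lb2 <- c(la[3], la[10], la[1], la[5], la[20],
    setdiff(universe, c(la[3], la[10], la[1], la[5], la[20])))
  w <- function(r) 1 / log2(r + 1)
  manual <- (w(1) * w(3) + w(3) * w(1) + w(5) * w(4)) / sum(w(1:5)^2)
  expect_equal(coxsim_top1(la, lb2, 0.01), manual, tolerance = 1e-12)
  expect_equal(coxsim_top1(lb2, la, 0.01), coxsim_top1(la, lb2, 0.01))
  expect_error(coxsim_top1(la[1:50], lb[1:50], 0.01), "universe")
  # bounded in [0, 1] over random rankings
  set.seed(12)
  for (i in 1:20) {
    v <- coxsim_top1(sample(universe), sample(universe), 0.01)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("quartile levels partition distinct values 25/25/25/25", {
  set.seed(13)
  x <- runif(100)
  lv <- assign_support_levels(x)
  expect_equal(unname(table(lv)), array(c(25L, 25L, 25L, 25L)))
  expect_identical(sort(unique(lv)), 0:3)
  # boundary ties go to the lower level
  y <- c(rep(0.25, 30), seq(0.3, 1, length.out = 70))
  q1 <- stats::quantile(y, 0.25, names = FALSE)
  expect_true(all(assign_support_levels(y)[y == q1] == 0))
  expect_true(all(is.na(assign_support_levels(c(NA, 1, 2, 3, 4))[1])))
})

test_that("supportability against an exact copy yields maxCOXSIM 1", {
  fam <- family_fixture(n_platforms = 1)
  pl <- fam$platforms[[1]]
  map <- ortholog_map(data.frame(a = pl$gene_ids, b = pl$gene_ids))
  rep <- supportability(pl, list(self = pl), list(map), top_fraction = 0.1)
  expect_equal(rep$max_coxsim, rep(1, length(pl$gene_ids)))
  expect_true(all(rep$best_reference == "self"))
})

test_that("guides without orthologs are flagged and excluded from quartiles", {
  fam <- family_fixture()
  pl <- fam$platforms[[1]]
  map <- fam$maps[[1]]
  map_partial <- ortholog_map(as.data.frame(map[1:40, ]))
  rep <- supportability(pl, list(r = fam$platforms[[2]]), list(map_partial),
    top_fraction = 0.1)
  unmapped <- setdiff(pl$gene_ids, map_partial$gene_a)
  expect_true(all(is.na(rep$max_coxsim[rep$guide_gene %in% unmapped])))
  expect_true(all(is.na(rep$level[rep$guide_gene %in% unmapped])))
  mapped <- rep[!is.na(rep$max_coxsim), ]
  expect_identical(mapped$level, assign_support_levels(mapped$max_coxsim))
})

test_that("genes in shared modules earn higher maxCOXSIM than unshared ones", {
  fam <- family_fixture(n_modules = 4, shared_fraction = 0.5, seed = 131,
    reps = 15, n_samples = 60)
  rep <- supportability(fam$platforms[[1]], fam$platforms[-1], fam$maps,
    top_fraction = 0.05)
  shared_genes <- unlist(fam$shared_modules)
  in_shared <- rep$guide_gene %in% shared_genes
  # unshared-module genes: members of platform 1's private modules are not
  # identifiable from the fixture, so compare shared-module genes against all
  # other guides
  wt <- stats::wilcox.test(rep$max_coxsim[in_shared],
    rep$max_coxsim[!in_shared], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("mean supportability rises with the shared-module fraction", {
  means <- vapply(c(0, 0.5, 1), function(sf) {
    fam <- family_fixture(n_modules = 4, shared_fraction = sf, seed = 141,
      reps = 15, n_samples = 60)
    rep <- supportability(fam$platforms[[1]], fam$platforms[-1], fam$maps,
      top_fraction = 0.05)
    mean(rep$max_coxsim, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("family similarity is ordered by shared fraction", {
  sims <- vapply(c(0, 1), function(sf) {
    fam <- family_fixture(n_modules = 4, shared_fraction = sf, seed = 151,
      reps = 15, n_samples = 60)
    platform_similarity(common_pair_scores(fam$platforms,
      fam$maps))["P1", "P2"]
  }, 0)
  expect_lt(sims[1], sims[2])
})
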