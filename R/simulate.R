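#' Specification of a synthetic coexpression dataset
#'
#' Describes a planted-module expression dataset: `n_modules` blocks of
#' `genes_per_module` genes driven by a shared latent factor (so their
#' expected pairwise Pearson correlation is `within_corr`), plus independent
#' background genes. The generator is a latent-factor Gaussian model on the
#' log2 scale with an optional Poisson count layer — enough structure to
#' exercise correlation, Mutual Rank and the downstream statistics, not a
#' full RNA-seq noise model.
#'
#' @param n_modules Number of planted coexpression modules (default 5).
#' @param genes_per_module Genes per module (default 10).
#' @param within_corr Target within-module Pearson correlation, strictly in
#'   (0, 1) (default 0.8).
#' @param background_genes Independent genes outside any module (default 50).
#' @param n_samples Number of samples, >= 3 (default 50).
#' @param noise_sd Per-gene noise standard deviation on the log2 scale
#'   (default 1).
#' @param seed Master seed (default 1).
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(n_modules = 5, genes_per_module = 10,
                        within_corr = 0.8, background_genes = 50,
                        n_samples = 50, noise_sd = 1, seed = 1) {
  if (within_corr <= 0 || within_corr >= 1) {
    stop("`within_corr` must be strictly between 0 and 1", call. = FALSE)
  }
  if (n_samples < 3) stop("need at least 3 samples", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  structure(
    list(n_modules = as.integer(n_modules),
      genes_per_module = as.integer(genes_per_module),
      within_corr = within_corr,
      background_genes = as.integer(background_genes),
      n_samples = as.integer(n_samples),
      noise_sd = noise_sd, seed = as.integer(seed)),
    class = "module_spec"
  )
}

# Gene ids g0001..; modules occupy the leading blocks.
.spec_gene_ids <- function(spec) {
  n <- spec$n_modules * spec$genes_per_module + spec$background_genes
  sprintf("g%04d", seq_len(n))
}

#' Module membership implied by a spec
#'
#' @param spec A `module_spec`.
#' @return Named list: module id -> member gene ids (background genes belong
#'   to no module).
#' @export
module_members <- function(spec) {
  ids <- .spec_gene_ids(spec)
  stats::setNames(
    lapply(seq_len(spec$n_modules), function(i) {
      ids[seq((i - 1) * spec$genes_per_module + 1,
        i * spec$genes_per_module)]
    }),
    sprintf("module%02d", seq_len(spec$n_modules))
  )
}

# Core latent-factor sampler on the log2 scale, given explicit membership
# (list of gene-id vectors) over a fixed id set. Module gene profile =
# a * factor + noise, a chosen so cor = within_corr; background genes are
# independent with the same total variance.
.simulate_log2 <- function(ids, members, spec) {
  ns <- spec$n_samples
  a <- spec$noise_sd * sqrt(spec$within_corr / (1 - spec$within_corr))
  total_sd <- sqrt(a^2 + spec$noise_sd^2)
  x <- matrix(stats::rnorm(length(ids) * ns, sd = spec$noise_sd),
    length(ids), ns, dimnames = list(ids, sprintf("s%03d", seq_len(ns))))
  bg <- rep(TRUE, length(ids))
  for (m in members) {
    idx <- match(m, ids)
    factor <- stats::rnorm(ns)
    x[idx, ] <- x[idx, ] + a * rep(factor, each = length(idx))
    bg[idx] <- FALSE
  }
  x[bg, ] <- x[bg, , drop = FALSE] * (total_sd / spec$noise_sd)
  # per-gene baseline so a count layer straddles realistic filter thresholds
  baseline <- stats::rnorm(length(ids), mean = 7, sd = 1.5)
  x + baseline
}

#' Generate a synthetic expression matrix with planted modules
#'
#' Deterministic per seed. On the `"log2"` scale (default) the matrix is the
#' latent-factor model directly; on the `"counts"` scale each log2 value is
#' exponentiated to a Poisson mean and counts are drawn, which adds the
#' sampling noise the preprocessing filters are designed for.
#'
#' @param spec A `module_spec`.
#' @param scale `"log2"` or `"counts"`.
#' @return An `expr_matrix`.
#' @export
simulate_expression <- function(spec, scale = c("log2", "counts")) {
  stopifnot(inherits(spec, "module_spec"))
  scale <- match.arg(scale)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  ids <- .spec_gene_ids(spec)
  x <- .simulate_log2(ids, module_members(spec), spec)
  if (scale == "log2") {
    expression_matrix(x, scale = "log2")
  } else {
    counts <- matrix(stats::rpois(length(x), lambda = 2^as.vector(x)),
      nrow(x), ncol(x), dimnames = dimnames(x))
    expression_matrix(counts * 1.0, scale = "counts")
  }
}

#' Generate a pathway annotation matching the planted modules
#'
#' One pathway per module, containing a `coverage` fraction of its genes
#' (the leading `ceiling(coverage * genes_per_module)` members).
#'
#' @param spec A `module_spec`.
#' @param coverage Fraction of each module annotated, in (0, 1] (default 1).
#' @return A `pathway_annotation`.
#' @export
generate_annotation <- function(spec, coverage = 1) {
  stopifnot(inherits(spec, "module_spec"))
  if (coverage <= 0 || coverage > 1) {
    stop("`coverage` must lie in (0, 1]", call. = FALSE)
  }
  k <- ceiling(coverage * spec$genes_per_module)
  sets <- lapply(module_members(spec), function(m) m[seq_len(k)])
  names(sets) <- sub("^module", "pathway", names(sets))
  pathway_annotation(sets)
}

#' Generate a family of related synthetic platforms
#'
#' Builds `n_platforms` expression matrices over the same underlying gene set:
#' a `shared_fraction` of the modules has identical membership on every
#' platform; the remaining module slots get platform-specific random
#' memberships drawn from the non-shared gene pool. `divergence` additionally
#' swaps that fraction of each shared module's members (on every platform
#' after the first) for random pool genes, emulating partial conservation.
#' Gene identifiers are platform-prefixed renamings of one common id set, and
#' the returned ortholog maps are the corresponding identity correspondences
#' (platform 1 -> platform i).
#'
#' @param spec A `module_spec` (its `n_modules`, sizes, correlation, samples
#'   and noise apply to every platform).
#' @param n_platforms Number of platforms (>= 1).
#' @param shared_fraction Fraction of modules with conserved membership, in
#'   [0, 1].
#' @param divergence Fraction of each shared module's members perturbed on
#'   non-first platforms, in [0, 1) (default 0).
#' @return A list with elements `expressions` (named list of log2-scale
#'   `expr_matrix`), `maps` (list of `ortholog_map`s, platform 1 to each other
#'   platform) and `shared_modules` (membership list, platform-1 id space).
#' @export
generate_platform_family <- function(spec, n_platforms, shared_fraction,
                                     divergence = 0) {
  stopifnot(inherits(spec, "module_spec"), n_platforms >= 1)
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("`shared_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (divergence < 0 || divergence >= 1) {
    stop("`divergence` must lie in [0, 1)", call. = FALSE)
  }
  ids <- .spec_gene_ids(spec)
  members <- module_members(spec)
  n_shared <- round(shared_fraction * spec$n_modules)
  shared_members <- members[seq_len(n_shared)]
  pool <- setdiff(ids, unlist(shared_members))
  seeds <- .spawn_seeds(spec$seed, n_platforms)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  expressions <- list()
  maps <- list()
  for (p in seq_len(n_platforms)) {
    set.seed(seeds[p])
    mem <- shared_members
    if (p > 1 && divergence > 0 && n_shared > 0) {
      n_swap <- round(divergence * spec$genes_per_module)
      for (i in seq_along(mem)) {
        if (n_swap == 0) next
        repl <- sample(pool, n_swap)
        mem[[i]] <- c(mem[[i]][seq_len(spec$genes_per_module - n_swap)], repl)
      }
    }
    # platform-private modules drawn from the pool
    n_private <- spec$n_modules - n_shared
    avail <- setdiff(pool, unlist(mem))
    for (i in seq_len(n_private)) {
      grab <- sample(avail, spec$genes_per_module)
      mem[[paste0("private", p, "_", i)]] <- grab
      avail <- setdiff(avail, grab)
    }
    x <- .simulate_log2(ids, mem, spec)
    pid <- sprintf("P%d", p)
    rownames(x) <- paste0(pid, "_", ids)
    expressions[[pid]] <- expression_matrix(x, scale = "log2")
    if (p > 1) {
      maps[[p - 1L]] <- ortholog_map(data.frame(
        gene_a = paste0("P1_", ids),
        gene_b = paste0(pid, "_", ids)
      ))
    }
  }
  list(expressions = expressions, maps = maps,
    shared_modules = lapply(shared_members, function(m) paste0("P1_", m)))
}
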