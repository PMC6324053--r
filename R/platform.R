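#' Build a coexpression platform
#'
#' The ensemble pipeline producing the final Mutual Rank matrix of one
#' platform (one species x one technology): the centered matrix is decomposed
#' once by PCA (truncated at `max_pcs`); then, `n_repetitions` times, a random
#' `fraction` of the kept PCs is drawn, gene profiles are reconstructed from
#' that subset, Pearson correlation and Mutual Rank are computed; finally the
#' repetition-level MR matrices are averaged in logit space. Subsampling the
#' component space makes the result robust to dominant individual factors in
#' the compendium.
#'
#' A master seed spawns one child seed per repetition, so the result is
#' reproducible and independent of repetition execution order. Repetitions in
#' which some genes are degenerate (zero variance under the drawn subset)
#' contribute to unaffected pairs only.
#'
#' @param m A preprocessed, gene-centered `expr_matrix` (see
#'   [preprocess_expression()]).
#' @param max_pcs PC truncation bound (default 1000).
#' @param fraction Fraction of kept PCs drawn per repetition (default 0.1).
#' @param n_repetitions Number of ensemble repetitions (default 1000; use a
#'   few dozen for desk-scale work).
#' @param seed Master seed controlling all subsampling.
#' @param shift Rank-to-probability continuity shift for the logit
#'   aggregation; see [aggregate_mr()].
#' @param verbose Log one line per repetition.
#' @return An object of class `coex_platform`: fields `gene_ids`, `mr`
#'   (symmetric MR matrix, diagonal sentinel 0), `n_repetitions`,
#'   `subsample_fraction`, `seed`, `params`.
#' @examples
#' m <- simulate_expression(module_spec(n_modules = 2, genes_per_module = 5,
#'   background_genes = 5, n_samples = 20, seed = 1))
#' p <- build_platform(preprocess_expression(m), max_pcs = 10,
#'   fraction = 0.5, n_repetitions = 5, seed = 1)
#' glance(p)
#' @export
build_platform <- function(m, max_pcs = 1000, fraction = 0.1,
                           n_repetitions = 1000, seed = 1, shift = 0.5,
                           verbose = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!is.numeric(n_repetitions) || n_repetitions < 1) {
    stop("`n_repetitions` must be >= 1", call. = FALSE)
  }
  n_repetitions <- as.integer(n_repetitions)
  d <- pca_truncate(m, max_pcs = max_pcs)
  ng <- n_genes(m)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
    globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
    envir = globalenv()))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_repetitions)

  acc <- matrix(0, ng, ng)
  cnt <- matrix(0L, ng, ng)
  n_degenerate <- 0L
  for (i in seq_len(n_repetitions)) {
    set.seed(rep_seeds[i])
    sel <- subsample_pcs(d, fraction)
    corr <- withCallingHandlers(
      correlation_from_pcs(d, sel),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (length(attr(corr, "degenerate"))) n_degenerate <- n_degenerate + 1L
    mr_i <- mutual_rank(corr)
    diag(mr_i) <- NA_real_  # self sentinel never enters the average
    l <- .mr_to_logit(mr_i, ng, shift)
    ok <- !is.na(l)
    acc[ok] <- acc[ok] + l[ok]
    cnt <- cnt + ok
    if (verbose) {
      message(sprintf("repetition %d/%d: %d PCs", i, n_repetitions,
        length(sel)))
    }
  }
  if (n_degenerate > 0L) {
    warning(sprintf(
      "%d repetition(s) had degenerate gene profiles; affected pairs averaged over the remaining repetitions",
      n_degenerate
    ), call. = FALSE)
  }
  avg <- acc / cnt
  avg[cnt == 0L] <- NA_real_
  mr <- .logit_to_mr(avg, ng, shift)
  diag(mr) <- 0
  dimnames(mr) <- list(gene_ids(m), gene_ids(m))

  structure(
    list(
      gene_ids = gene_ids(m),
      mr = mr,
      n_repetitions = n_repetitions,
      subsample_fraction = fraction,
      seed = seed,
      params = list(max_pcs = max_pcs, n_pcs_kept = d$n_kept, shift = shift,
        n_samples = n_samples(m))
    ),
    class = "coex_platform"
  )
}

#' Wrap an existing Mutual Rank matrix as a platform
#'
#' @param mr Symmetric MR matrix with gene ids as dimnames.
#' @param ... Provenance fields stored alongside.
#' @return A `coex_platform`.
#' @export
coex_platform <- function(mr, ...) {
  stopifnot(is.matrix(mr), nrow(mr) == ncol(mr), !is.null(rownames(mr)))
  structure(
    list(gene_ids = rownames(mr), mr = mr, n_repetitions = NA_integer_,
      subsample_fraction = NA_real_, seed = NA_integer_,
      params = list(...)),
    class = "coex_platform"
  )
}

#' @export
print.coex_platform <- function(x, ...) {
  cat(sprintf(
    "<coex_platform> %d genes; %s repetitions, fraction %s, seed %s\n",
    length(x$gene_ids), x$n_repetitions, x$subsample_fraction, x$seed
  ))
  invisible(x)
}

#' Tidy a coexpression platform into a pair table
#'
#' @param x A `coex_platform`.
#' @param ... Unused.
#' @return A tibble with one row per unordered gene pair (`gene_a` <
#'   `gene_b` lexicographically) and its `mr` value.
#' @export
tidy.coex_platform <- function(x, ...) {
  g <- x$gene_ids
  idx <- which(upper.tri(x$mr), arr.ind = TRUE)
  a <- g[idx[, 1]]
  b <- g[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  tibble::tibble(gene_a = a, gene_b = b, mr = x$mr[idx]) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' One-row summary of a coexpression platform
#'
#' @param x A `coex_platform`.
#' @param ... Unused.
#' @return A one-row tibble: gene count, PCs kept, repetitions, subsample
#'   fraction, seed, and the median off-diagonal MR.
#' @export
glance.coex_platform <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids),
    n_pcs_kept = x$params$n_pcs_kept %||% NA_integer_,
    n_repetitions = x$n_repetitions,
    subsample_fraction = x$subsample_fraction,
    seed = x$seed,
    median_mr = stats::median(x$mr[upper.tri(x$mr)], na.rm = TRUE)
  )
}

#' Ranked coexpressed-gene list of a guide gene
#'
#' @param platform A `coex_platform`.
#' @param guide Guide gene identifier.
#' @param universe Optional subset of gene ids to rank within (the guide
#'   itself is always excluded).
#' @return Character vector of genes ordered by ascending MR (strongest
#'   coexpression first); ties broken by gene id for determinism.
#' @export
coexpressed_list <- function(platform, guide, universe = NULL) {
  stopifnot(inherits(platform, "coex_platform"))
  if (!guide %in% platform$gene_ids) stop("unknown guide gene", call. = FALSE)
  cand <- setdiff(universe %||% platform$gene_ids, guide)
  cand <- cand[cand %in% platform$gene_ids]
  v <- platform$mr[guide, cand]
  cand[order(v, cand)]
}

#' Read / write the Mutual Rank table of a platform
#'
#' Long-format TSV with columns `gene_a`, `gene_b`, `mr`, one row per
#' unordered pair with `gene_a` < `gene_b` lexicographically.
#'
#' @param platform A `coex_platform`.
#' @param path File path.
#' @return `write_platform_tsv()` returns `path` invisibly;
#'   `read_platform_tsv()` a `coex_platform` (provenance fields are not stored
#'   in the TSV and come back as `NA`).
#' @export
write_platform_tsv <- function(platform, path) {
  df <- tidy(platform)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_platform_tsv
#' @export
read_platform_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_a", "gene_b", "mr") %in% names(df)))
  genes <- sort(unique(c(df$gene_a, df$gene_b)))
  mr <- matrix(NA_real_, length(genes), length(genes),
    dimnames = list(genes, genes))
  mr[cbind(df$gene_a, df$gene_b)] <- df$mr
  mr[cbind(df$gene_b, df$gene_a)] <- df$mr
  diag(mr) <- 0
  coex_platform(mr)
}
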