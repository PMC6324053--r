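#' One-to-one ortholog maps
#'
#' A two-column correspondence between the gene identifiers of two platforms.
#' Each gene may appear at most once on each side.
#'
#' @param df Data frame whose first column holds genes of platform A and
#'   second column genes of platform B.
#' @return A validated tibble of class `ortholog_map` with columns `gene_a`,
#'   `gene_b`.
#' @export
ortholog_map <- function(df) {
  stopifnot(is.data.frame(df), ncol(df) >= 2)
  out <- tibble::tibble(gene_a = as.character(df[[1]]),
    gene_b = as.character(df[[2]]))
  if (anyDuplicated(out$gene_a) || anyDuplicated(out$gene_b)) {
    stop("ortholog map must be one-to-one", call. = FALSE)
  }
  class(out) <- c("ortholog_map", class(out))
  out
}

#' Read / write an ortholog map TSV (two gene-id columns, header required)
#'
#' @param path File path.
#' @return `read_ortholog_tsv()` returns an `ortholog_map` tibble.
#' @export
read_ortholog_tsv <- function(path) {
  ortholog_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_ortholog_tsv
#' @param map An `ortholog_map`.
#' @export
write_ortholog_tsv <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Translate platform-1 gene ids into platform i's id space; NA where no
# ortholog exists.
.translate <- function(genes, map) {
  map$gene_b[match(genes, map$gene_a)]
}

#' Mutual Rank of all common orthologous gene pairs across platforms
#'
#' Restricts every platform to the genes shared by all of them (through the
#' ortholog maps, expressed in the first platform's identifier space) and
#' returns each platform's Mutual Rank for every unordered pair of common
#' genes: `g` common genes yield `g(g-1)/2` pairs.
#'
#' @param platforms Named list of `coex_platform` objects (>= 1).
#' @param maps List of `length(platforms) - 1` ortholog maps; `maps[[i]]`
#'   translates platform 1 identifiers (`gene_a`) to platform `i + 1`
#'   identifiers (`gene_b`). For a single platform, pass `list()`.
#' @return A tibble with columns `gene_a`, `gene_b` (first platform's ids,
#'   `gene_a < gene_b`) and one MR column per platform.
#' @export
common_pair_scores <- function(platforms, maps = list()) {
  stopifnot(is.list(platforms), length(platforms) >= 1)
  if (is.null(names(platforms)) || anyDuplicated(names(platforms))) {
    names(platforms) <- paste0("platform_", seq_along(platforms))
  }
  if (length(maps) != length(platforms) - 1L) {
    stop("need one ortholog map per platform beyond the first", call. = FALSE)
  }
  common <- platforms[[1]]$gene_ids
  for (i in seq_along(maps)) {
    tr <- .translate(common, maps[[i]])
    common <- common[!is.na(tr) & tr %in% platforms[[i + 1]]$gene_ids]
  }
  common <- sort(common)
  if (length(common) < 3) {
    stop("fewer than 3 genes common to all platforms", call. = FALSE)
  }
  idx <- utils::combn(length(common), 2)
  out <- tibble::tibble(gene_a = common[idx[1, ]], gene_b = common[idx[2, ]])
  for (i in seq_along(platforms)) {
    ids <- if (i == 1) common else .translate(common, maps[[i - 1]])
    out[[names(platforms)[i]]] <-
      platforms[[i]]$mr[cbind(ids[idx[1, ]], ids[idx[2, ]])]
  }
  out
}

#' Spearman similarity between platforms
#'
#' Rank correlation of Mutual Rank values over the common orthologous gene
#' pairs (average ranks for ties). Because it is rank-based, any strictly
#' monotone transform of a platform's MR values leaves its similarities
#' unchanged.
#'
#' @param table Pair x platform table from [common_pair_scores()].
#' @return Symmetric platform x platform correlation matrix (unit diagonal),
#'   class `coex_similarity`.
#' @export
platform_similarity <- function(table) {
  cols <- setdiff(names(table), c("gene_a", "gene_b"))
  if (nrow(table) < 3) stop("need at least 3 gene pairs", call. = FALSE)
  m <- as.matrix(table[cols])
  if (any(apply(m, 2, function(x) length(unique(x)) == 1L))) {
    stop("a platform has constant MR over the common pairs", call. = FALSE)
  }
  sim <- stats::cor(m, method = "spearman")
  structure(sim, class = c("coex_similarity", "matrix"))
}

#' Tidy a platform similarity matrix
#'
#' @param x A `coex_similarity` matrix.
#' @param ... Unused.
#' @return A long tibble: `platform_a`, `platform_b`, `similarity`.
#' @export
tidy.coex_similarity <- function(x, ...) {
  m <- unclass(x)
  tibble::as_tibble(m, rownames = "platform_a") |>
    tidyr::pivot_longer(-"platform_a", names_to = "platform_b",
      values_to = "similarity")
}

#' Cluster platforms by coexpression similarity
#'
#' Complete-linkage hierarchical clustering on the correlation distance
#' `1 - similarity`. Leaf order is the deterministic order `stats::hclust()`
#' produces for the given input order (ties resolved by the input ordering).
#'
#' @param sim Similarity matrix from [platform_similarity()].
#' @return An `hclust` object.
#' @export
cluster_platforms <- function(sim) {
  m <- unclass(sim)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  stats::hclust(stats::as.dist(1 - m), method = "complete")
}

#' Newick string of a platform dendrogram
#'
#' @param hc An `hclust` from [cluster_platforms()].
#' @return A Newick-format character string.
#' @export
platform_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Weighted coincidence of two top coexpressed-gene lists
#'
#' Compares the top `k = ceiling(top_fraction * n_universe)` genes of two
#' ranked coexpressed-gene lists over a shared gene universe. Each rank `r`
#' gets the log-discounted weight `w(r) = 1/log2(r + 1)`, and the statistic is
#' `sum over shared top-k genes of w(rank_a) * w(rank_b)`, normalized by the
#' self-overlap maximum `sum_{r=1..k} w(r)^2`. Identical top-k rankings score
#' 1; disjoint top-k sets score 0; agreement at early ranks counts most.
#'
#' @param list_a,list_b Character vectors: genes ordered by descending
#'   coexpression strength (ascending MR), in a shared identifier space.
#' @param top_fraction Fraction of the universe forming the compared top list
#'   (default 0.01).
#' @param n_universe Size of the shared gene universe (default: length of
#'   `list_a`).
#' @param weight_fn Rank-discount function; default `1/log2(r + 1)`.
#' @return A scalar in [0, 1].
#' @export
coxsim_top1 <- function(list_a, list_b, top_fraction = 0.01,
                        n_universe = length(list_a),
                        weight_fn = function(r) 1 / log2(r + 1)) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (n_universe < 1 / top_fraction) {
    stop(sprintf("shared universe has %d genes; need at least %d for top %g%%",
      n_universe, ceiling(1 / top_fraction), 100 * top_fraction),
      call. = FALSE)
  }
  k <- ceiling(top_fraction * n_universe)
  top_a <- list_a[seq_len(k)]
  top_b <- list_b[seq_len(k)]
  shared <- intersect(top_a, top_b)
  if (length(shared) == 0) return(0)
  wa <- weight_fn(match(shared, top_a))
  wb <- weight_fn(match(shared, top_b))
  sum(wa * wb) / sum(weight_fn(seq_len(k))^2)
}

#' Quartile supportability levels
#'
#' Discretizes a vector of maxCOXSIM values into four quantile levels, 0
#' (lowest quartile) to 3 (highest). Values tied with a quartile boundary get
#' the lower level, so higher levels are conservative. `NA` values (guides
#' with no ortholog) stay `NA` and do not enter the quantile computation.
#'
#' @param x Numeric vector of maxCOXSIM values.
#' @return Integer vector of levels in `{0, 1, 2, 3}` (or `NA`).
#' @export
assign_support_levels <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  lv <- (x > q[1]) + (x > q[2]) + (x > q[3])
  as.integer(lv)
}

#' Per-guide-gene supportability against reference platforms
#'
#' For every guide gene on the platform, the guide's ranked coexpressed-gene
#' list (within the genes shared with a reference, ortholog-translated) is
#' compared with the corresponding guide's list on each reference via
#' [coxsim_top1()]; the maximum over references is the guide's maxCOXSIM,
#' which is then discretized into quartile levels 0-3 across all guides.
#' Guides with no ortholog in any reference are reported with `NA` and
#' excluded from the quartiles.
#'
#' @param platform A `coex_platform`.
#' @param references Named list of reference `coex_platform`s.
#' @param maps List of ortholog maps parallel to `references`; `maps[[i]]`
#'   translates `platform` identifiers (`gene_a`) to `references[[i]]`
#'   identifiers (`gene_b`).
#' @param top_fraction Top-list fraction compared (default 0.01).
#' @return A tibble: `guide_gene`, `max_coxsim`, `level`, `best_reference`.
#' @export
supportability <- function(platform, references, maps, top_fraction = 0.01) {
  stopifnot(inherits(platform, "coex_platform"), is.list(references),
    length(references) >= 1, length(maps) == length(references))
  if (is.null(names(references))) {
    names(references) <- paste0("reference_", seq_along(references))
  }
  guides <- platform$gene_ids
  if (length(guides) < 4) stop("need at least 4 guide genes", call. = FALSE)

  # per-reference shared universe (platform-id space) and its translation
  shared <- lapply(seq_along(references), function(i) {
    tr <- .translate(platform$gene_ids, maps[[i]])
    ok <- !is.na(tr) & tr %in% references[[i]]$gene_ids
    list(genes = platform$gene_ids[ok], map = maps[[i]])
  })

  best <- rep(NA_real_, length(guides))
  best_ref <- rep(NA_character_, length(guides))
  for (gi in seq_along(guides)) {
    g <- guides[gi]
    for (ri in seq_along(references)) {
      uni <- shared[[ri]]$genes
      if (!g %in% uni) next
      g_ref <- .translate(g, shared[[ri]]$map)
      uni_ref <- .translate(uni, shared[[ri]]$map)
      la <- coexpressed_list(platform, g, universe = uni)
      lb_ref <- coexpressed_list(references[[ri]], g_ref,
        universe = uni_ref)
      # translate the reference list back into platform id space
      back <- stats::setNames(uni, uni_ref)
      lb <- unname(back[lb_ref])
      v <- coxsim_top1(la, lb, top_fraction = top_fraction,
        n_universe = length(la))
      if (is.na(best[gi]) || v > best[gi]) {
        best[gi] <- v
        best_ref[gi] <- names(references)[ri]
      }
    }
  }
  tibble::tibble(
    guide_gene = guides,
    max_coxsim = best,
    level = assign_support_levels(best),
    best_reference = best_ref
  )
}
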