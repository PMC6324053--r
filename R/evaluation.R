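#' Label gene pairs by shared pathway membership
#'
#' Builds the labeled pair set behind the platform-quality statistic: every
#' unordered pair of annotated genes (pathway members present on the platform)
#' is a case, positive iff the two genes share at least one retained pathway.
#' Positive pairs carry a weight reflecting annotation specificity; negative
#' pairs carry weight 1. Each pair's score is its Mutual Rank (smaller =
#' stronger coexpression).
#'
#' @param platform A `coex_platform`.
#' @param annotation A `pathway_annotation`, typically after
#'   [filter_pathways()] against the platform's genes. Member sets are
#'   intersected with the platform gene set here in any case.
#' @param weight_mode `"max_inverse_size"` (default): the weight is the
#'   largest inverse size among shared pathways, i.e. the most specific shared
#'   annotation decides. `"sum_inverse_size"`: inverse sizes of all shared
#'   pathways are summed.
#' @return A tibble with one row per unordered annotated-gene pair:
#'   `gene_a`, `gene_b`, `score` (MR), `label` (logical), `weight`.
#' @export
label_pairs <- function(platform, annotation,
                        weight_mode = c("max_inverse_size",
                          "sum_inverse_size")) {
  stopifnot(inherits(platform, "coex_platform"),
    inherits(annotation, "pathway_annotation"))
  weight_mode <- match.arg(weight_mode)
  sets <- lapply(annotation$gene_sets, intersect, y = platform$gene_ids)
  sets <- sets[lengths(sets) >= 2]
  genes <- sort(unique(unlist(sets)))
  ng <- length(genes)
  if (ng < 2) stop("fewer than 2 annotated genes on the platform",
    call. = FALSE)
  wmat <- matrix(0, ng, ng, dimnames = list(genes, genes))
  for (s in sets) {
    idx <- match(s, genes)
    w <- 1 / length(s)
    if (weight_mode == "max_inverse_size") {
      wmat[idx, idx] <- pmax(wmat[idx, idx], w)
    } else {
      wmat[idx, idx] <- wmat[idx, idx] + w
    }
  }
  ut <- which(upper.tri(wmat), arr.ind = TRUE)
  pos <- wmat[ut] > 0
  tibble::tibble(
    gene_a = genes[ut[, 1]],
    gene_b = genes[ut[, 2]],
    score = platform$mr[cbind(genes[ut[, 1]], genes[ut[, 2]])],
    label = pos,
    weight = ifelse(pos, wmat[ut], 1)
  )
}

#' Weighted partial AUROC at a false-positive-rate cutoff
#'
#' Pairs are ranked by ascending score (Mutual Rank: strongest coexpression
#' first). The true-positive rate accumulates positive-pair weights
#' (normalized by total positive weight); the false-positive rate accumulates
#' negative pairs (normalized by their count). The area under this weighted
#' ROC curve is taken from FPR 0 to `fpr_max`; tied scores advance TPR and FPR
#' jointly, i.e. trapezoidal interpolation.
#'
#' With `standardize = TRUE` (default) the partial area is rescaled so that a
#' random ranking scores 0.5 and perfect separation scores 1
#' (`0.5 * (1 + (A - Amin) / (Amax - Amin))` with `Amin = fpr_max^2/2`,
#' `Amax = fpr_max`); at `fpr_max = 1` this equals the plain AUROC.
#' `standardize = FALSE` returns the raw area divided by `fpr_max`.
#'
#' @param pairs A tibble from [label_pairs()] (columns `score`, `label`,
#'   `weight`).
#' @param fpr_max Upper false-positive-rate bound of the partial area
#'   (default 0.01).
#' @param standardize Rescale so random = 0.5, perfect = 1 (default TRUE).
#' @return A scalar in [0, 1].
#' @export
weighted_partial_auroc <- function(pairs, fpr_max = 0.01, standardize = TRUE) {
  stopifnot(is.data.frame(pairs),
    all(c("score", "label", "weight") %in% names(pairs)))
  if (!is.numeric(fpr_max) || fpr_max <= 0 || fpr_max > 1) {
    stop("`fpr_max` must lie in (0, 1]", call. = FALSE)
  }
  lab <- as.logical(pairs$label)
  if (all(lab) || !any(lab)) {
    stop("need at least one positive and one negative pair", call. = FALSE)
  }
  ord <- order(pairs$score)
  sc <- pairs$score[ord]
  lab <- lab[ord]
  pw <- ifelse(lab, pairs$weight[ord], 0)
  neg <- as.numeric(!lab)
  grp <- cumsum(c(TRUE, sc[-1] != sc[-length(sc)]))
  tp <- unname(cumsum(rowsum(pw, grp)[, 1]) / sum(pw))
  fp <- unname(cumsum(rowsum(neg, grp)[, 1]) / sum(neg))
  x <- c(0, fp)
  y <- c(0, tp)
  area <- 0
  for (i in seq_len(length(x) - 1L)) {
    x0 <- x[i]; x1 <- x[i + 1L]; y0 <- y[i]; y1 <- y[i + 1L]
    if (x1 <= fpr_max) {
      area <- area + (x1 - x0) * (y0 + y1) / 2
    } else {
      if (x0 < fpr_max) {
        ycut <- y0 + (y1 - y0) * (fpr_max - x0) / (x1 - x0)
        area <- area + (fpr_max - x0) * (y0 + ycut) / 2
      }
      break
    }
  }
  if (standardize) {
    a_min <- fpr_max^2 / 2
    a_max <- fpr_max
    0.5 * (1 + (area - a_min) / (a_max - a_min))
  } else {
    area / fpr_max
  }
}

#' Score a platform against pathway annotations
#'
#' The platform-quality statistic: pathways are restricted to the platform's
#' genes and size-filtered (strictly below `max_pathway_size`), annotated gene
#' pairs are labeled by shared membership with inverse-size weights, and the
#' weighted partial AUROC at `fpr_max` measures how well small Mutual Rank
#' discriminates same-pathway pairs.
#'
#' @param platform A `coex_platform`.
#' @param annotation A `pathway_annotation` (unfiltered is fine).
#' @param max_pathway_size Strict pathway size bound (default 50).
#' @param fpr_max Partial-AUROC cutoff (default 0.01).
#' @param weight_mode See [label_pairs()].
#' @return An object of class `coex_eval` with the labeled pairs and scores;
#'   see [glance.coex_eval()].
#' @export
evaluate_platform <- function(platform, annotation, max_pathway_size = 50,
                              fpr_max = 0.01,
                              weight_mode = "max_inverse_size") {
  ann <- filter_pathways(annotation, max_size = max_pathway_size,
    platform_genes = platform$gene_ids)
  pairs <- label_pairs(platform, ann, weight_mode = weight_mode)
  structure(
    list(
      pairs = pairs,
      n_pathways = length(ann$gene_sets),
      fpr_max = fpr_max,
      score = weighted_partial_auroc(pairs, fpr_max, standardize = TRUE),
      pauc_raw = weighted_partial_auroc(pairs, fpr_max, standardize = FALSE)
    ),
    class = "coex_eval"
  )
}

#' @export
print.coex_eval <- function(x, ...) {
  cat(sprintf(
    "<coex_eval> %d pathways, %d pos / %d neg pairs, score %.4f (FPR <= %g)\n",
    x$n_pathways, sum(x$pairs$label), sum(!x$pairs$label), x$score, x$fpr_max
  ))
  invisible(x)
}

#' Labeled pairs of a platform evaluation
#'
#' @param x A `coex_eval`.
#' @param ... Unused.
#' @return The labeled pair tibble (see [label_pairs()]).
#' @export
tidy.coex_eval <- function(x, ...) x$pairs

#' One-row evaluation report
#'
#' @param x A `coex_eval`.
#' @param ... Unused.
#' @return A one-row tibble: `n_pathways`, `n_pos_pairs`, `n_neg_pairs`,
#'   `fpr_max`, `kegg_score` (standardized weighted partial AUROC) and
#'   `pauc_raw` (raw area / `fpr_max`).
#' @export
glance.coex_eval <- function(x, ...) {
  tibble::tibble(
    n_pathways = x$n_pathways,
    n_pos_pairs = sum(x$pairs$label),
    n_neg_pairs = sum(!x$pairs$label),
    fpr_max = x$fpr_max,
    kegg_score = x$score,
    pauc_raw = x$pauc_raw
  )
}
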