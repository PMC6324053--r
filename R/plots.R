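#' Plot a coexpression platform as a Mutual Rank heatmap
#'
#' @param object A `coex_platform`.
#' @param ... Unused.
#' @return A ggplot: gene x gene tiles colored by log10 Mutual Rank (dark =
#'   strong coexpression).
#' @export
autoplot.coex_platform <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_a, y = .data$gene_b,
    fill = log10(.data$mr))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1, name = "log10 MR") +
    ggplot2::labs(x = NULL, y = NULL,
      title = "Mutual Rank coexpression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot the weighted ROC curve of a platform evaluation
#'
#' @param object A `coex_eval`.
#' @param ... Unused.
#' @return A ggplot of the weighted ROC up to 5x the partial-area cutoff,
#'   with the cutoff marked.
#' @export
autoplot.coex_eval <- function(object, ...) {
  pairs <- object$pairs[order(object$pairs$score), ]
  pw <- ifelse(pairs$label, pairs$weight, 0)
  df <- tibble::tibble(
    fpr = cumsum(!pairs$label) / sum(!pairs$label),
    tpr = cumsum(pw) / sum(pw)
  )
  df <- df[df$fpr <= min(1, 5 * object$fpr_max), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$fpr_max, linetype = "dashed") +
    ggplot2::labs(x = "False positive rate", y = "Weighted true positive rate",
      title = sprintf("Weighted ROC (score %.3f at FPR <= %g)",
        object$score, object$fpr_max)) +
    ggplot2::theme_minimal()
}

#' Plot a platform similarity matrix
#'
#' @param object A `coex_similarity`.
#' @param ... Unused.
#' @return A ggplot tile map of pairwise Spearman similarities.
#' @export
autoplot.coex_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$platform_a, y = .data$platform_b,
    fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f",
      .data$similarity)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "Spearman") +
    ggplot2::labs(x = NULL, y = NULL, title = "Platform similarity") +
    ggplot2::theme_minimal()
}

#' Bar plot of supportability levels
#'
#' @param report Tibble from [supportability()].
#' @return A ggplot showing the proportion of guide genes per level 0-3.
#' @export
plot_supportability <- function(report) {
  df <- report[!is.na(report$level), ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$level,
    levels = 0:3))) +
    ggplot2::geom_bar(ggplot2::aes(y = ggplot2::after_stat(.data$prop),
      group = 1)) +
    ggplot2::labs(x = "Supportability level", y = "Proportion of guide genes",
      title = "Coexpressed-gene-list supportability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
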