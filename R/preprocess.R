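#' Discard low-depth samples
#'
#' Sequencing runs with few mapped reads measure lowly expressed genes
#' unreliably, so runs whose total mapped counts fall strictly below the
#' threshold are discarded; a sample summing exactly to the threshold is kept.
#' Gene set and the original sample order are preserved.
#'
#' @param m A count-scale `expr_matrix`.
#' @param min_total_counts Minimum column sum a sample must reach to be kept
#'   (default 2e6 mapped counts).
#' @return An `expr_matrix` with the surviving samples.
#' @export
filter_low_depth_samples <- function(m, min_total_counts = 2e6) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "counts") {
    stop("depth filtering applies to count-scale matrices only", call. = FALSE)
  }
  if (!is.numeric(min_total_counts) || length(min_total_counts) != 1L ||
      min_total_counts <= 0) {
    stop("`min_total_counts` must be a positive scalar", call. = FALSE)
  }
  keep <- colSums(m$values) >= min_total_counts
  if (!any(keep)) stop("no sample passes the depth filter", call. = FALSE)
  expression_matrix(m$values[, keep, drop = FALSE], scale = "counts")
}

#' Discard constantly low-expressed genes
#'
#' Genes whose average count across the (already depth-filtered) runs falls
#' strictly below the threshold are removed; a gene averaging exactly the
#' threshold is kept.
#'
#' @param m A count-scale `expr_matrix`, normally after
#'   [filter_low_depth_samples()].
#' @param min_mean_count Minimum row mean required to keep a gene (default 30).
#' @return An `expr_matrix` with the surviving genes.
#' @export
filter_low_expression_genes <- function(m, min_mean_count = 30) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "counts") {
    stop("the mean-count filter applies to count-scale matrices only",
      call. = FALSE)
  }
  if (!is.numeric(min_mean_count) || length(min_mean_count) != 1L ||
      min_mean_count <= 0) {
    stop("`min_mean_count` must be a positive scalar", call. = FALSE)
  }
  keep <- rowMeans(m$values) >= min_mean_count
  if (!any(keep)) stop("no gene passes the mean-count filter", call. = FALSE)
  expression_matrix(m$values[keep, , drop = FALSE], scale = "counts")
}

#' Log-transform counts
#'
#' Converts every count `v` to `log2(v + pseudocount)`. The default
#' pseudocount 0.125 maps a zero count to exactly -3.
#'
#' @param m A count-scale `expr_matrix`.
#' @param pseudocount Positive offset added before taking logs (default 0.125).
#' @return A log2-scale `expr_matrix` of the same shape.
#' @export
log_transform <- function(m, pseudocount = 0.125) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "counts") {
    stop("log_transform expects a count-scale matrix", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop("`pseudocount` must be a positive scalar", call. = FALSE)
  }
  if (any(m$values < 0)) stop("negative values in count matrix", call. = FALSE)
  expression_matrix(log2(m$values + pseudocount), scale = "log2")
}

#' Zero-center each gene
#'
#' Subtracts the per-gene mean so every row averages zero, the form the PCA
#' stage expects. Idempotent.
#'
#' @param m A log2-scale `expr_matrix`.
#' @return A log2-scale `expr_matrix` whose row means are ~0.
#' @export
center_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") {
    stop("center_genes expects a log2-scale matrix; log-transform counts first",
      call. = FALSE)
  }
  expression_matrix(m$values - rowMeans(m$values), scale = "log2")
}

#' Full preprocessing chain
#'
#' Runs depth filter, low-expression filter, log transform and gene centering
#' for count input, or centering alone for log2 input. If a batch-corrected
#' matrix is supplied (e.g. ComBat output computed upstream), it replaces the
#' log-transformed matrix before centering.
#'
#' @param m An `expr_matrix` (counts or log2 scale).
#' @param min_total_counts,min_mean_count,pseudocount Filter and transform
#'   parameters; see the individual steps.
#' @param corrected Optional log2-scale `expr_matrix` from an upstream batch
#'   correction; must share the filtered matrix's gene and sample sets.
#' @return A centered log2-scale `expr_matrix`.
#' @export
preprocess_expression <- function(m, min_total_counts = 2e6,
                                  min_mean_count = 30, pseudocount = 0.125,
                                  corrected = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale == "counts") {
    m <- filter_low_depth_samples(m, min_total_counts)
    m <- filter_low_expression_genes(m, min_mean_count)
    m <- log_transform(m, pseudocount)
  }
  if (!is.null(corrected)) {
    stopifnot(inherits(corrected, "expr_matrix"))
    if (corrected$scale != "log2") {
      stop("`corrected` must be on log2 scale", call. = FALSE)
    }
    if (!setequal(gene_ids(corrected), gene_ids(m)) ||
        !setequal(sample_ids(corrected), sample_ids(m))) {
      stop("`corrected` must cover exactly the filtered genes and samples",
        call. = FALSE)
    }
    m <- expression_matrix(
      corrected$values[gene_ids(m), sample_ids(m), drop = FALSE],
      scale = "log2"
    )
  }
  center_genes(m)
}
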