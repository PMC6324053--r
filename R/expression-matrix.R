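#' Construct an expression matrix
#'
#' The container every pipeline stage operates on: a genes x samples numeric
#' matrix tagged with its scale. Count-scale matrices (raw RNA-seq
#' quantifications) are eligible for the depth and low-expression filters and
#' the log transform; log2-scale matrices (e.g. RMA-summarized microarray
#' intensities, or anything already normalized upstream) enter the pipeline at
#' [center_genes()].
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are used as identifiers when `gene_ids` / `sample_ids` are
#'   not given.
#' @param gene_ids,sample_ids Character vectors of unique identifiers.
#' @param scale Either `"counts"` (non-negative raw counts) or `"log2"`.
#' @return An object of class `expr_matrix`.
#' @examples
#' m <- expression_matrix(matrix(rpois(12, 50), 3, 4,
#'   dimnames = list(paste0("g", 1:3), paste0("s", 1:4))), scale = "counts")
#' n_genes(m)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("counts", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required (dimnames or arguments)",
      call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("missing or non-finite expression values are not supported",
      call. = FALSE)
  }
  if (scale == "counts" && any(values < 0)) {
    stop("count-scale values must be non-negative", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, scale = scale), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples, scale = %s\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  invisible(x)
}

#' Accessors for expression matrices
#'
#' @param m An `expr_matrix`.
#' @return `gene_ids()`/`sample_ids()` return character vectors; `n_genes()`
#'   and `n_samples()` integers; `expr_values()` the bare numeric matrix.
#' @export
gene_ids <- function(m) {
  UseMethod("gene_ids")
}

#' @export
gene_ids.expr_matrix <- function(m) rownames(m$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' @rdname gene_ids
#' @export
n_genes <- function(m) nrow(m$values)

#' @rdname gene_ids
#' @export
n_samples <- function(m) ncol(m$values)

#' @rdname gene_ids
#' @export
expr_values <- function(m) m$values

#' Tidy an expression matrix into long format
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value")
}

#' Read / write an expression matrix as TSV
#'
#' Format: header row of sample identifiers, first column gene identifiers,
#' tab-separated numeric body. The writer prints values with `%.6g` so that a
#' read/write cycle round-trips bit-exactly at that precision. Gzipped input
#' is handled transparently.
#'
#' @param path File path.
#' @param scale Scale flag to attach on read.
#' @return `read_expression_tsv()` returns an `expr_matrix`;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, scale = c("counts", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a gene column and >=1 sample",
    call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  expression_matrix(vals, gene_ids = df[[1]], sample_ids = colnames(df)[-1],
    scale = scale)
}

#' @rdname read_expression_tsv
#' @param m An `expr_matrix` to write.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", sample_ids(m)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(r) paste(sprintf("%.6g", r),
    collapse = "\t"))
  writeLines(paste(gene_ids(m), body, sep = "\t"), con)
  invisible(path)
}
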