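#' Pathway annotation sets
#'
#' A pathway annotation maps pathway identifiers to member gene sets; pathway
#' size (the member count) drives both the specificity filter and the
#' inverse-size weights of the evaluation statistic.
#'
#' @param gene_sets Named list of character vectors (pathway id -> member
#'   genes).
#' @param descriptions Optional named character vector of pathway
#'   descriptions.
#' @return An object of class `pathway_annotation`.
#' @export
pathway_annotation <- function(gene_sets, descriptions = NULL) {
  if (!is.list(gene_sets) || is.null(names(gene_sets)) ||
      anyDuplicated(names(gene_sets))) {
    stop("`gene_sets` must be a uniquely named list", call. = FALSE)
  }
  gene_sets <- lapply(gene_sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(gene_sets)),
      names(gene_sets))
  }
  structure(list(gene_sets = gene_sets,
    descriptions = descriptions[names(gene_sets)]),
    class = "pathway_annotation")
}

#' @export
print.pathway_annotation <- function(x, ...) {
  sizes <- lengths(x$gene_sets)
  cat(sprintf("<pathway_annotation> %d pathways, sizes %d-%d\n",
    length(sizes), if (length(sizes)) min(sizes) else 0L,
    if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Tidy a pathway annotation
#'
#' @param x A `pathway_annotation`.
#' @param ... Unused.
#' @return A tibble with columns `pathway`, `gene`, `size`.
#' @export
tidy.pathway_annotation <- function(x, ...) {
  tibble::tibble(
    pathway = rep(names(x$gene_sets), lengths(x$gene_sets)),
    gene = unlist(x$gene_sets, use.names = FALSE)
  ) |>
    dplyr::add_count(.data$pathway, name = "size")
}

#' Read / write GMT gene set files
#'
#' Standard GMT: one pathway per line, `name TAB description TAB gene TAB
#' gene ...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a `pathway_annotation`; `write_gmt()` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1], call. = FALSE)
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), ids)
  sets <- stats::setNames(lapply(fields, function(f) f[-(1:2)]), ids)
  pathway_annotation(sets, desc)
}

#' @rdname read_gmt
#' @param a A `pathway_annotation` to write.
#' @export
write_gmt <- function(a, path) {
  stopifnot(inherits(a, "pathway_annotation"))
  lines <- vapply(names(a$gene_sets), function(id) {
    paste(c(id, a$descriptions[[id]], a$gene_sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Keep small, specific pathways
#'
#' Retains pathways whose size is strictly below `max_size` (the default 50
#' keeps only highly specific annotations) and at least 2 after intersection
#' with the platform gene set, so every retained pathway contributes at least
#' one gene pair.
#'
#' @param a A `pathway_annotation`.
#' @param max_size Strict upper size bound (a pathway of exactly `max_size`
#'   genes is removed).
#' @param platform_genes Optional character vector; member sets are
#'   intersected with it before the size test.
#' @return A filtered `pathway_annotation`.
#' @export
filter_pathways <- function(a, max_size = 50, platform_genes = NULL) {
  stopifnot(inherits(a, "pathway_annotation"))
  sets <- a$gene_sets
  if (!is.null(platform_genes)) {
    sets <- lapply(sets, intersect, y = as.character(platform_genes))
  }
  keep <- lengths(sets) >= 2 & lengths(sets) < max_size
  if (!any(keep)) stop("no pathway survives the size filter", call. = FALSE)
  pathway_annotation(sets[keep], a$descriptions[keep])
}
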