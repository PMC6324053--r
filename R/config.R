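#' Pipeline configuration
#'
#' One validated record holding every stage's parameters, defaulting to the
#' production constants (PC truncation 1000, 10% subsampling, 1000
#' repetitions, pseudocount 0.125, depth threshold 2e6, mean-count threshold
#' 30, pathway size bound 50, FPR bound 1%, top-list fraction 1%). Unknown
#' keys are rejected on construction and on load.
#'
#' @param max_pcs,fraction,n_repetitions,shift Coexpression-core parameters;
#'   see [build_platform()].
#' @param pseudocount,min_total_counts,min_mean_count Preprocessing
#'   parameters; see [preprocess_expression()].
#' @param pathway_max_size,fpr_max Evaluation parameters; see
#'   [evaluate_platform()].
#' @param top_fraction Supportability top-list fraction; see
#'   [supportability()].
#' @param seed Master seed.
#' @return A list of class `coex_config`.
#' @export
pipeline_config <- function(max_pcs = 1000, fraction = 0.1,
                            n_repetitions = 1000, shift = 0.5,
                            pseudocount = 0.125, min_total_counts = 2e6,
                            min_mean_count = 30, pathway_max_size = 50,
                            fpr_max = 0.01, top_fraction = 0.01, seed = 1) {
  cfg <- list(max_pcs = max_pcs, fraction = fraction,
    n_repetitions = n_repetitions, shift = shift, pseudocount = pseudocount,
    min_total_counts = min_total_counts, min_mean_count = min_mean_count,
    pathway_max_size = pathway_max_size, fpr_max = fpr_max,
    top_fraction = top_fraction, seed = seed)
  validate_config(cfg)
}

.config_keys <- c("max_pcs", "fraction", "n_repetitions", "shift",
  "pseudocount", "min_total_counts", "min_mean_count", "pathway_max_size",
  "fpr_max", "top_fraction", "seed")

#' Validate a configuration list
#'
#' @param cfg Named list of configuration values.
#' @return The validated `coex_config`.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE)
  }
  missing <- setdiff(.config_keys, names(cfg))
  if (length(missing)) {
    stop("missing config key(s): ", paste(missing, collapse = ", "),
      call. = FALSE)
  }
  with(cfg, {
    stopifnot(
      max_pcs >= 1, fraction > 0, fraction <= 1, n_repetitions >= 1,
      shift >= 0, pseudocount > 0, min_total_counts > 0, min_mean_count > 0,
      pathway_max_size >= 3, fpr_max > 0, fpr_max <= 1,
      top_fraction > 0, top_fraction <= 1
    )
  })
  structure(cfg[.config_keys], class = "coex_config")
}

#' Read / write a configuration as YAML
#'
#' Round-trips unchanged: `read_config(write_config(cfg, path))` equals `cfg`.
#'
#' @param path File path.
#' @return `read_config()` returns a validated `coex_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg A `coex_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.coex_config <- function(x, ...) {
  cat("<coex_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}
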