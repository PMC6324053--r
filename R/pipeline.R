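#' Run the coexpression pipeline end to end
#'
#' Orchestrates simulate -> build -> evaluate -> compare -> support over an
#' artifact directory. Inputs are either files (`expr_path`, count-scale TSV,
#' plus `gmt_path`) or, when `sim_spec` is given, synthetic data generated
#' into `out_dir` first. The compare/support stages run when the simulate
#' stage produced a multi-platform family (`n_platforms > 1`).
#'
#' Every run writes a `manifest.json` recording the package version, the full
#' configuration and its hash, the seed, input checksums and output
#' checksums, which is sufficient to reproduce the outputs bit-identically.
#' A stage failure aborts with the stage named in the error.
#'
#' @param out_dir Artifact directory (created if needed).
#' @param config A `coex_config`; see [pipeline_config()].
#' @param expr_path Optional count-scale expression TSV.
#' @param gmt_path Optional pathway GMT.
#' @param sim_spec Optional `module_spec`; triggers the simulate stage.
#' @param n_platforms Platforms to simulate for compare/support (default 2).
#' @param shared_fraction Shared-module fraction of the simulated family
#'   (default 1).
#' @param stages Character subset of
#'   `c("simulate", "build", "evaluate", "compare", "support")`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         expr_path = NULL, gmt_path = NULL, sim_spec = NULL,
                         n_platforms = 2, shared_fraction = 1,
                         stages = c("simulate", "build", "evaluate",
                           "compare", "support")) {
  config <- validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .fail <- function(stage) {
    function(e) stop(sprintf("stage '%s' failed: %s", stage,
      conditionMessage(e)), call. = FALSE)
  }
  outputs <- character()
  family <- NULL

  if ("simulate" %in% stages && !is.null(sim_spec)) {
    tryCatch({
      m <- simulate_expression(sim_spec, scale = "counts")
      expr_path <- file.path(out_dir, "expression.tsv")
      write_expression_tsv(m, expr_path)
      gmt_path <- file.path(out_dir, "pathways.gmt")
      write_gmt(generate_annotation(sim_spec), gmt_path)
      outputs <- c(outputs, expr_path, gmt_path)
      if (n_platforms > 1) {
        family <- generate_platform_family(sim_spec, n_platforms,
          shared_fraction)
        for (i in seq_along(family$maps)) {
          p <- file.path(out_dir, sprintf("orthologs_P1_P%d.tsv", i + 1))
          write_ortholog_tsv(family$maps[[i]], p)
          outputs <- c(outputs, p)
        }
      }
    }, error = .fail("simulate"))
  }
  inputs <- c(expr_path, gmt_path)

  platform <- NULL
  if ("build" %in% stages) {
    tryCatch({
      if (is.null(expr_path)) stop("no expression input")
      raw <- read_expression_tsv(expr_path, scale = "counts")
      pre <- preprocess_expression(raw,
        min_total_counts = config$min_total_counts,
        min_mean_count = config$min_mean_count,
        pseudocount = config$pseudocount)
      platform <- build_platform(pre, max_pcs = config$max_pcs,
        fraction = config$fraction, n_repetitions = config$n_repetitions,
        seed = config$seed, shift = config$shift)
      p <- file.path(out_dir, "platform_mr.tsv")
      write_platform_tsv(platform, p)
      outputs <- c(outputs, p)
    }, error = .fail("build"))
  }

  if ("evaluate" %in% stages && !is.null(platform) && !is.null(gmt_path)) {
    tryCatch({
      ev <- evaluate_platform(platform, read_gmt(gmt_path),
        max_pathway_size = config$pathway_max_size, fpr_max = config$fpr_max)
      rep <- glance(ev)
      p <- file.path(out_dir, "evaluation.tsv")
      utils::write.table(rep, p, sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(as.list(rep), file.path(out_dir,
        "evaluation.json"), auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, p, file.path(out_dir, "evaluation.json"))
    }, error = .fail("evaluate"))
  }

  platforms <- NULL
  if (("compare" %in% stages || "support" %in% stages) && !is.null(family)) {
    tryCatch({
      platforms <- lapply(family$expressions, function(e) {
        build_platform(center_genes(e), max_pcs = config$max_pcs,
          fraction = config$fraction, n_repetitions = config$n_repetitions,
          seed = config$seed, shift = config$shift)
      })
      if ("compare" %in% stages) {
        tab <- common_pair_scores(platforms, family$maps)
        sim <- platform_similarity(tab)
        p <- file.path(out_dir, "similarity.tsv")
        utils::write.table(as.data.frame(unclass(sim)), p, sep = "\t",
          quote = FALSE)
        writeLines(platform_newick(cluster_platforms(sim)),
          file.path(out_dir, "platforms.nwk"))
        outputs <- c(outputs, p, file.path(out_dir, "platforms.nwk"))
      }
    }, error = .fail("compare"))
  }

  if ("support" %in% stages && !is.null(platforms) && length(platforms) > 1) {
    tryCatch({
      sup <- supportability(platforms[[1]], platforms[-1], family$maps,
        top_fraction = config$top_fraction)
      p <- file.path(out_dir, "supportability.tsv")
      utils::write.table(sup, p, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, p)
    }, error = .fail("support"))
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  checksum <- function(paths) {
    paths <- unique(paths)
    as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("coexbuild")),
    seed = config$seed,
    config = unclass(config),
    config_hash = unname(tools::md5sum(cfg_path)),
    inputs = checksum(inputs),
    outputs = checksum(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
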