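#' Pipeline configuration
#'
#' Bundles every choice the end-to-end analysis needs: the cohort source
#' (exactly one of an input CSV path or a simulation design), the network
#' estimation config, pattern-assignment threshold, bridging predictors, and
#' the single seed recorded in every output.
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate.
#' @param design A [planted_design()] used when `input` is `NULL`.
#' @param n_sim Simulated cohort size (when simulating).
#' @param demographics A [demographic_spec()] (when simulating).
#' @param mgm An [mgm_config()].
#' @param min_count Pattern-assignment threshold (default 2).
#' @param min_diseases Multimorbidity filter threshold (default 2).
#' @param bridge_metric Centrality used to rank bridging diseases.
#' @param n_bridges How many top-ranked diseases enter the regression
#'   (default 5).
#' @param stratify Fit separate male and female networks (default `TRUE`).
#' @param weighted Weighted centralities (default `TRUE`).
#' @param seed Integer master seed.
#' @param catalog Disease catalog.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, design = NULL, n_sim = 2000,
                            demographics = demographic_spec(),
                            mgm = NULL, min_count = 2, min_diseases = 2,
                            bridge_metric = "betweenness", n_bridges = 5,
                            stratify = TRUE, weighted = TRUE, seed = 1,
                            catalog = default_catalog()) {
  if (is.null(input) && is.null(design)) design <- default_design()
  if (!is.null(input) && !is.null(design)) {
    stop("supply exactly one of input path or simulation design", call. = FALSE)
  }
  if (is.null(mgm)) mgm <- mgm_config(seed = seed)
  structure(list(input = input, design = design, n_sim = n_sim,
                 demographics = demographics, mgm = mgm,
                 min_count = min_count, min_diseases = min_diseases,
                 bridge_metric = bridge_metric, n_bridges = n_bridges,
                 stratify = isTRUE(stratify), weighted = isTRUE(weighted),
                 seed = as.integer(seed), catalog = catalog),
            class = "pipeline_config")
}

#' Run the full multimorbidity-network pipeline
#'
#' Orchestrates simulate/read -> multimorbidity filter -> nodewise network
#' estimation -> community detection -> centralities -> pattern assignment ->
#' gender comparison -> bridging-disease regression, writing one file bundle
#' under `outdir`. With `stratify = TRUE` (default) the male and female
#' networks are fitted independently, and a pooled network provides the
#' shared pattern definition used for the cross-gender prevalence comparison
#' and the regression outcome. Identical config and seed produce
#' byte-identical numeric outputs. If a stage fails, files written so far are
#' preserved and the manifest records the failed stage.
#'
#' Files written: `cohort.csv`, per-scope (`pooled`, and `M`/`F` when
#' stratified) `network_<scope>.graphml`, `network_<scope>.tsv`,
#' `partition_<scope>.json`, `centrality_<scope>.csv`, plus
#' `assignment.csv`, `comparison.csv`, `regression.csv` and `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cohort`, `fits`,
#'   `partitions`, `centralities`, `bridges`, `assignment`, `comparison`,
#'   `regression`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config_hash = rlang::hash(config),
                   package_version = as.character(utils::packageVersion("multimorbnet")),
                   stages = list())
  stage <- "init"
  res <- list()
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  run <- tryCatch({
    stage <- "cohort"
    cohort <- if (!is.null(config$input)) {
      read_cohort(config$input, config$catalog)
    } else {
      simulate_cohort(config$design, n = config$n_sim,
                      spec = config$demographics, seed = config$seed)
    }
    cohort <- filter_multimorbid(cohort, config$min_diseases)
    write_cohort(cohort, file.path(outdir, "cohort.csv"))
    manifest$stages$cohort <- list(n = nrow(cohort))

    scopes <- list(pooled = cohort)
    if (config$stratify) {
      scopes$M <- cohort[cohort$gender == "M", , drop = FALSE]
      scopes$F <- cohort[cohort$gender == "F", , drop = FALSE]
      for (s in c("M", "F")) attr(scopes[[s]], "catalog") <- config$catalog
    }
    fits <- list()
    partitions <- list()
    centralities <- list()
    for (s in names(scopes)) {
      stage <- paste0("network_", s)
      fits[[s]] <- fit_nodewise(scopes[[s]], config$mgm)
      write_network(fits[[s]]$network,
                    file.path(outdir, paste0("network_", s, ".graphml")),
                    "graphml")
      write_network(fits[[s]]$network,
                    file.path(outdir, paste0("network_", s, ".tsv")),
                    "edgelist_tsv")
      write_fit_report(fits[[s]],
                       file.path(outdir, paste0("fit_report_", s, ".csv")))
      stage <- paste0("communities_", s)
      partitions[[s]] <- detect_communities(fits[[s]]$network)
      write_partition(partitions[[s]],
                      file.path(outdir, paste0("partition_", s, ".json")))
      stage <- paste0("centrality_", s)
      centralities[[s]] <- compute_centralities(fits[[s]]$network,
                                                weighted = config$weighted)
      readr::write_csv(centralities[[s]],
                       file.path(outdir, paste0("centrality_", s, ".csv")),
                       progress = FALSE)
      manifest$stages[[paste0("network_", s)]] <-
        list(n = nrow(scopes[[s]]), edges = nrow(fits[[s]]$network$edges),
             communities = length(unique(partitions[[s]]$membership$community)),
             Q = partitions[[s]]$Q)
    }

    stage <- "assignment"
    assignment <- assign_patterns(cohort, partitions$pooled,
                                  min_count = config$min_count)
    write_assignment(assignment, file.path(outdir, "assignment.csv"))

    stage <- "comparison"
    comparison <- compare_prevalence(assignment, cohort)
    readr::write_csv(comparison, file.path(outdir, "comparison.csv"),
                     progress = FALSE)

    stage <- "regression"
    ranked <- rank_bridges(centralities$pooled, metric = config$bridge_metric,
                           top_k = config$n_bridges)
    spec <- model_spec(predictors = ranked$disease)
    regression <- suppressWarnings(fit_logistic(cohort, assignment, spec))
    write_regression(regression, file.path(outdir, "regression.csv"))

    manifest$stages$done <- TRUE
    list(cohort = cohort, fits = fits, partitions = partitions,
         centralities = centralities, bridges = ranked,
         assignment = assignment, comparison = comparison,
         regression = regression)
  }, error = function(e) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(e)
    write_manifest()
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  write_manifest()
  run$manifest <- manifest
  invisible(run)
}
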