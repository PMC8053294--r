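#' Pipeline configuration
#'
#' Paths and thresholds for the end-to-end analysis: DEG selection, pathway
#' impact/flux scoring with hierarchy aggregation, regulon enrichment with
#' state calls, and the multi-level pathway/gene/TF network.
#'
#' @param deg_path TSV of differential-expression statistics
#'   (see [read_deg_table()]).
#' @param pathway_gmt GMT of pathway memberships.
#' @param regulon_gmt GMT of TF-target regulons; defaults to `pathway_gmt`
#'   when a single library plays both roles.
#' @param hierarchy_path TSV pathway hierarchy.
#' @param edges_path TSV pathway-link edge list.
#' @param output_dir directory for all outputs (created if needed).
#' @param fdr_cutoff_deg DEG threshold used downstream (default 0.10).
#' @param fdr_cutoff_deg_strict stricter DEG threshold reported alongside in
#'   the DEG summary (default 0.05).
#' @param fdr_cutoff_tf regulon significance threshold (default 0.05).
#' @param top_n how many top up/down pathways to report (default 10).
#' @param network_seeds pathway ids seeding the network expansion; `NULL`
#'   picks the top-ranked up- and downregulated pathway present in the link
#'   graph.
#' @param network_levels expansion depth (default 1).
#' @param normalize_case upper-case gene ids in all inputs before matching.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(deg_path, pathway_gmt, regulon_gmt = pathway_gmt,
                            hierarchy_path, edges_path, output_dir,
                            fdr_cutoff_deg = 0.10,
                            fdr_cutoff_deg_strict = 0.05,
                            fdr_cutoff_tf = 0.05, top_n = 10L,
                            network_seeds = NULL, network_levels = 1L,
                            normalize_case = FALSE) {
  cutoffs <- c(fdr_cutoff_deg, fdr_cutoff_deg_strict, fdr_cutoff_tf)
  if (any(!is.finite(cutoffs)) || any(cutoffs <= 0) || any(cutoffs > 1)) {
    stop("all FDR cutoffs must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(top_n) || top_n < 1) {
    stop("top_n must be >= 1", call. = FALSE)
  }
  if (!is.numeric(network_levels) || network_levels < 0) {
    stop("network_levels must be >= 0", call. = FALSE)
  }
  structure(list(deg_path = deg_path, pathway_gmt = pathway_gmt,
                 regulon_gmt = regulon_gmt, hierarchy_path = hierarchy_path,
                 edges_path = edges_path, output_dir = output_dir,
                 fdr_cutoff_deg = fdr_cutoff_deg,
                 fdr_cutoff_deg_strict = fdr_cutoff_deg_strict,
                 fdr_cutoff_tf = fdr_cutoff_tf, top_n = as.integer(top_n),
                 network_seeds = network_seeds,
                 network_levels = as.integer(network_levels),
                 normalize_case = isTRUE(normalize_case)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read and validate all inputs; (2) DEG selection and up/down
#' counts at both FDR cutoffs; (3) pathway impact/flux scoring, hierarchy
#' aggregation at subcategory and category level, top up/down ranking;
#' (4) regulon enrichment, impact/flux and activation-state calls; (5)
#' network expansion from the seed pathways, DEG mapping and TF layer;
#' (6) a JSON manifest with the configuration, input checksums and package
#' version. Outputs are staged in a temporary directory and moved into
#' `output_dir` only when every stage succeeds, so a failure leaves no
#' partial outputs. Identical configuration and inputs yield byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[diaflux] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  staging <- file.path(tempfile("diaflux_run_"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  say("stage input: reading inputs")
  inputs <- stage("input", {
    list(table = read_deg_table(config$deg_path,
                                normalize_case = config$normalize_case),
         pathways = read_gmt(config$pathway_gmt,
                             normalize_case = config$normalize_case),
         regulons = read_gmt(config$regulon_gmt,
                             normalize_case = config$normalize_case),
         hierarchy = read_hierarchy(config$hierarchy_path),
         graph = read_edges(config$edges_path))
  })

  say("stage deg: selecting differentially expressed genes")
  deg_summary <- stage("deg", {
    rows <- lapply(c(config$fdr_cutoff_deg_strict, config$fdr_cutoff_deg),
                   function(cutoff) {
      deg <- select_deg(inputs$table, cutoff)
      counts <- count_by_direction(deg, inputs$table)
      data.frame(fdr_cutoff = cutoff, n_deg = length(deg),
                 n_up = counts$n_up, n_down = counts$n_down,
                 n_zero = counts$n_zero, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  deg <- select_deg(inputs$table, config$fdr_cutoff_deg)
  say("  %d DEG at FDR <= %g (downstream), %d at FDR <= %g",
      deg_summary$n_deg[2], config$fdr_cutoff_deg,
      deg_summary$n_deg[1], config$fdr_cutoff_deg_strict)

  say("stage pathways: impact and flux scoring")
  pathway_scores <- stage("pathways",
    score_collection(inputs$pathways, inputs$table, config$fdr_cutoff_deg))
  sub_agg <- stage("pathways",
    aggregate_hierarchy(pathway_scores, inputs$hierarchy, "subcategory"))
  cat_agg <- stage("pathways",
    aggregate_hierarchy(pathway_scores, inputs$hierarchy, "category"))
  top_up <- rank_top(pathway_scores, config$top_n, "up")
  top_down <- rank_top(pathway_scores, config$top_n, "down")

  say("stage regulons: enrichment and activation-state calls")
  tf_state <- stage("regulons",
    tf_state_report(inputs$regulons, inputs$table,
                    fdr_cutoff_deg = config$fdr_cutoff_deg,
                    fdr_cutoff_tf = config$fdr_cutoff_tf))
  say("  %d significant regulon(s) at FDR <= %g", nrow(tf_state),
      config$fdr_cutoff_tf)

  say("stage network: multi-level expansion and tri-partite assembly")
  view <- stage("network", {
    seeds <- config$network_seeds
    if (is.null(seeds)) {
      seeds <- intersect(c(utils::head(top_up$set_id, 1L),
                           utils::head(top_down$set_id, 1L)),
                         inputs$graph$nodes)
      if (length(seeds) == 0L) {
        seeds <- utils::head(sort(inputs$graph$nodes), 1L)
      }
    }
    v <- expand_neighborhood(inputs$graph, seeds, config$network_levels)
    v <- map_genes_to_network(v, inputs$pathways, deg, inputs$table)
    attach_tf_layer(v, tf_state)
  })

  say("stage output: writing result tables and manifest")
  stage("output", {
    write_report(deg_summary, file.path(staging, "deg_summary.tsv"))
    write_report(pathway_scores, file.path(staging, "pathway_impact.tsv"))
    write_report(sub_agg, file.path(staging, "subcategory_impact.tsv"))
    write_report(cat_agg, file.path(staging, "category_impact.tsv"))
    write_report(top_up, file.path(staging, "top_up.tsv"))
    write_report(top_down, file.path(staging, "top_down.tsv"))
    write_report(tf_state, file.path(staging, "tf_state.tsv"))
    export_network(view, file.path(staging, ""))
  })
  input_paths <- c(deg = config$deg_path, pathways = config$pathway_gmt,
                   regulons = config$regulon_gmt,
                   hierarchy = config$hierarchy_path,
                   edges = config$edges_path)
  # the manifest records the analysis configuration, not the destination,
  # so identical inputs + settings give byte-identical manifests
  cfg_recorded <- unclass(config)
  cfg_recorded$output_dir <- NULL
  manifest <- list(
    package = "diaflux",
    version = as.character(utils::packageVersion("diaflux")),
    config = cfg_recorded,
    input_md5 = as.list(stats::setNames(unname(tools::md5sum(input_paths)),
                                        names(input_paths))),
    outputs = sort(c(list.files(staging), "manifest.json")))
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(config$output_dir, f),
              overwrite = TRUE)
  }
  say("done: %d files in %s", length(list.files(config$output_dir)),
      config$output_dir)
  invisible(manifest)
}
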