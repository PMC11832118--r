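#' Configuration for a full network-reconstruction run
#'
#' Collects every input and tuning parameter of [run_pipeline()]. Two
#' input modes: `synthetic` (a [synthetic_spec()] — inputs are generated,
#' written to the output directory, and planted-structure recovery is
#' reported) or file paths to an expression TSV plus anchor-definition
#' tables. Defaults mirror the reference analysis: PCIT significance,
#' correlation cutoff 0.7, CPM filter at 1 CPM in at least half the
#' samples.
#'
#' @param out_dir output directory (created if needed).
#' @param synthetic optional [synthetic_spec()].
#' @param expression_path,counts_path,ortholog_path,organelle_path,tf_path,overlay_path
#'   input file paths (file mode); `tf_path`/`overlay_path`/`counts_path`
#'   are optional.
#' @param cutoff correlation-magnitude cutoff for [threshold_edges()].
#' @param inclusive,keep_negative see [threshold_edges()].
#' @param min_cpm,min_cpm_fraction see [cpm_filter()].
#' @param classify_mode,classify_floor see [attach_overlay()].
#' @param run_overlay,run_tf enable the overlay / TF-network stages.
#' @param seed integer seed echoed into the report (the generator uses the
#'   spec's own seed).
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            synthetic = NULL,
                            expression_path = NULL, counts_path = NULL,
                            ortholog_path = NULL, organelle_path = NULL,
                            tf_path = NULL, overlay_path = NULL,
                            cutoff = 0.7, inclusive = TRUE,
                            keep_negative = TRUE,
                            min_cpm = 1, min_cpm_fraction = 0.5,
                            classify_mode = "auto", classify_floor = 0,
                            run_overlay = TRUE, run_tf = TRUE,
                            seed = 1) {
  if (missing(out_dir)) stop("`out_dir` is required")
  if (is.null(synthetic)) {
    if (is.null(expression_path) || is.null(ortholog_path) ||
        is.null(organelle_path))
      stop("file mode needs expression_path, ortholog_path and organelle_path")
  } else {
    stopifnot(inherits(synthetic, "synthetic_spec"))
  }
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must lie strictly between 0 and 1")
  structure(
    list(out_dir = out_dir, synthetic = synthetic,
         expression_path = expression_path, counts_path = counts_path,
         ortholog_path = ortholog_path, organelle_path = organelle_path,
         tf_path = tf_path, overlay_path = overlay_path,
         cutoff = cutoff, inclusive = inclusive,
         keep_negative = keep_negative,
         min_cpm = min_cpm, min_cpm_fraction = min_cpm_fraction,
         classify_mode = classify_mode, classify_floor = classify_floor,
         run_overlay = isTRUE(run_overlay), run_tf = isTRUE(run_tf),
         seed = as.integer(seed)),
    class = "pipeline_config")
}

config_echo <- function(config) {
  keep <- c("cutoff", "inclusive", "keep_negative", "min_cpm",
            "min_cpm_fraction", "classify_mode", "classify_floor",
            "run_overlay", "run_tf", "seed")
  out <- config[keep]
  if (!is.null(config$synthetic))
    out$synthetic <- config$synthetic[setdiff(names(config$synthetic), "modules")]
  out
}

run_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[mitonet] stage %-14s %.2fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full anchored co-expression network pipeline
#'
#' Executes anchor selection, the PCIT screen, correlation thresholding,
#' network assembly, topology summaries, and (as configured) the
#' CPM-filtered differential-expression overlay and the TF-augmented
#' network with the TF-retention filter. All result files are written to
#' the configured output directory along with a JSON run report carrying
#' the stage counts (genes in, anchor set, significant pairs, edges,
#' nodes, components, ...). For a fixed configuration the report and
#' every output file are reproduced byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return the run report (a nested list, invisibly), as written to
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config_echo(config))

  # --- inputs -------------------------------------------------------------
  catalog <- NULL; counts <- NULL; overlay_tab <- NULL; tf_list <- NULL
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    sim <- run_stage("simulate", generate_expression(spec))
    expr <- sim$expression
    catalog <- sim$catalog
    counts <- run_stage("counts", generate_counts(spec))
    overlay_tab <- run_stage("overlay-sim",
                             generate_overlay(spec, rownames(expr)))
    # exercise the real anchor-assembly path: nuclear anchors arrive via an
    # ortholog map, organelle-encoded genes via their own list
    nuclear <- catalog$gene_id[catalog$is_anchor & !catalog$is_organelle_encoded]
    orth <- data.frame(source_gene_id = paste0("SRC_", nuclear),
                       target_gene_id = nuclear, stringsAsFactors = FALSE)
    organelle <- catalog$gene_id[catalog$is_organelle_encoded]
    tf_list <- catalog$gene_id[catalog$is_tf]
    write_expression(expr, file.path(out_dir, "expression.tsv"))
    utils::write.table(catalog, file.path(out_dir, "catalog.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    expr <- run_stage("read-expression", read_expression(config$expression_path))
    orth <- run_stage("read-orthologs", read_ortholog_table(config$ortholog_path))
    organelle <- run_stage("read-organelle", read_gene_list(config$organelle_path))
    if (!is.null(config$counts_path))
      counts <- run_stage("read-counts", read_counts(config$counts_path))
    if (!is.null(config$overlay_path))
      overlay_tab <- run_stage("read-overlay", read_overlay(config$overlay_path))
    if (!is.null(config$tf_path))
      tf_list <- run_stage("read-tf", read_gene_list(config$tf_path))
  }
  report$input <- list(n_genes = nrow(expr), n_samples = ncol(expr))

  # --- anchor selection ---------------------------------------------------
  sel <- run_stage("select-genes",
                   build_anchor_set(orth, organelle, rownames(expr)))
  anchor <- sel$anchor_set
  write_gene_list(anchor, file.path(out_dir, "anchor_genes.txt"))
  report$anchor_selection <- as.list(sel$report)

  # --- PCIT + threshold ---------------------------------------------------
  fit <- run_stage("pcit", pcit(expr[anchor, , drop = FALSE]))
  edges <- run_stage("threshold",
                     threshold_edges(fit, cutoff = config$cutoff,
                                     inclusive = config$inclusive,
                                     keep_negative = config$keep_negative))
  n_pairs <- length(anchor) * (length(anchor) - 1) / 2
  report$pcit <- list(
    genes_in = length(anchor), pairs_tested = n_pairs,
    significant_pairs = sum(fit$significant[upper.tri(fit$significant)]),
    cutoff = config$cutoff, edges = nrow(edges))

  # --- network + topology -------------------------------------------------
  net <- run_stage("build-network", build_network(edges, catalog))
  topo <- run_stage("topology", topology_report(net))
  write_network(net, file.path(out_dir, "network_edges.tsv"), "edge-tsv")
  write_network(net, file.path(out_dir, "network.sif"), "sif")
  utils::write.table(topo$nodes, file.path(out_dir, "topology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$network <- list(
    nodes = topo$n_nodes, edges = topo$n_edges,
    components = topo$component_count,
    component_sizes = as.integer(topo$component_sizes),
    max_degree = if (topo$n_nodes > 0) max(topo$degree) else 0L)

  if (!is.null(config$synthetic)) {
    rec <- planted_module_metrics(edges, catalog, genes = anchor)
    report$planted_recovery <- list(
      within_module_recall = rec$within_module_recall,
      cross_module_false_edge_rate = rec$cross_module_false_edge_rate)
  }

  # --- overlay ------------------------------------------------------------
  if (config$run_overlay && !is.null(overlay_tab)) {
    kept <- NULL
    if (!is.null(counts)) {
      kept <- run_stage("cpm-filter",
                        cpm_filter(counts, min_cpm = config$min_cpm,
                                   min_fraction = config$min_cpm_fraction))
      overlay_tab <- overlay_tab[overlay_tab$gene_id %in% kept, , drop = FALSE]
    }
    net <- run_stage("overlay",
                     attach_overlay(net, overlay_tab,
                                    mode = config$classify_mode,
                                    floor = config$classify_floor))
    up <- consistent_genes(overlay_tab, "up", mode = config$classify_mode,
                           floor = config$classify_floor)
    down <- consistent_genes(overlay_tab, "down", mode = config$classify_mode,
                             floor = config$classify_floor)
    write_gene_list(up, file.path(out_dir, "consistent_up.txt"))
    write_gene_list(down, file.path(out_dir, "consistent_down.txt"))
    write_overlay(overlay_tab, file.path(out_dir, "overlay.tsv"))
    report$overlay <- list(
      contrasts = length(unique(overlay_tab$contrast_id)),
      genes_after_cpm = if (is.null(kept)) NULL else length(kept),
      consistent_up = length(up), consistent_down = length(down))
  }
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")

  # --- TF network ---------------------------------------------------------
  if (config$run_tf && !is.null(tf_list) && length(tf_list) > 0) {
    labels <- run_stage("tf-gene-set", build_tf_gene_set(anchor, tf_list))
    pool <- intersect(labels$gene_id, rownames(expr))
    tf_fit <- run_stage("tf-pcit", pcit(expr[pool, , drop = FALSE]))
    tf_edges <- threshold_edges(tf_fit, cutoff = config$cutoff,
                                inclusive = config$inclusive,
                                keep_negative = config$keep_negative)
    tf_net <- build_network(tf_edges, catalog)
    filt <- run_stage("tf-filter", filter_tf_nodes(tf_net, labels))
    ranks <- run_stage("tf-rank", rank_tf(filt$network, labels))
    utils::write.table(filt$report, file.path(out_dir, "tf_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ranks$top_by_degree,
                       file.path(out_dir, "tf_top_degree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ranks$top_by_radiality,
                       file.path(out_dir, "tf_top_radiality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_network(filt$network, file.path(out_dir, "tf_network_edges.tsv"),
                  "edge-tsv")
    report$tf_network <- list(
      gene_pool = length(pool),
      unfiltered_nodes = igraph::vcount(tf_net),
      unfiltered_edges = igraph::ecount(tf_net),
      tf_nodes = nrow(filt$report),
      tf_excluded = sum(!filt$report$retained),
      filtered_nodes = igraph::vcount(filt$network),
      filtered_edges = igraph::ecount(filt$network))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(report)
}
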