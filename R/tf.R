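#' Combine anchor genes and transcription factors into one labeled set
#'
#' Union of the anchor gene list and the TF list, each gene labeled
#' `"anchor-only"`, `"tf-only"` or `"both"` (a TF that is itself an anchor
#' gene, e.g. a mitochondrially localized regulator).
#'
#' @param anchor character vector of anchor gene ids (non-empty).
#' @param tfs character vector of TF gene ids (non-empty).
#' @return data.frame with columns `gene_id` (sorted) and `label`.
#' @export
build_tf_gene_set <- function(anchor, tfs) {
  if (length(anchor) == 0L) stop("`anchor` is empty")
  if (length(tfs) == 0L) stop("`tfs` is empty")
  anchor <- unique(anchor); tfs <- unique(tfs)
  ids <- sort(union(anchor, tfs))
  label <- ifelse(ids %in% anchor & ids %in% tfs, "both",
                  ifelse(ids %in% anchor, "anchor-only", "tf-only"))
  data.frame(gene_id = ids, label = label, stringsAsFactors = FALSE)
}

tf_labels_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stats::setNames(labels$label, labels$gene_id)
  } else if (is.character(labels) && !is.null(names(labels))) {
    labels
  } else stop("`labels` must be a build_tf_gene_set() data.frame or a named character vector")
}

#' Filter transcription-factor nodes by their connectivity profile
#'
#' Applies the TF-retention rule: a TF-only node is excluded iff it has
#' strictly more neighbors that are TF-only than neighbors that are anchor
#' genes (label `"anchor-only"` or `"both"`). Counts are evaluated on the
#' unfiltered graph and all removals happen simultaneously (single pass —
#' no re-evaluation after removals). Nodes labeled `"anchor-only"` or
#' `"both"` are never removed; equal counts retain the TF.
#'
#' @param net an undirected igraph network whose nodes are all covered by
#'   `labels`.
#' @param labels output of [build_tf_gene_set()] (or a named character
#'   vector of labels).
#' @return list with `network` (the filtered graph) and `report`: a
#'   data.frame over all TF nodes (labels `"tf-only"` and `"both"`) with
#'   columns `tf_id`, `label`, `n_tf` (TF-only neighbors), `n_mito`
#'   (anchor-side neighbors), `retained`.
#' @export
filter_tf_nodes <- function(net, labels) {
  lab <- tf_labels_vector(labels)
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, names(lab))
  if (length(missing) > 0L)
    stop("labels missing for node(s): ", paste(missing, collapse = ", "))
  node_lab <- lab[nodes]

  tf_nodes <- nodes[node_lab %in% c("tf-only", "both")]
  if (length(tf_nodes) == 0L) {
    return(list(network = net,
                report = data.frame(tf_id = character(0), label = character(0),
                                    n_tf = integer(0), n_mito = integer(0),
                                    retained = logical(0))))
  }
  n_tf <- integer(length(tf_nodes))
  n_mito <- integer(length(tf_nodes))
  for (i in seq_along(tf_nodes)) {
    nb <- names(igraph::neighbors(net, tf_nodes[i]))
    nl <- node_lab[nb]
    n_tf[i] <- sum(nl == "tf-only")
    n_mito[i] <- sum(nl %in% c("anchor-only", "both"))
  }
  retained <- node_lab[tf_nodes] == "both" | n_tf <= n_mito
  report <- data.frame(tf_id = tf_nodes, label = unname(node_lab[tf_nodes]),
                       n_tf = n_tf, n_mito = n_mito, retained = retained,
                       stringsAsFactors = FALSE)
  report <- report[order(report$tf_id), , drop = FALSE]
  rownames(report) <- NULL
  drop <- tf_nodes[!retained]
  net2 <- if (length(drop) > 0L) igraph::delete_vertices(net, drop) else net
  list(network = net2, report = report)
}

#' Rank transcription factors by degree and by radiality
#'
#' Ranks every TF node (labels `"tf-only"` and `"both"`) of a (typically
#' TF-filtered) network by degree and, separately, by radiality; ties are
#' broken by gene id.
#'
#' @param net an undirected igraph network.
#' @param labels output of [build_tf_gene_set()] (or named label vector).
#' @param top_k how many TFs to keep in the `top_*` tables (default 20).
#' @return list with `by_degree` and `by_radiality` (full ranked
#'   data.frames with columns `tf_id`, `label`, `degree`, `radiality`),
#'   plus `top_by_degree` and `top_by_radiality` (first `top_k` rows).
#' @export
rank_tf <- function(net, labels, top_k = 20) {
  lab <- tf_labels_vector(labels)
  nodes <- igraph::V(net)$name
  node_lab <- lab[nodes]
  tf_nodes <- nodes[!is.na(node_lab) & node_lab %in% c("tf-only", "both")]
  deg <- igraph::degree(net)
  rad <- radiality(net)
  tab <- data.frame(tf_id = tf_nodes, label = unname(node_lab[tf_nodes]),
                    degree = as.integer(deg[tf_nodes]),
                    radiality = as.numeric(rad[tf_nodes]),
                    stringsAsFactors = FALSE)
  by_degree <- tab[order(-tab$degree, tab$tf_id), , drop = FALSE]
  rownames(by_degree) <- NULL
  by_radiality <- tab[order(-tab$radiality, tab$tf_id, na.last = TRUE), ,
                      drop = FALSE]
  rownames(by_radiality) <- NULL
  list(by_degree = by_degree, by_radiality = by_radiality,
       top_by_degree = utils::head(by_degree, top_k),
       top_by_radiality = utils::head(by_radiality, top_k))
}
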