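#' Build the co-expression network from an edge list
#'
#' Assembles an undirected weighted igraph graph from a thresholded edge
#' list. The node set is exactly the set of edge endpoints — anchor genes
#' with no surviving edge do not become nodes. Catalog attributes
#' (`block`, `is_anchor`, `is_tf`, `is_organelle_encoded`, `localization`)
#' are attached to the nodes; genes missing from the catalog default to
#' `FALSE` flags and localization `"unknown"`.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`
#'   (e.g. from [threshold_edges()]). Self-edges and duplicate pairs are
#'   errors.
#' @param catalog optional gene catalog data.frame (see
#'   [generate_expression()]); `NULL` for attribute-less nodes.
#' @return an [igraph][igraph::graph_from_data_frame] undirected graph.
#' @export
build_network <- function(edges, catalog = NULL) {
  if (!is.data.frame(edges) ||
      !all(c("gene_a", "gene_b", "weight") %in% names(edges)))
    stop("`edges` must have columns gene_a, gene_b, weight")
  if (nrow(edges) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  if (any(edges$gene_a == edges$gene_b))
    stop("self-edges are not allowed")
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate edge: ", dup)
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(catalog)) {
    i <- match(nodes, catalog$gene_id)
    vdf$block <- ifelse(is.na(i), "unknown", catalog$block[i])
    vdf$is_anchor <- ifelse(is.na(i), FALSE, catalog$is_anchor[i])
    vdf$is_tf <- ifelse(is.na(i), FALSE, catalog$is_tf[i])
    vdf$is_organelle_encoded <-
      ifelse(is.na(i), FALSE, catalog$is_organelle_encoded[i])
    vdf$localization <- ifelse(is.na(i), "unknown", catalog$localization[i])
  }
  igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "weight")],
    directed = FALSE, vertices = vdf)
}

#' Node degree and degree histogram
#'
#' @param net an undirected igraph network (see [build_network()]).
#' @return list with `degree` (named integer vector) and `histogram`
#'   (table of degree frequencies).
#' @export
node_degree <- function(net) {
  d <- igraph::degree(net)
  list(degree = d, histogram = table(d))
}

#' Connected components, largest first
#'
#' @param net an undirected igraph network.
#' @return list with `count`, `sizes` (decreasing; ties broken by the
#'   smallest member id), and `members`, a list of sorted gene-id vectors,
#'   plus `membership`: a named integer vector of component ids (1 =
#'   largest).
#' @export
network_components <- function(net) {
  comp <- igraph::components(net)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, `[`, character(1), 1L))
  members <- members[ord]
  names(members) <- NULL
  membership <- integer(0)
  for (i in seq_along(members))
    membership[members[[i]]] <- i
  list(count = length(members),
       sizes = vapply(members, length, integer(1)),
       members = members,
       membership = membership[names(comp$membership)])
}

#' Neighbors of a gene in the network
#'
#' @param net an undirected igraph network.
#' @param gene a gene id present in the network.
#' @return sorted character vector of adjacent gene ids.
#' @export
gene_neighbors <- function(net, gene) {
  if (!gene %in% igraph::V(net)$name)
    stop("gene not in network: ", gene)
  sort(names(igraph::neighbors(net, gene)))
}

#' Radiality centrality (within-component, diameter-normalized)
#'
#' For a node v in a component C with m >= 2 nodes and unweighted diameter
#' \eqn{\Delta_C \ge 1},
#' \deqn{Rad(v) = \frac{\Delta_C + 1 - \bar{d}(v)}{\Delta_C}}
#' where \eqn{\bar{d}(v)} is v's mean shortest-path (hop-count) distance to
#' the other nodes of its component. Values lie in \[0, 1\] and reach 1
#' exactly when v is adjacent to every other node of its component.
#' Singleton components get `NA`. Edge weights are ignored (hop counts).
#'
#' @param net an undirected igraph network.
#' @return named numeric vector of radiality values.
#' @export
radiality <- function(net) {
  out <- stats::setNames(rep(NA_real_, igraph::vcount(net)),
                         igraph::V(net)$name)
  comp <- igraph::components(net)
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    m <- length(members)
    if (m < 2L) next
    d <- igraph::distances(net, v = members, to = members, weights = NA)
    delta <- max(d)
    mean_d <- rowSums(d) / (m - 1L)
    out[igraph::V(net)$name[members]] <- (delta + 1 - mean_d) / delta
  }
  out
}

#' Topology report for a co-expression network
#'
#' Per-node degree, radiality and component membership, plus the degree
#' histogram and component size spectrum — the summaries a network
#' analyzer would report.
#'
#' @param net an undirected igraph network.
#' @return object of class `"topology_report"`: list with `n_nodes`,
#'   `n_edges`, `degree`, `degree_histogram`, `radiality`, `component`
#'   (named component ids, 1 = largest), `component_sizes`,
#'   `component_count`, and `nodes`, a per-node data.frame.
#' @export
topology_report <- function(net) {
  deg <- node_degree(net)
  comp <- network_components(net)
  rad <- radiality(net)
  nodes <- data.frame(
    gene_id = igraph::V(net)$name,
    degree = as.integer(deg$degree),
    radiality = as.numeric(rad),
    component = as.integer(comp$membership[igraph::V(net)$name]),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$degree, nodes$gene_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(
    list(n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
         degree = deg$degree, degree_histogram = deg$histogram,
         radiality = rad, component = comp$membership,
         component_sizes = comp$sizes, component_count = comp$count,
         nodes = nodes),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("Co-expression network topology\n")
  cat(sprintf("  nodes: %d   edges: %d   components: %d\n",
              x$n_nodes, x$n_edges, x$component_count))
  if (x$component_count > 0)
    cat("  component sizes:",
        paste(utils::head(x$component_sizes, 10), collapse = ", "),
        if (x$component_count > 10) "..." else "", "\n")
  if (x$n_nodes > 0) {
    cat(sprintf("  degree: max %d, median %s\n", max(x$degree),
                format(stats::median(x$degree))))
    cat("  top nodes by degree:\n")
    print(utils::head(x$nodes, 5))
  }
  invisible(x)
}
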