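#' Counts-per-million expression filter
#'
#' Implements the standard expression filter: a gene is retained iff it
#' shows at least `min_cpm` counts per million in at least
#' `ceiling(min_fraction * n_samples)` samples (the "at least 1 CPM in at
#' least half of the samples" rule at the defaults). CPM is
#' count / library size × 1e6 with library size the column sum.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction minimum fraction of samples at or above `min_cpm`
#'   (default 0.5; "at least half" uses the ceiling for odd sample counts).
#' @return character vector of kept gene ids, in input row order.
#' @examples
#' cts <- rbind(g1 = c(10, 10, 0, 0),
#'              g2 = c(0, 0, 0, 0),
#'              rest = 1e6 - c(10, 10, 0, 0))  # library sizes all 1e6
#' cpm_filter(cts)  # g1 kept (2 of 4 samples >= 1 CPM), g2 dropped
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_fraction = 0.5) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) stop("counts must be integers")
  if (is.null(rownames(counts))) stop("`counts` must have gene-id rownames")
  if (min_fraction < 0 || min_fraction > 1)
    stop("`min_fraction` must lie in [0, 1]")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop_mitonet(paste0("zero library size in sample(s): ",
                        paste(bad, collapse = ", ")),
                 class = "mitonet_zero_library", samples = bad)
  }
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(cpm >= min_cpm) >= need
  rownames(counts)[keep]
}

#' Classify a gene's differential-expression state
#'
#' Two reading modes of an overlay table:
#' with a DE flag, a gene is `"up"`/`"down"` by the sign of its fold change
#' when flagged DE and `"unaffected"` otherwise (a zero fold change is
#' `"unaffected"` even when flagged);
#' without a flag, the sign of the fold change decides, with magnitudes at
#' or below `floor` (default 0) classified `"unaffected"`.
#' Missing values are always `"unaffected"`.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param is_de optional logical vector of DE flags (same length).
#' @param floor fold-change magnitude at or below which a gene is
#'   `"unaffected"` when no DE flag is given.
#' @return character vector in \{`"up"`, `"down"`, `"unaffected"`\}.
#' @export
classify_node <- function(log2fc, is_de = NULL, floor = 0) {
  base <- ifelse(is.na(log2fc) | log2fc == 0, "unaffected",
                 ifelse(log2fc > 0, "up", "down"))
  if (!is.null(is_de)) {
    ifelse(is.na(is_de) | !is_de, "unaffected", base)
  } else {
    ifelse(is.na(log2fc) | abs(log2fc) <= floor, "unaffected", base)
  }
}

validate_overlay <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("gene_id", "contrast_id", "log2fc") %in% names(table)))
    stop("overlay table must have columns gene_id, contrast_id, log2fc")
  if (anyDuplicated(table[, c("gene_id", "contrast_id")]))
    stop("overlay table has duplicate (gene, contrast) rows")
  if (length(unique(table$contrast_id)) == 0L)
    stop("overlay table has no contrasts")
  invisible(table)
}

overlay_mode <- function(table, mode) {
  if (mode == "auto")
    mode <- if ("is_de" %in% names(table) && any(!is.na(table$is_de)))
      "de" else "fold_change"
  if (mode == "de" && !"is_de" %in% names(table))
    stop("mode 'de' requires an is_de column")
  mode
}

#' Attach per-contrast fold changes and classes to network nodes
#'
#' For every contrast in the overlay table, each node gains a numeric
#' attribute `log2fc_<contrast>` and a character attribute
#' `class_<contrast>` (`"up"`/`"down"`/`"unaffected"`, via
#' [classify_node()]). Genes absent from the table get `NA` fold change
#' and class `"unaffected"`. The node and edge sets are unchanged, and
#' re-attaching the same table is a no-op.
#'
#' @param net an undirected igraph network (see [build_network()]).
#' @param table overlay data.frame with columns `gene_id`, `contrast_id`,
#'   `log2fc` and optionally `is_de`.
#' @param mode `"auto"` (use the DE flag when present), `"de"` or
#'   `"fold_change"`.
#' @param floor passed to [classify_node()] in fold-change mode.
#' @return the network with overlay node attributes attached.
#' @export
attach_overlay <- function(net, table, mode = c("auto", "de", "fold_change"),
                           floor = 0) {
  mode <- match.arg(mode)
  validate_overlay(table)
  mode <- overlay_mode(table, mode)
  contrasts <- sort(unique(table$contrast_id))
  if (length(contrasts) == 0L) stop("empty contrast set")
  nodes <- igraph::V(net)$name
  for (cc in contrasts) {
    sub <- table[table$contrast_id == cc, , drop = FALSE]
    i <- match(nodes, sub$gene_id)
    lfc <- sub$log2fc[i]
    de <- if (mode == "de") sub$is_de[i] else NULL
    cls <- classify_node(lfc, is_de = de, floor = floor)
    cls[is.na(i)] <- "unaffected"
    net <- igraph::set_vertex_attr(net, paste0("log2fc_", cc), value = lfc)
    net <- igraph::set_vertex_attr(net, paste0("class_", cc), value = cls)
  }
  net
}

#' Genes with a consistent DE direction across every contrast
#'
#' Returns the genes whose classification (via [classify_node()]) equals
#' `direction` in all contrasts of the table. A gene missing any contrast
#' is not consistent. Optionally restricted to a scope set (e.g. the
#' members of one sub-network).
#'
#' @param table overlay data.frame (`gene_id`, `contrast_id`, `log2fc`,
#'   optional `is_de`).
#' @param direction `"up"` or `"down"`.
#' @param scope optional gene-id vector to restrict to; an empty scope
#'   yields an empty result.
#' @param mode,floor see [attach_overlay()].
#' @return sorted character vector of consistent gene ids.
#' @export
consistent_genes <- function(table, direction = c("up", "down"),
                             scope = NULL,
                             mode = c("auto", "de", "fold_change"),
                             floor = 0) {
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  validate_overlay(table)
  mode <- overlay_mode(table, mode)
  if (!is.null(scope)) {
    table <- table[table$gene_id %in% scope, , drop = FALSE]
    if (nrow(table) == 0L) return(character(0))
  }
  k <- length(unique(table$contrast_id))
  de <- if (mode == "de") table$is_de else NULL
  cls <- classify_node(table$log2fc, is_de = de, floor = floor)
  hits <- tapply(cls == direction, table$gene_id,
                 function(v) length(v) == k && all(v))
  sort(names(hits)[hits])
}
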