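#' Assemble the anchor gene set
#'
#' Builds the anchor set the network is centred on: the distinct target ids
#' of an ortholog-mapping table (e.g. human mitoproteome genes mapped to
#' the study species), united with the organelle-encoded gene list, then
#' intersected with the genes present in the expression data. Matching is
#' case-sensitive and exact; many-to-one ortholog mappings collapse to
#' distinct target ids.
#'
#' @param orthologs data.frame with columns `source_gene_id`,
#'   `target_gene_id` (one row per mapping; duplicates are ignored), e.g.
#'   from [read_ortholog_table()].
#' @param organelle_genes character vector of organelle-encoded gene ids
#'   (always part of the anchor set candidates).
#' @param expressed_genes character vector of gene ids present in the
#'   expression matrix.
#' @return list with `anchor_set` (sorted gene ids) and `report`, a named
#'   integer vector with stage counts `mapped` (distinct ortholog targets),
#'   `union` (after adding organelle genes) and `present` (after
#'   intersecting with the expressed genes).
#' @examples
#' orth <- data.frame(source_gene_id = c("h1", "h2"),
#'                    target_gene_id = c("b1", "b1"))
#' build_anchor_set(orth, "b2", c("b1", "b2", "b3"))
#' @export
build_anchor_set <- function(orthologs, organelle_genes, expressed_genes) {
  if (!is.data.frame(orthologs) ||
      !all(c("source_gene_id", "target_gene_id") %in% names(orthologs)))
    stop("`orthologs` must have columns `source_gene_id` and `target_gene_id`")
  if (nrow(orthologs) == 0L) stop("`orthologs` is empty")
  if (length(organelle_genes) == 0L) stop("`organelle_genes` is empty")
  if (length(expressed_genes) == 0L) stop("`expressed_genes` is empty")

  mapped <- sort(unique(orthologs$target_gene_id))
  candidates <- sort(union(mapped, unique(organelle_genes)))
  anchor <- sort(intersect(candidates, expressed_genes))
  report <- c(mapped = length(mapped), union = length(candidates),
              present = length(anchor))
  if (length(anchor) == 0L)
    stop_mitonet(
      sprintf(paste0("anchor set is empty after intersection with the ",
                     "expression data (mapped = %d, union = %d, present = 0); ",
                     "this usually signals a gene-id namespace mismatch"),
              report[["mapped"]], report[["union"]]),
      class = "mitonet_empty_anchor", report = report)
  list(anchor_set = anchor, report = report)
}
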