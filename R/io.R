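#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids and the
#' gene id in the first column. Ragged rows, duplicate gene ids,
#' non-numeric or negative values raise errors that name the offending
#' line.
#'
#' @param path path to the TSV file.
#' @param allow_negative permit negative values (off by default:
#'   expression is non-negative).
#' @return numeric matrix with gene-id rownames and sample-id colnames.
#' @export
read_expression <- function(path, allow_negative = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(fields) < 2L) stop("expression file has no data rows: ", path)
  bad <- which(fields != fields[1L])
  if (length(bad) > 0L)
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, bad[1L], fields[bad[1L]], fields[1L]))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  ids <- df[[1L]]
  dup <- which(duplicated(ids))
  if (length(dup) > 0L)
    stop(sprintf("duplicate gene id '%s' in %s at line %d",
                 ids[dup[1L]], path, dup[1L] + 1L))
  vals <- suppressWarnings(
    vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(df)[-1L]))
  na_cells <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(na_cells) > 0L)
    stop(sprintf("non-numeric value in %s at line %d (gene '%s')",
                 path, na_cells[1L, 1L] + 1L, ids[na_cells[1L, 1L]]))
  if (!allow_negative && any(vals < 0)) {
    i <- which(rowSums(vals < 0) > 0)[1L]
    stop(sprintf("negative value in %s at line %d (gene '%s')",
                 path, i + 1L, ids[i]))
  }
  rownames(vals) <- ids
  vals
}

#' Write a genes-by-samples matrix as TSV
#'
#' First column `gene_id`, then one column per sample. Values are written
#' with 17 significant digits so that a write/read round trip is exact.
#'
#' @param mat numeric matrix with rownames and colnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("S%03d", seq_len(ncol(mat)))
  txt <- apply(mat, 2L, function(col) sprintf("%.17g", col))
  if (nrow(mat) == 1L) txt <- matrix(txt, nrow = 1L)
  df <- data.frame(gene_id = rownames(mat), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix from TSV
#'
#' Same layout as [read_expression()], with an additional integrality
#' check.
#'
#' @inheritParams read_expression
#' @return integer matrix.
#' @export
read_counts <- function(path) {
  m <- read_expression(path)
  if (any(m != floor(m))) stop("counts file contains non-integer values: ", path)
  storage.mode(m) <- "integer"
  m
}

#' Read / write a one-id-per-line gene list
#'
#' @param path file path.
#' @return character vector of gene ids (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_gene_list
#' @param genes character vector of gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' Read an ortholog-mapping table from two-column TSV
#'
#' Columns are taken as source and target gene id (header required; any
#' column names are accepted and normalized). Duplicate (source, target)
#' rows are dropped.
#'
#' @param path file path.
#' @return data.frame with columns `source_gene_id`, `target_gene_id`.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("ortholog table needs two columns: ", path)
  out <- data.frame(source_gene_id = df[[1L]], target_gene_id = df[[2L]],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Read / write a long-format overlay table
#'
#' TSV with columns `gene_id`, `contrast_id`, `log2fc` and optionally
#' `is_de` (logical).
#'
#' @param path file path.
#' @return overlay data.frame.
#' @export
read_overlay <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "contrast_id", "log2fc")
  if (!all(need %in% names(df)))
    stop("overlay table needs columns gene_id, contrast_id, log2fc: ", path)
  df$log2fc <- as.numeric(df$log2fc)
  if ("is_de" %in% names(df)) df$is_de <- as.logical(df$is_de)
  validate_overlay(df)
  df
}

#' @rdname read_overlay
#' @param table overlay data.frame.
#' @export
write_overlay <- function(table, path) {
  validate_overlay(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network as edge-list TSV, SIF or GraphML
#'
#' `"edge-tsv"` writes `gene_a`, `gene_b`, `weight` (weight to 6
#' decimals); `"sif"` writes Cytoscape simple-interaction lines
#' (`gene_a pp gene_b`); `"graphml"` writes GraphML with all node
#' attributes (missing character attributes are serialized as empty
#' strings, not dropped).
#'
#' @param net an undirected igraph network.
#' @param path output path.
#' @param format one of `"edge-tsv"`, `"sif"`, `"graphml"`.
#' @return the path, invisibly.
#' @export
write_network <- function(net, path, format = c("edge-tsv", "sif", "graphml")) {
  if (length(format) == 1L && !format %in% c("edge-tsv", "sif", "graphml"))
    stop("unknown network format: ", format)
  format <- match.arg(format)
  el <- igraph::as_data_frame(net, what = "edges")
  if (format == "edge-tsv") {
    out <- data.frame(gene_a = pmin(el$from, el$to),
                      gene_b = pmax(el$from, el$to),
                      weight = sprintf("%.6f", el$weight),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    a <- pmin(el$from, el$to); b <- pmax(el$from, el$to)
    ord <- order(a, b)
    writeLines(paste(a[ord], "pp", b[ord]), path)
  } else {
    for (at in igraph::vertex_attr_names(net)) {
      v <- igraph::vertex_attr(net, at)
      if (is.character(v) && anyNA(v))
        net <- igraph::set_vertex_attr(net, at, value = ifelse(is.na(v), "", v))
      if (is.logical(v))
        net <- igraph::set_vertex_attr(net, at, value = as.integer(v))
    }
    igraph::write_graph(net, path, format = "graphml")
  }
  invisible(path)
}
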