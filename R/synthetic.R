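#' Specification for the synthetic expression study
#'
#' Describes a seeded synthetic data set with known planted structure:
#' block-correlated gene modules, a tight quasi-isolated cluster emulating
#' the mtDNA-encoded sub-network, independent background genes,
#' transcription factors (half attached to modules, half free), planted
#' low-expression genes for the CPM filter, and multi-contrast fold-change
#' tables with a planted consistently-signed subset.
#'
#' Defaults are the package's reference study conditions: 5 modules of 20
#' genes at within-module correlation 0.85, 40 background genes (5 of them
#' low-expression), a 28-gene isolated cluster at 0.95, 20 TFs, 200
#' samples and 6 contrasts.
#'
#' @param n_samples number of samples (columns); at least 3.
#' @param modules data.frame with columns `size` (positive integers) and
#'   `rho` (within-module correlation, in \[0, 1)). One row per module.
#' @param n_background_genes independent background genes.
#' @param isolated_cluster_size size of the quasi-isolated cluster
#'   (zero cross-correlation to everything else).
#' @param isolated_rho within-cluster correlation of the isolated block.
#' @param tf_count number of transcription-factor genes; `floor(tf_count/2)`
#'   of them are attached round-robin to the modules (sharing the module's
#'   correlation), the rest are independent.
#' @param n_contrasts number of fold-change contrasts (default 6).
#' @param consistent_gene_fraction fraction of genes planted with the same
#'   fold-change sign in every contrast.
#' @param n_low_genes number of background genes planted below 1 CPM in
#'   most samples (must not exceed `n_background_genes`).
#' @param seed integer seed; all generator outputs are deterministic in it.
#' @return an object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_samples = 200,
                           modules = data.frame(size = rep(20L, 5),
                                                rho = rep(0.85, 5)),
                           n_background_genes = 40,
                           isolated_cluster_size = 28,
                           isolated_rho = 0.95,
                           tf_count = 20,
                           n_contrasts = 6,
                           consistent_gene_fraction = 0.1,
                           n_low_genes = 5,
                           seed = 1) {
  if (!is_count(n_samples, min = 3L))
    stop("`n_samples` must be an integer >= 3 (correlation is degenerate below that)")
  if (!is.data.frame(modules) || !all(c("size", "rho") %in% names(modules)))
    stop("`modules` must be a data.frame with columns `size` and `rho`")
  if (nrow(modules) > 0) {
    if (!all(vapply(modules$size, is_count, logical(1), min = 1L)))
      stop("module sizes must be positive integers")
    if (any(modules$rho < 0 | modules$rho >= 1))
      stop("module `rho` must lie in [0, 1): rho = 1 is not positive definite")
  }
  if (!is_count(n_background_genes)) stop("`n_background_genes` must be a non-negative integer")
  if (!is_count(isolated_cluster_size)) stop("`isolated_cluster_size` must be a non-negative integer")
  if (isolated_rho < 0 || isolated_rho >= 1)
    stop("`isolated_rho` must lie in [0, 1)")
  if (!is_count(tf_count)) stop("`tf_count` must be a non-negative integer")
  if (!is_count(n_contrasts, min = 1L)) stop("`n_contrasts` must be a positive integer")
  if (consistent_gene_fraction < 0 || consistent_gene_fraction > 1)
    stop("`consistent_gene_fraction` must lie in [0, 1]")
  if (!is_count(n_low_genes)) stop("`n_low_genes` must be a non-negative integer")
  if (n_low_genes > n_background_genes)
    stop("`n_low_genes` cannot exceed `n_background_genes`")
  if (!is_count(abs(seed))) stop("`seed` must be an integer")
  structure(
    list(n_samples = as.integer(n_samples), modules = modules,
         n_background_genes = as.integer(n_background_genes),
         isolated_cluster_size = as.integer(isolated_cluster_size),
         isolated_rho = isolated_rho, tf_count = as.integer(tf_count),
         n_contrasts = as.integer(n_contrasts),
         consistent_gene_fraction = consistent_gene_fraction,
         n_low_genes = as.integer(n_low_genes), seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic study specification\n")
  cat(sprintf("  samples: %d   seed: %d\n", x$n_samples, x$seed))
  cat(sprintf("  modules: %d (sizes %s; rho %s)\n", nrow(x$modules),
              paste(x$modules$size, collapse = ","),
              paste(x$modules$rho, collapse = ",")))
  cat(sprintf("  background: %d (low-expression: %d)   isolated: %d (rho %.2f)   TFs: %d\n",
              x$n_background_genes, x$n_low_genes,
              x$isolated_cluster_size, x$isolated_rho, x$tf_count))
  cat(sprintf("  contrasts: %d   consistent fraction: %.2f\n",
              x$n_contrasts, x$consistent_gene_fraction))
  invisible(x)
}

total_genes <- function(spec) {
  sum(spec$modules$size) + spec$n_background_genes +
    spec$isolated_cluster_size + spec$tf_count
}

# Deterministic gene-id layout and block assignment for a spec.
# TFs attached to modules keep block = the module id but type = "tf".
synthetic_layout <- function(spec) {
  n_mod <- nrow(spec$modules)
  ids <- character(0); block <- character(0); type <- character(0)
  for (k in seq_len(n_mod)) {
    g <- sprintf("MOD%d_G%03d", k, seq_len(spec$modules$size[k]))
    ids <- c(ids, g)
    block <- c(block, rep(sprintf("module%d", k), length(g)))
    type <- c(type, rep("module", length(g)))
  }
  if (spec$n_background_genes > 0) {
    g <- sprintf("BG_G%03d", seq_len(spec$n_background_genes))
    ids <- c(ids, g)
    block <- c(block, rep("background", length(g)))
    type <- c(type, rep("background", length(g)))
  }
  if (spec$isolated_cluster_size > 0) {
    g <- sprintf("MT_G%03d", seq_len(spec$isolated_cluster_size))
    ids <- c(ids, g)
    block <- c(block, rep("isolated", length(g)))
    type <- c(type, rep("isolated", length(g)))
  }
  if (spec$tf_count > 0) {
    g <- sprintf("TF_G%03d", seq_len(spec$tf_count))
    n_att <- if (n_mod > 0) spec$tf_count %/% 2L else 0L
    b <- rep("tf_background", spec$tf_count)
    if (n_att > 0)
      b[seq_len(n_att)] <- sprintf("module%d", ((seq_len(n_att) - 1L) %% n_mod) + 1L)
    ids <- c(ids, g)
    block <- c(block, b)
    type <- c(type, rep("tf", length(g)))
  }
  data.frame(gene_id = ids, block = block, type = type,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic expression matrix with planted correlation modules
#'
#' Draws gene expression in log space from a block-structured covariance —
#' within each module a compound-symmetric correlation `rho` (one shared
#' latent factor per block), zero correlation across blocks, the isolated
#' cluster correlated only among itself — then exponentiates, yielding
#' non-negative FPKM-like values with log-normal marginals (sdlog 0.5,
#' log-means uniform on \[log 1, log 400\]).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expression` (genes x samples matrix) and `catalog`
#'   (data.frame with `gene_id`, `block`, `is_anchor`, `is_tf`,
#'   `is_organelle_encoded`, `localization`). Module and isolated-cluster
#'   genes are anchors; isolated genes are flagged organelle-encoded.
#'   Deterministic for a fixed seed.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lay <- synthetic_layout(spec)
  n_genes <- nrow(lay)
  if (n_genes == 0L) stop("spec describes zero genes")
  n <- spec$n_samples

  z <- matrix(0, nrow = n_genes, ncol = n,
              dimnames = list(lay$gene_id, sprintf("S%03d", seq_len(n))))
  with_seed(spec$seed, {
    blocks <- unique(lay$block)
    for (b in blocks) {
      rows <- which(lay$block == b)
      rho <- if (startsWith(b, "module")) {
        k <- as.integer(sub("module", "", b))
        spec$modules$rho[k]
      } else if (b == "isolated") {
        spec$isolated_rho
      } else 0
      if (rho > 0 && length(rows) > 1L) {
        f <- rnorm(n)
        e <- matrix(rnorm(length(rows) * n), nrow = length(rows))
        z[rows, ] <- sqrt(rho) * rep(f, each = length(rows)) +
          sqrt(1 - rho) * e
      } else {
        z[rows, ] <- matrix(rnorm(length(rows) * n), nrow = length(rows))
      }
    }
    mu <- runif(n_genes, log(1), log(400))
    expr <- exp(mu + 0.5 * z)

    loc_classes <- c("matrix", "inner membrane", "intermembrane space",
                     "outer membrane", "membrane", "unknown")
    is_anchor <- lay$type %in% c("module", "isolated")
    localization <- rep("unknown", n_genes)
    nuc <- which(lay$type == "module")
    localization[nuc] <- sample(loc_classes, length(nuc), replace = TRUE)
    localization[lay$type == "isolated"] <- "inner membrane"

    catalog <- data.frame(
      gene_id = lay$gene_id, block = lay$block,
      is_anchor = is_anchor, is_tf = lay$type == "tf",
      is_organelle_encoded = lay$type == "isolated",
      localization = localization, stringsAsFactors = FALSE)
    list(expression = expr, catalog = catalog)
  })
}

#' Generate a synthetic count matrix with planted low-expression genes
#'
#' Poisson counts with heterogeneous library sizes (uniform on
#' \[0.5e6, 2e6\]). All genes have expected expression of at least 10 CPM
#' except the planted low-expression genes (the first `n_low_genes`
#' background genes), whose expected rate is 0.05 CPM — below 1 CPM in far
#' more than half of the samples, so they are the CPM filter's casualties.
#'
#' @param spec a [synthetic_spec()].
#' @return integer count matrix (genes x samples) with attribute
#'   `"low_genes"` naming the planted low-expression genes.
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  lay <- synthetic_layout(spec)
  n_genes <- nrow(lay)
  if (n_genes == 0L) stop("spec describes zero genes")
  n <- spec$n_samples
  low <- character(0)
  if (spec$n_low_genes > 0)
    low <- lay$gene_id[lay$block == "background"][seq_len(spec$n_low_genes)]
  with_seed(spec$seed + 1L, {
    lib <- round(runif(n, 5e5, 2e6))
    rate_cpm <- runif(n_genes, 10, 500)
    rate_cpm[lay$gene_id %in% low] <- 0.05
    lambda <- outer(rate_cpm, lib) / 1e6
    counts <- matrix(rpois(n_genes * n, lambda), nrow = n_genes,
                     dimnames = list(lay$gene_id, sprintf("S%03d", seq_len(n))))
    storage.mode(counts) <- "integer"
    attr(counts, "low_genes") <- low
    counts
  })
}

#' Generate a synthetic multi-contrast fold-change table
#'
#' Produces a long-format table of log2 fold changes per gene per contrast.
#' A seeded fraction of genes is planted "consistent": the same sign (drawn
#' per gene) in every contrast, with magnitude uniform on \[0.3, 2.5\], and
#' flagged differentially expressed (`is_de = TRUE`) in every contrast.
#' The remaining genes get independent N(0, 1) fold changes per contrast
#' and per-(gene, contrast) DE flags at rate 0.3.
#'
#' @param spec a [synthetic_spec()]; `n_contrasts` and
#'   `consistent_gene_fraction` are used.
#' @param genes character vector of gene ids (non-empty).
#' @return data.frame with columns `gene_id`, `contrast_id` (`"C1"` ...),
#'   `log2fc`, `is_de`, plus attribute `"planted"`: a data.frame of the
#'   planted genes and their direction (`"up"`/`"down"`).
#' @export
generate_overlay <- function(spec, genes) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(genes) == 0L) stop("`genes` must be non-empty")
  if (anyDuplicated(genes)) stop("duplicate gene ids")
  k <- spec$n_contrasts
  contrasts <- sprintf("C%d", seq_len(k))
  with_seed(spec$seed + 2L, {
    n_cons <- round(spec$consistent_gene_fraction * length(genes))
    planted <- if (n_cons > 0) sort(sample(genes, n_cons)) else character(0)
    sign_p <- if (n_cons > 0) sample(c(1, -1), n_cons, replace = TRUE) else numeric(0)

    lfc <- matrix(rnorm(length(genes) * k), nrow = length(genes),
                  dimnames = list(genes, contrasts))
    de <- matrix(rbinom(length(genes) * k, 1L, 0.3) == 1L,
                 nrow = length(genes), dimnames = list(genes, contrasts))
    if (n_cons > 0) {
      mag <- matrix(runif(n_cons * k, 0.3, 2.5), nrow = n_cons)
      lfc[planted, ] <- sign_p * mag
      de[planted, ] <- TRUE
    }
    out <- data.frame(
      gene_id = rep(genes, times = k),
      contrast_id = rep(contrasts, each = length(genes)),
      log2fc = as.vector(lfc), is_de = as.vector(de),
      stringsAsFactors = FALSE)
    out <- out[order(out$gene_id, out$contrast_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "planted") <- data.frame(
      gene_id = planted,
      direction = ifelse(sign_p > 0, "up", "down"),
      stringsAsFactors = FALSE)
    out
  })
}

#' Recovery of planted correlation modules by an edge list
#'
#' Measures how well a thresholded edge list recovers the generator's
#' planted structure: recall of within-module gene pairs (over all module
#' blocks, attached TFs included) and the fraction of cross-block gene
#' pairs that wrongly appear as edges.
#'
#' @param edges edge-list data.frame from [threshold_edges()].
#' @param catalog generator catalog (from [generate_expression()]).
#' @param genes optional gene-id vector: restrict the evaluation to the
#'   genes that actually entered the analysis (e.g. the anchor set).
#' @return list with `within_module_recall`, `cross_module_false_edge_rate`,
#'   `n_within_pairs`, `n_cross_pairs`, `n_edges`.
#' @export
planted_module_metrics <- function(edges, catalog, genes = NULL) {
  stopifnot(is.data.frame(edges), is.data.frame(catalog))
  if (!is.null(genes))
    catalog <- catalog[catalog$gene_id %in% genes, , drop = FALSE]
  blk <- catalog$block
  names(blk) <- catalog$gene_id
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  edge_keys <- key(edges$gene_a, edges$gene_b)

  mods <- unique(blk[startsWith(blk, "module")])
  within_pairs <- character(0)
  for (m in mods) {
    g <- sort(catalog$gene_id[blk == m])
    if (length(g) > 1L) {
      cmb <- utils::combn(g, 2L)
      within_pairs <- c(within_pairs, key(cmb[1L, ], cmb[2L, ]))
    }
  }
  recall <- if (length(within_pairs)) mean(within_pairs %in% edge_keys) else NA_real_

  # cross-block pairs among all cataloged genes
  g <- catalog$gene_id
  cmb <- utils::combn(g, 2L)
  cross <- blk[cmb[1L, ]] != blk[cmb[2L, ]]
  cross_keys <- key(cmb[1L, cross], cmb[2L, cross])
  false_rate <- if (length(cross_keys)) mean(cross_keys %in% edge_keys) else NA_real_

  list(within_module_recall = recall,
       cross_module_false_edge_rate = false_rate,
       n_within_pairs = length(within_pairs),
       n_cross_pairs = length(cross_keys),
       n_edges = nrow(edges))
}
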