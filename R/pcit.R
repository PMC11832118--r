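#' Pairwise correlation matrix of an expression matrix
#'
#' Computes the product-moment (Pearson) correlation between every pair of
#' genes across samples. Rows are genes, columns samples, as produced by
#' [read_expression()] or [generate_expression()].
#'
#' @param expr numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns. At least 3 samples are required.
#' @return symmetric correlation matrix with unit diagonal, gene ids as
#'   dimnames.
#' @examples
#' x <- matrix(rnorm(40), nrow = 4, dimnames = list(paste0("g", 1:4), NULL))
#' r <- correlation_matrix(x)
#' stopifnot(isSymmetric(r), all(diag(r) == 1))
#' @export
correlation_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix (genes x samples)")
  if (ncol(expr) < 3L)
    stop("correlation requires at least 3 samples, got ", ncol(expr))
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("g%d", seq_len(nrow(expr)))
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene ids in expression matrix")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(expr)[v == 0]
    stop_mitonet(
      paste0("zero-variance gene(s): ", paste(bad, collapse = ", "),
             "; drop constant transcripts before correlating"),
      class = "mitonet_zero_variance", genes = bad)
  }
  r <- stats::cor(t(expr))
  diag(r) <- 1
  r
}

validate_correlation <- function(r) {
  if (!is.matrix(r) || !is.numeric(r) || nrow(r) != ncol(r))
    stop("correlation input must be a square numeric matrix")
  if (nrow(r) < 2L)
    stop("need at least 2 genes")
  if (is.null(rownames(r))) {
    rownames(r) <- colnames(r) <- sprintf("g%d", seq_len(nrow(r)))
  }
  if (!isSymmetric(unname(r), tol = 1e-10))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(r) - 1) > 1e-10))
    stop("correlation matrix must have unit diagonal")
  off <- abs(r[upper.tri(r)])
  if (any(off > 1 + 1e-12))
    stop("correlation magnitudes exceed 1")
  if (any(off >= 1)) {
    stop_mitonet(
      "off-diagonal |r| = 1 found; deduplicate perfectly collinear genes before PCIT",
      class = "mitonet_collinear")
  }
  # exact symmetry so canonical reordering is bitwise-stable
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  diag(r) <- 1
  r
}

#' PCIT significance screen over a correlation matrix
#'
#' Applies the partial correlation and information theory (PCIT)
#' trio-elimination rule: for every unordered gene trio (x, y, z) the three
#' first-order partial correlations
#' \deqn{r_{xy.z} = \frac{r_{xy} - r_{xz} r_{yz}}
#'   {\sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}}}
#' define the trio tolerance
#' \deqn{\epsilon = \frac{1}{3}\left(\left|\frac{r_{xy.z}}{r_{xy}}\right| +
#'   \left|\frac{r_{xz.y}}{r_{xz}}\right| +
#'   \left|\frac{r_{yz.x}}{r_{yz}}\right|\right)}
#' and pair (x, y) is eliminated within the trio iff
#' \eqn{|r_{xy}| \le |\epsilon r_{xz}|} and
#' \eqn{|r_{xy}| \le |\epsilon r_{yz}|}. A pair is significant overall iff
#' no trio eliminates it. Ratios whose direct correlation has magnitude
#' below 1e-12 contribute 0 to the tolerance, and a trio whose tolerance is
#' exactly 0 eliminates nothing; with only 2 genes no trio exists and both
#' pairs are (vacuously) significant.
#'
#' Gene order is canonicalised (sorted ids) before trio enumeration, so the
#' result is independent of input ordering down to the last bit.
#'
#' @param corr symmetric correlation matrix with unit diagonal (e.g. from
#'   [correlation_matrix()]). Off-diagonal \eqn{|r| = 1} is an error.
#' @return an object of class `"pcit"`: a list with `genes`, `correlation`
#'   (the input, original order), `significant` (symmetric logical mask,
#'   diagonal `FALSE`).
#' @seealso [pcit()] for the expression-matrix front end,
#'   [pcit_brute_force()] for the reference implementation,
#'   [threshold_edges()] to extract the edge list.
#' @export
pcit_significance <- function(corr) {
  r <- validate_correlation(corr)
  ids <- rownames(r)
  ord <- order(ids)
  rs <- r[ord, ord, drop = FALSE]
  mask <- .pcit_mask_cpp(rs)
  inv <- order(ord)
  mask <- mask[inv, inv, drop = FALSE]
  dimnames(mask) <- list(ids, ids)
  structure(
    list(genes = ids, correlation = r, significant = mask,
         n_genes = length(ids), call = sys.call()),
    class = "pcit")
}

#' Fit a PCIT co-expression screen to an expression matrix
#'
#' Convenience front end: computes the pairwise correlation matrix with
#' [correlation_matrix()] and runs the PCIT trio-elimination screen with
#' [pcit_significance()].
#'
#' @inheritParams correlation_matrix
#' @return an object of class `"pcit"`; see [pcit_significance()].
#' @examples
#' sim <- generate_expression(synthetic_spec(
#'   n_samples = 50, modules = data.frame(size = 6, rho = 0.9),
#'   n_background_genes = 6, isolated_cluster_size = 0, tf_count = 0,
#'   seed = 1))
#' fit <- pcit(sim$expression)
#' fit
#' edges <- threshold_edges(fit, cutoff = 0.7)
#' @export
pcit <- function(expr) {
  fit <- pcit_significance(correlation_matrix(expr))
  fit$n_samples <- ncol(expr)
  fit$call <- sys.call()
  fit
}

#' Brute-force PCIT reference implementation
#'
#' Identical contract to [pcit_significance()], implemented as three nested
#' explicit loops in plain R with no algebraic shortcuts. Intended as an
#' independent oracle: on any input its significance mask equals the
#' vectorized implementation's mask exactly.
#'
#' @inheritParams pcit_significance
#' @return an object of class `"pcit"`.
#' @export
pcit_brute_force <- function(corr) {
  r <- validate_correlation(corr)
  ids <- rownames(r)
  ord <- order(ids)
  rs <- r[ord, ord, drop = FALSE]
  n <- nrow(rs)
  elim <- matrix(FALSE, n, n)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      for (j in seq.int(i + 1L, n - 1L)) {
        for (k in seq.int(j + 1L, n)) {
          rij <- rs[i, j]; rik <- rs[i, k]; rjk <- rs[j, k]
          pij <- (rij - rik * rjk) / sqrt((1 - rik * rik) * (1 - rjk * rjk))
          pik <- (rik - rij * rjk) / sqrt((1 - rij * rij) * (1 - rjk * rjk))
          pjk <- (rjk - rij * rik) / sqrt((1 - rij * rij) * (1 - rik * rik))
          t1 <- if (abs(rij) < 1e-12) 0 else abs(pij / rij)
          t2 <- if (abs(rik) < 1e-12) 0 else abs(pik / rik)
          t3 <- if (abs(rjk) < 1e-12) 0 else abs(pjk / rjk)
          eps <- (t1 + t2 + t3) / 3
          if (eps > 0) {
            if (abs(rij) <= abs(eps * rik) && abs(rij) <= abs(eps * rjk))
              elim[i, j] <- elim[j, i] <- TRUE
            if (abs(rik) <= abs(eps * rij) && abs(rik) <= abs(eps * rjk))
              elim[i, k] <- elim[k, i] <- TRUE
            if (abs(rjk) <= abs(eps * rij) && abs(rjk) <= abs(eps * rik))
              elim[j, k] <- elim[k, j] <- TRUE
          }
        }
      }
    }
  }
  mask <- !elim
  diag(mask) <- FALSE
  inv <- order(ord)
  mask <- mask[inv, inv, drop = FALSE]
  dimnames(mask) <- list(ids, ids)
  structure(
    list(genes = ids, correlation = r, significant = mask,
         n_genes = length(ids), call = sys.call()),
    class = "pcit")
}

#' Trio tolerance of a single PCIT trio
#'
#' The data-driven tolerance \eqn{\epsilon} for one gene trio given its
#' three pairwise correlations; mainly useful for worked examples.
#'
#' @param r_xy,r_xz,r_yz pairwise correlations of the trio, each with
#'   magnitude strictly below 1.
#' @return the tolerance \eqn{\epsilon} (scalar).
#' @examples
#' trio_tolerance(0.9, 0.8, 0.6)  # ~0.88965
#' @export
trio_tolerance <- function(r_xy, r_xz, r_yz) {
  stopifnot(abs(r_xy) < 1, abs(r_xz) < 1, abs(r_yz) < 1)
  pxy <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  pxz <- (r_xz - r_xy * r_yz) / sqrt((1 - r_xy^2) * (1 - r_yz^2))
  pyz <- (r_yz - r_xy * r_xz) / sqrt((1 - r_xy^2) * (1 - r_xz^2))
  t1 <- if (abs(r_xy) < 1e-12) 0 else abs(pxy / r_xy)
  t2 <- if (abs(r_xz) < 1e-12) 0 else abs(pxz / r_xz)
  t3 <- if (abs(r_yz) < 1e-12) 0 else abs(pyz / r_yz)
  (t1 + t2 + t3) / 3
}

#' Threshold PCIT-significant correlations into an edge list
#'
#' Keeps the significant pairs whose correlation magnitude reaches the
#' cutoff (0.7 by default, inclusive), as an undirected edge list with the
#' signed correlation as weight.
#'
#' @param fit a `"pcit"` object.
#' @param cutoff correlation-magnitude cutoff, strictly between 0 and 1.
#' @param inclusive keep edges with \eqn{|r| \ge} cutoff (default); if
#'   `FALSE`, strictly greater.
#' @param keep_negative if `FALSE`, drop negative-weight edges after
#'   thresholding.
#' @return data.frame with columns `gene_a`, `gene_b` (lexicographically
#'   `gene_a < gene_b`), `weight`; sorted by (`gene_a`, `gene_b`); the
#'   cutoff is attached as attribute `"cutoff"`.
#' @export
threshold_edges <- function(fit, cutoff = 0.7, inclusive = TRUE,
                            keep_negative = TRUE) {
  if (!inherits(fit, "pcit")) stop("`fit` must be a 'pcit' object")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    stop("`cutoff` must lie strictly between 0 and 1")
  r <- fit$correlation
  keep <- fit$significant &
    (if (inclusive) abs(r) >= cutoff else abs(r) > cutoff)
  if (!keep_negative) keep <- keep & r > 0
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  ids <- fit$genes
  a <- ids[idx[, 1L]]
  b <- ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, weight = r[idx],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' @export
print.pcit <- function(x, ...) {
  np <- x$n_genes * (x$n_genes - 1) / 2
  ns <- sum(x$significant[upper.tri(x$significant)])
  cat("PCIT co-expression screen\n")
  cat(sprintf("  genes:             %d\n", x$n_genes))
  if (!is.null(x$n_samples))
    cat(sprintf("  samples:           %d\n", x$n_samples))
  cat(sprintf("  pairs tested:      %d\n", np))
  cat(sprintf("  significant pairs: %d (%.1f%%)\n", ns, 100 * ns / max(np, 1)))
  invisible(x)
}

#' @export
summary.pcit <- function(object, cutoff = 0.7, ...) {
  up <- upper.tri(object$significant)
  sig <- object$significant[up]
  r <- object$correlation[up]
  edges <- sum(sig & abs(r) >= cutoff)
  out <- list(
    n_genes = object$n_genes, n_samples = object$n_samples,
    pairs = length(r), significant = sum(sig),
    cutoff = cutoff, edges_at_cutoff = edges,
    abs_r_quartiles = stats::quantile(abs(r), c(0.25, 0.5, 0.75)),
    abs_r_significant_quartiles =
      if (any(sig)) stats::quantile(abs(r[sig]), c(0.25, 0.5, 0.75)) else NULL)
  class(out) <- "summary.pcit"
  out
}

#' @export
print.summary.pcit <- function(x, ...) {
  cat("PCIT co-expression screen\n")
  cat(sprintf("  genes: %d   pairs: %d   significant: %d\n",
              x$n_genes, x$pairs, x$significant))
  cat(sprintf("  edges at |r| >= %.2f: %d\n", x$cutoff, x$edges_at_cutoff))
  cat("  |r| quartiles (all pairs):        ",
      paste(sprintf("%.3f", x$abs_r_quartiles), collapse = "  "), "\n")
  if (!is.null(x$abs_r_significant_quartiles))
    cat("  |r| quartiles (significant pairs):",
        paste(sprintf("%.3f", x$abs_r_significant_quartiles), collapse = "  "),
        "\n")
  invisible(x)
}

#' @export
coef.pcit <- function(object, ...) object$correlation

#' Histogram of pairwise correlations, significant pairs highlighted
#'
#' @param x a `"pcit"` object.
#' @param breaks passed to [graphics::hist()].
#' @param ... further arguments passed to [graphics::hist()].
#' @export
plot.pcit <- function(x, breaks = 50, ...) {
  up <- upper.tri(x$significant)
  r <- x$correlation[up]
  sig <- x$significant[up]
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  graphics::hist(r, breaks = h$breaks, col = "grey80", border = "grey60",
                 main = "Pairwise correlations", xlab = "r", ...)
  if (any(sig))
    graphics::hist(r[sig], breaks = h$breaks, col = "orange",
                   border = "grey40", add = TRUE)
  graphics::legend("topleft", fill = c("grey80", "orange"),
                   legend = c("all pairs", "PCIT-significant"), bty = "n")
  invisible(x)
}
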