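# Shared fixtures and independent oracles for the test suite.

# Random valid correlation matrix: correlations of a random data draw, so
# symmetry/unit-diagonal/|r|<1 hold by construction.
random_corr <- function(n, seed, n_samples = 40) {
  set.seed(seed)
  x <- matrix(rnorm(n * n_samples), nrow = n)
  rownames(x) <- sprintf("g%03d", sample(n))  # scrambled ids on purpose
  correlation_matrix(x)
}

star_edges <- function(n_leaves, center = "hub") {
  leaves <- sprintf("leaf%02d", seq_len(n_leaves))
  data.frame(gene_a = pmin(center, leaves), gene_b = pmax(center, leaves),
             weight = 0.9, stringsAsFactors = FALSE)
}

complete_edges <- function(n) {
  ids <- sprintf("n%02d", seq_len(n))
  cmb <- combn(ids, 2)
  data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ], weight = 0.8,
             stringsAsFactors = FALSE)
}

# Random connected graph: a random spanning tree plus extra random edges.
random_connected_edges <- function(n, seed, extra = n) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  a <- character(0); b <- character(0)
  for (i in 2:n) {               # attach each node to an earlier one
    j <- sample(i - 1L, 1L)
    a <- c(a, ids[j]); b <- c(b, ids[i])
  }
  for (k in seq_len(extra)) {
    p <- sample(n, 2L)
    a <- c(a, ids[p[1L]]); b <- c(b, ids[p[2L]])
  }
  df <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                   weight = 1, stringsAsFactors = FALSE)
  df <- df[df$gene_a != df$gene_b, ]
  df <- df[!duplicated(df[, 1:2]), ]
  rownames(df) <- NULL
  df
}

# Brute-force all-pairs shortest paths by BFS over an edge data.frame;
# independent of igraph. Returns a distance matrix (Inf across components).
bfs_distances <- function(edges) {
  ids <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- lapply(setNames(vector("list", length(ids)), ids), function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  for (s in ids) {
    d[s, s] <- 0
    frontier <- s
    dist <- 0
    while (length(frontier) > 0) {
      dist <- dist + 1
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(d[s, nxt])]
      d[s, nxt] <- dist
      frontier <- nxt
    }
  }
  d
}

# Radiality recomputed from BFS distances (the reference definition).
radiality_oracle <- function(edges) {
  d <- bfs_distances(edges)
  ids <- rownames(d)
  out <- setNames(rep(NA_real_, length(ids)), ids)
  seen <- character(0)
  for (s in ids) {
    if (s %in% seen) next
    comp <- ids[is.finite(d[s, ])]
    seen <- c(seen, comp)
    if (length(comp) < 2) next
    sub <- d[comp, comp, drop = FALSE]
    delta <- max(sub)
    for (v in comp)
      out[v] <- (delta + 1 - sum(sub[v, ]) / (length(comp) - 1)) / delta
  }
  out
}

tiny_spec <- function(seed = 7) {
  synthetic_spec(
    n_samples = 60,
    modules = data.frame(size = c(8, 8), rho = c(0.85, 0.85)),
    n_background_genes = 10, isolated_cluster_size = 6, tf_count = 6,
    n_low_genes = 3, seed = seed)
}
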