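test_that("build_tf_gene_set labels anchor-only, tf-only and dual genes", {
  out <- build_tf_gene_set(c("a", "b"), c("b", "c"))
  expect_equal(out$gene_id, c("a", "b", "c"))
  expect_equal(out$label, c("anchor-only", "both", "tf-only"))
  disj <- build_tf_gene_set(c("a", "b"), c("c", "d"))
  expect_equal(nrow(disj), 4)
  expect_error(build_tf_gene_set(character(0), "t"), "empty")
})

test_that("the TF filter removes exactly the TFs with more TF than anchor neighbors", {
  # t1: 3 TF-neighbors, 2 anchors -> excluded; t2: 2/2 -> retained;
  # t3: anchors only -> retained; d1 ("both") never removed
  e <- data.frame(
    gene_a = c("t1", "t1", "t1", "t1", "t1", "t2", "t2", "t2",
               "t3", "t3", "d1", "d1"),
    gene_b = c("t2", "t4", "t5", "m1", "m2", "t4", "m3", "m4",
               "m1", "m5", "t4", "m2"),
    weight = 0.9)
  labels <- build_tf_gene_set(
    anchor = c("m1", "m2", "m3", "m4", "m5", "d1"),
    tfs = c("t1", "t2", "t3", "t4", "t5", "d1"))
  net <- build_network(e)
  out <- filter_tf_nodes(net, labels)
  rep <- out$report
  expect_false(rep$retained[rep$tf_id == "t1"])
  expect_equal(rep[rep$tf_id == "t1", c("n_tf", "n_mito")],
               data.frame(n_tf = 3L, n_mito = 2L,
                          row.names = which(rep$tf_id == "t1")))
  expect_true(rep$retained[rep$tf_id == "t2"])   # equality retains
  expect_true(rep$retained[rep$tf_id == "t3"])
  expect_true(rep$retained[rep$tf_id == "d1"])   # dual gene exempt
  expect_false("t1" %in% igraph::V(out$network)$name)
  expect_true(all(c("m1", "m2") %in% igraph::V(out$network)$name))
})

test_that("filtering is single-pass: counts come from the unfiltered graph", {
  # chain m1 - t1 - t2 - t3 - {t4, t5}: under iterated re-evaluation t4/t5
  # would be re-admitted once t3 disappears; single-pass excludes them on
  # the unfiltered counts
  e <- data.frame(gene_a = c("m1", "t1", "t2", "t3", "t3"),
                  gene_b = c("t1", "t2", "t3", "t4", "t5"),
                  weight = 0.8)
  labels <- build_tf_gene_set(anchor = "m1", tfs = c("t1", "t2", "t3", "t4", "t5"))
  out <- filter_tf_nodes(build_network(e), labels)
  rep <- out$report
  # t1: n_tf 1 (t2), n_mito 1 -> retained; t2: n_tf 2, n_mito 0 -> excluded
  expect_true(rep$retained[rep$tf_id == "t1"])
  expect_false(rep$retained[rep$tf_id == "t2"])
  expect_false(rep$retained[rep$tf_id == "t3"])
  # t4/t5 are leaves of t3 with zero anchors but zero TF-only links beyond t3
  expect_false(rep$retained[rep$tf_id == "t4"])  # 1 TF neighbor > 0 anchors
  # single pass: the decision for t1 did not change although t2 vanished
  expect_true("t1" %in% igraph::V(out$network)$name)
})

test_that("filter invariants hold on random labeled graphs", {
  for (s in 1:10) {
    e <- random_connected_edges(18, seed = 300 + s, extra = 25)
    ids <- sort(unique(c(e$gene_a, e$gene_b)))
    set.seed(400 + s)
    lab <- sample(c("anchor-only", "tf-only", "both"), length(ids),
                  replace = TRUE, prob = c(0.5, 0.4, 0.1))
    names(lab) <- ids
    net <- build_network(e)
    out <- filter_tf_nodes(net, lab)
    rep <- out$report
    # recount neighbor profiles independently from the edge list
    for (i in seq_len(nrow(rep))) {
      t <- rep$tf_id[i]
      nb <- c(e$gene_b[e$gene_a == t], e$gene_a[e$gene_b == t])
      expect_equal(rep$n_tf[i], sum(lab[nb] == "tf-only"))
      expect_equal(rep$n_mito[i], sum(lab[nb] %in% c("anchor-only", "both")))
      if (rep$label[i] == "tf-only") {
        expect_equal(rep$retained[i], rep$n_tf[i] <= rep$n_mito[i])
      } else {
        expect_true(rep$retained[i])
      }
    }
    # anchor-side nodes survive
    anchors <- ids[lab[ids] == "anchor-only"]
    expect_true(all(anchors %in% igraph::V(out$network)$name))
    # order independence: permuting the edge list changes nothing
    ep <- e[sample(nrow(e)), ]
    out2 <- filter_tf_nodes(build_network(ep), lab)
    expect_equal(out2$report, rep)
  }
})

test_that("a TF planted inside a tight module outranks free TFs", {
  spec <- synthetic_spec(
    n_samples = 120, modules = data.frame(size = 10, rho = 0.9),
    n_background_genes = 6, isolated_cluster_size = 0, tf_count = 4,
    n_low_genes = 0, seed = 5)
  sim <- generate_expression(spec)
  cat <- sim$catalog
  anchor <- cat$gene_id[cat$is_anchor]
  tfs <- cat$gene_id[cat$is_tf]
  labels <- build_tf_gene_set(anchor, tfs)
  fit <- pcit(sim$expression)
  net <- build_network(threshold_edges(fit), cat)
  out <- filter_tf_nodes(net, labels)
  ranks <- rank_tf(out$network, labels)
  attached <- cat$gene_id[cat$is_tf & startsWith(cat$block, "module")]
  free <- setdiff(tfs, attached)
  expect_equal(ranks$by_degree$tf_id[1], attached[1])
  expect_gt(ranks$by_degree$degree[1], 0)
  free_deg <- ranks$by_degree$degree[ranks$by_degree$tf_id %in% free]
  expect_true(all(ranks$by_degree$degree[1] > free_deg))
  expect_true(all(c("by_radiality", "top_by_degree") %in% names(ranks)))
  expect_lte(nrow(ranks$top_by_degree), 20)
})
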