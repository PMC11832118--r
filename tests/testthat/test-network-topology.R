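test_that("build_network uses edge endpoints as the node set", {
  e <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"),
                  weight = c(0.8, 0.9, 0.75))
  net <- build_network(e)
  expect_equal(igraph::vcount(net), 4)
  expect_equal(igraph::ecount(net), 3)
  # isolated catalog genes never become nodes
  cat <- data.frame(gene_id = letters[1:6], block = "x", is_anchor = TRUE,
                    is_tf = FALSE, is_organelle_encoded = FALSE,
                    localization = "matrix")
  net2 <- build_network(e, cat)
  expect_equal(sort(igraph::V(net2)$name), c("a", "b", "c", "d"))
  expect_equal(unique(igraph::V(net2)$localization), "matrix")
  # unknown endpoints default, not error
  e3 <- rbind(e, data.frame(gene_a = "zz", gene_b = "a", weight = 0.71))
  net3 <- build_network(e3, cat)
  expect_equal(igraph::V(net3)$localization[igraph::V(net3)$name == "zz"],
               "unknown")
  expect_equal(igraph::vcount(build_network(e[0, ])), 0)
  expect_error(build_network(rbind(e, e[1, ])), "duplicate edge")
  expect_error(build_network(data.frame(gene_a = "a", gene_b = "a", weight = 1)),
               "self-edges")
})

test_that("degree obeys the star pattern and the handshake lemma", {
  net <- build_network(star_edges(7))
  d <- node_degree(net)
  expect_equal(unname(d$degree["hub"]), 7)
  expect_true(all(d$degree[names(d$degree) != "hub"] == 1))
  for (s in 1:5) {
    e <- random_connected_edges(20, seed = s)
    net <- build_network(e)
    expect_equal(sum(igraph::degree(net)), 2 * nrow(e))
  }
})

test_that("components come back largest-first with planted clusters intact", {
  tri1 <- data.frame(gene_a = c("a1", "a1", "a2"), gene_b = c("a2", "a3", "a3"),
                     weight = 1)
  tri2 <- data.frame(gene_a = c("b1", "b1", "b2"), gene_b = c("b2", "b3", "b3"),
                     weight = 1)
  pair <- data.frame(gene_a = "c1", gene_b = "c2", weight = 1)
  comp <- network_components(build_network(rbind(tri1, tri2, pair)))
  expect_equal(comp$count, 3)
  expect_equal(comp$sizes, c(3, 3, 2))
  expect_equal(comp$members[[1]], c("a1", "a2", "a3"))  # tie broken by id
  expect_equal(comp$members[[3]], c("c1", "c2"))        # exclusive doublet
  expect_equal(unname(comp$membership[c("b1", "c2")]), c(2, 3))
})

test_that("neighbors are the sorted adjacency set", {
  net <- build_network(star_edges(4))
  expect_equal(gene_neighbors(net, "hub"), sprintf("leaf%02d", 1:4))
  expect_equal(gene_neighbors(net, "leaf03"), "hub")
  expect_error(gene_neighbors(net, "nope"), "not in network")
})

test_that("radiality matches the closed-form star and complete-graph values", {
  star5 <- build_network(star_edges(4))     # 5 nodes
  rad <- radiality(star5)
  expect_equal(unname(rad["hub"]), 1.0)              # (2 + 1 - 1) / 2
  expect_equal(unname(rad["leaf01"]), 0.625)         # (3 - 1.75) / 2
  comp <- build_network(complete_edges(6))
  expect_true(all(radiality(comp) == 1))
  # radiality of a singleton-free bound: always within [0, 1]
  expect_true(all(rad >= 0 & rad <= 1))
})

test_that("radiality agrees with the brute-force shortest-path oracle", {
  for (s in 1:10) {
    n <- 5 + 3 * s
    e <- random_connected_edges(n, seed = 100 + s)
    net <- build_network(e)
    expect_equal(radiality(net), radiality_oracle(e)[igraph::V(net)$name],
                 tolerance = 1e-12)
  }
})

test_that("radiality is per-component and NA-free only off singletons", {
  e <- rbind(star_edges(3), data.frame(gene_a = "p1", gene_b = "p2", weight = 1))
  net <- build_network(e)
  rad <- radiality(net)
  expect_equal(unname(rad[c("p1", "p2")]), c(1, 1))  # doublet: delta 1
  expect_equal(radiality(net), radiality_oracle(e)[igraph::V(net)$name])
})

test_that("configuration-style hub graphs yield heavy-tailed degree histograms", {
  # one dominant hub plus sparse periphery: max/median degree >= 10
  set.seed(1)
  n <- 1000
  ids <- sprintf("v%04d", 1:n)
  hubs <- ids[1:5]
  a <- c(rep(hubs, each = 60),
         ids[sample(6:n, 400, replace = TRUE)])
  b <- ids[sample(6:n, length(a), replace = TRUE)]
  keep <- a != b
  e <- data.frame(gene_a = pmin(a, b)[keep], gene_b = pmax(a, b)[keep], weight = 1)
  e <- e[!duplicated(e[, 1:2]), ]
  net <- build_network(e)
  d <- igraph::degree(net)
  expect_gte(max(d) / median(d), 10)
})

test_that("topology_report aggregates degree, radiality and components coherently", {
  spec <- tiny_spec()
  sim <- generate_expression(spec)
  fit <- pcit(sim$expression)
  net <- build_network(threshold_edges(fit), sim$catalog)
  rep <- topology_report(net)
  expect_s3_class(rep, "topology_report")
  expect_equal(sum(rep$degree), 2 * rep$n_edges)
  expect_equal(sum(rep$component_sizes), rep$n_nodes)
  expect_equal(nrow(rep$nodes), rep$n_nodes)
  expect_true(all(rep$nodes$radiality >= 0 & rep$nodes$radiality <= 1,
                  na.rm = TRUE))
  expect_output(print(rep), "components")
})
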