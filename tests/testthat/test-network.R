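test_that("subnetwork extraction filters edges by the weight floor", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.9
  W["a", "c"] <- W["c", "a"] <- 0.6
  W["b", "c"] <- W["c", "b"] <- 0.4
  net <- weighted_network(c("a", "b", "c"), W)
  sub <- extract_subnetwork(net, c("a", "b", "c"), weight_floor = 0.5)
  expect_equal(nrow(sub$edges), 2)
  expect_true(all(sub$edges$weight >= 0.5))
  full <- extract_subnetwork(net, c("a", "b", "c"), weight_floor = 0)
  expect_equal(nrow(full$edges), 3)
})

test_that("isolation pruning drops selected genes with no admissible edge", {
  W <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  W["a", "b"] <- W["b", "a"] <- 0.8
  W["c", "d"] <- W["d", "c"] <- 0.3   # below the floor: c and d become isolated
  net <- weighted_network(letters[1:4], W)
  pruned <- extract_subnetwork(net, letters[1:4], weight_floor = 0.5)
  expect_equal(pruned$nodes, c("a", "b"))
  kept <- extract_subnetwork(net, letters[1:4], weight_floor = 0.5,
                             prune_isolated = FALSE)
  expect_equal(kept$nodes, letters[1:4])
  expect_warning(extract_subnetwork(net, c("a", "zz"), weight_floor = 0),
                 "not in the network")
})

test_that("subnetwork extraction is idempotent at a fixed floor", {
  set.seed(8)
  net <- random_network(30, density = 0.2)
  sub1 <- extract_subnetwork(net, net$genes[1:20], weight_floor = 0.4)
  net_sub <- weighted_network_from_edges(
    data.frame(gene1 = sub1$edges$gene1, gene2 = sub1$edges$gene2,
               weight = sub1$edges$weight), genes = sub1$nodes)
  sub2 <- extract_subnetwork(net_sub, sub1$nodes, weight_floor = 0.4)
  expect_equal(sub2$nodes, sub1$nodes)
  expect_equal(sub2$edges, sub1$edges)
})

test_that("k-core numbers match hand-peeled examples", {
  k4 <- structure(list(nodes = letters[1:4],
                       edges = data.frame(gene1 = c("a", "a", "a", "b", "b", "c"),
                                          gene2 = c("b", "c", "d", "c", "d", "d"),
                                          weight = 1)), class = "subnetwork")
  dec <- k_core_decompose(k4)
  expect_true(all(dec$core_number == 3))
  tp <- k_core_decompose(triangle_pendant_sub())
  expect_equal(dec_core <- unname(tp$core_number[c("a", "b", "c", "d")]),
               c(2, 2, 2, 1))
  empty <- structure(list(nodes = c("x", "y"),
                          edges = data.frame(gene1 = character(0),
                                             gene2 = character(0),
                                             weight = numeric(0))),
                     class = "subnetwork")
  expect_true(all(k_core_decompose(empty)$core_number == 0))
})

test_that("core layers partition the nodes and compose into k-cores", {
  tp <- k_core_decompose(triangle_pendant_sub())
  layers <- core_layers(tp)
  expect_equal(layers[["1"]], "d")
  expect_equal(layers[["2"]], c("a", "b", "c"))
  expect_setequal(unlist(layers), c("a", "b", "c", "d"))
  # the k-core is the union of layers j >= k
  expect_setequal(unlist(layers[as.integer(names(layers)) >= 2]),
                  c("a", "b", "c"))
})

test_that("peeling equals the maximal-subgraph oracle and ignores node order", {
  set.seed(9)
  for (rep_i in 1:25) {
    n <- sample(4:9, 1)
    sub <- random_graph_sub(n, stats::runif(1, 0.2, 0.7))
    dec <- k_core_decompose(sub)
    for (k in 1:max(1, dec$kmax)) {
      expected <- kcore_subset_oracle(sub$nodes, sub$edges, k)
      got <- sort(names(dec$core_number)[dec$core_number >= k], method = "radix")
      expect_equal(got, expected)
    }
    perm <- sample(length(sub$nodes))
    sub_perm <- structure(list(nodes = sub$nodes[perm], edges = sub$edges,
                               weight_floor = 0), class = "subnetwork")
    dec_perm <- k_core_decompose(sub_perm)
    expect_equal(dec_perm$core_number[sub$nodes], dec$core_number[sub$nodes])
    # cross-check against igraph's coreness
    g <- igraph::graph_from_data_frame(sub$edges[, 1:2], directed = FALSE,
                                       vertices = sub$nodes)
    expect_equal(unname(dec$core_number[igraph::V(g)$name]),
                 unname(igraph::coreness(g)))
  }
})

test_that("the k-core of the (k-1)-core equals the k-core of the graph", {
  set.seed(10)
  sub <- random_graph_sub(12, 0.35)
  dec <- k_core_decompose(sub)
  for (k in 2:max(2, dec$kmax)) {
    keep <- names(dec$core_number)[dec$core_number >= k - 1]
    e <- sub$edges[sub$edges$gene1 %in% keep & sub$edges$gene2 %in% keep, ]
    dec_sub <- k_core_decompose(structure(list(nodes = keep, edges = e),
                                          class = "subnetwork"))
    expect_setequal(names(dec_sub$core_number)[dec_sub$core_number >= k],
                    names(dec$core_number)[dec$core_number >= k])
  }
})

test_that("core-periphery partition assigns nodes by core-number cutpoints", {
  core <- stats::setNames(c(36L, 10L, 11L, 35L, 2L), sprintf("n%d", 1:5))
  dec <- structure(list(core_number = core, kmax = 36L),
                   class = "core_decomposition")
  part <- partition_core_periphery(dec, 10L, 35L)
  expect_equal(part$inner, "n1")
  expect_setequal(part$medium, c("n3", "n4"))
  expect_setequal(part$outer, c("n2", "n5"))
  expect_error(partition_core_periphery(dec, 20L, 10L), "cutpoints")
  tp <- k_core_decompose(triangle_pendant_sub())
  p2 <- partition_core_periphery(tp, 1L, 2L)
  expect_equal(p2$outer, "d")
  expect_setequal(p2$medium, c("a", "b", "c"))
  expect_length(p2$inner, 0)
})

test_that("layer composition counts tagged genes per layer", {
  tp <- k_core_decompose(triangle_pendant_sub())
  comp <- layer_composition(tp, list(seed = "d", drug = character(0)))
  expect_equal(comp$seed[comp$layer == 1], 1L)
  expect_equal(comp$seed[comp$layer == 2], 0L)
  expect_true(all(comp$drug == 0L))
  expect_equal(sum(comp$seed), 1L)        # counts conserve the tag overlap
  expect_equal(sum(comp$n_nodes), 4L)
})

test_that("membership annotation flags and counts reference nodes", {
  sub <- triangle_pendant_sub()
  expect_message(f0 <- annotate_membership(sub, c("zz"), "drug target"),
                 "0 of 4")
  expect_false(any(f0))
  expect_message(fa <- annotate_membership(sub, sub$nodes), "4 of 4")
  expect_true(all(fa))
  expect_message(f3 <- annotate_membership(sub, c("a", "b", "c", "q")), "3 of 4")
  expect_equal(sum(f3), 3)
})

test_that("GraphML export round-trips node and edge counts", {
  sub <- triangle_pendant_sub()
  path <- withr::local_tempfile(fileext = ".graphml")
  write_subnetwork_graphml(sub, path,
                           node_attrs = data.frame(gene = sub$nodes,
                                                   core = c(2, 2, 2, 1)))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)
  expect_setequal(igraph::V(g)$name, sub$nodes)
})
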