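path_net <- function(nodes) {
  g <- igraph::make_ring(length(nodes), circular = FALSE)
  igraph::V(g)$name <- nodes
  as_bionetwork(g)
}

test_that("DE-induced subgraphs keep only edges between DE nodes", {
  net <- path_net(c("A", "B", "C"))
  g1 <- de_induced_subgraph(net, c("A", "C"))
  expect_identical(igraph::vcount(g1), 2)
  expect_identical(igraph::ecount(g1), 0)
  g2 <- de_induced_subgraph(net, c("A", "B"))
  expect_identical(igraph::ecount(g2), 1)
  expect_error(de_induced_subgraph(net, "ZZ"), "not in network")
  # brute-force edge filter oracle on random graphs
  set.seed(15)
  for (rep in 1:10) {
    rn <- random_bionetwork(25, 0.15)
    de <- sample(network_nodes(rn), 10)
    sub <- de_induced_subgraph(rn, de)
    e <- network_edges(rn)
    keep <- e[, 1] %in% de & e[, 2] %in% de
    expect_identical(as.integer(igraph::ecount(sub)), as.integer(sum(keep)))
  }
})

test_that("component reports match a union-find oracle and order deterministically", {
  g <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("C", "D")), directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = "Z")
  rep1 <- subnetwork_report(g)
  expect_identical(rep1$n_components, 2L)
  expect_identical(lengths(rep1$components), c(2L, 2L))
  expect_identical(rep1$components[[1]], c("A", "B"))  # lexicographic tie-break
  expect_identical(rep1$scattered, "Z")
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  rep0 <- subnetwork_report(empty)
  expect_identical(rep0$n_components, 0L)
  expect_identical(rep0$giant, character(0))

  set.seed(37)
  for (rep in 1:30) {
    n <- sample(5:60, 1)
    net <- random_bionetwork(n, runif(1, 0.02, 0.2))
    r <- subnetwork_report(net$graph)
    o <- uf_partition(network_nodes(net), network_edges(net))
    expect_identical(r$components, o$components)
    expect_identical(r$scattered, o$scattered)
  }
})

test_that("DE components refine the full-network components", {
  set.seed(57)
  net <- random_bionetwork(40, 0.08)
  full <- subnetwork_report(net$graph)
  full_comps <- c(full$components, as.list(full$scattered))
  de <- sample(network_nodes(net), 15)
  sub <- subnetwork_report(de_induced_subgraph(net, de))
  for (comp in sub$components) {
    holder <- vapply(full_comps, function(fc) all(comp %in% fc), TRUE)
    expect_identical(sum(holder), 1L)
  }
})

test_that("giant size is monotone non-decreasing in the DE set", {
  set.seed(67)
  net <- random_bionetwork(30, 0.12)
  de <- sample(network_nodes(net), 10)
  size0 <- length(subnetwork_report(de_induced_subgraph(net, de))$giant)
  for (extra in setdiff(network_nodes(net), de)[1:5]) {
    size1 <- length(subnetwork_report(de_induced_subgraph(net, c(de, extra)))$giant)
    expect_gte(size1, size0)
  }
})

test_that("subnetwork size test handles the degenerate full-set case", {
  net <- gen_scale_free(60, 2, seed = 12)
  r <- subnetwork_size_test(net, network_nodes(net), n_iter = 30, seed = 1)
  expect_identical(r$observed, as.numeric(igraph::vcount(net$graph)))
  expect_true(is.na(r$z_score))            # degenerate null, flagged undefined
  expect_gt(r$p_empirical, 0)
})

test_that("a planted clique inflates the giant subnetwork size", {
  set.seed(8)
  sparse <- igraph::sample_gnp(120, 0.01)
  igraph::V(sparse)$name <- sprintf("N%03d", 1:120)
  cl <- igraph::make_full_graph(12)
  igraph::V(cl)$name <- sprintf("C%02d", 1:12)
  net <- as_bionetwork(igraph::disjoint_union(sparse, cl))
  r <- subnetwork_size_test(net, sprintf("C%02d", 1:12), n_iter = 199, seed = 2,
                            side = "greater")
  expect_identical(r$observed, 12)
  expect_equal(r$p_empirical, 1 / 200)
})

test_that("hub capture counts DE hubs in the giant component", {
  # clique of 12 (all hubs up to k_min = 8) plus a far-away star
  cl <- igraph::make_full_graph(12)
  igraph::V(cl)$name <- sprintf("C%02d", 1:12)
  star <- igraph::make_star(15, mode = "undirected")
  igraph::V(star)$name <- c("HUB", sprintf("L%02d", 1:14))
  net <- as_bionetwork(igraph::disjoint_union(cl, star))
  de <- c(sprintf("C%02d", 1:12), "HUB")
  r <- hub_capture_test(net, de, k_min = 11, n_iter = 199, seed = 3)
  # giant = the clique; its 12 members have degree 11, HUB has 14 but is scattered
  expect_identical(r$observed, 12)
  expect_identical(r$side, "greater")
  expect_error(hub_capture_test(net, sprintf("L%02d", 1:5), k_min = 11), "no hub")
})

test_that("fully connected DE sets give a degenerate hub-capture null", {
  cl <- as_bionetwork(igraph::make_full_graph(25))
  igraph::V(cl$graph)$name <- sprintf("C%02d", 1:25)
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- sprintf("R%d", 1:5)
  net <- as_bionetwork(igraph::disjoint_union(cl$graph, ring))
  de <- sprintf("C%02d", 1:10)
  r <- hub_capture_test(net, de, k_min = 20, n_iter = 50, seed = 4)
  expect_identical(r$observed, as.numeric(length(de)))  # giant = whole DE set
  expect_true(is.na(r$z_score))
})

test_that("hubs outside the giant component give observed zero and large p", {
  # DE set: a triangle (giant, low degree) plus two DE hubs isolated from it
  tri <- igraph::make_full_graph(3); igraph::V(tri)$name <- c("T1", "T2", "T3")
  s1 <- igraph::make_star(12, mode = "undirected")
  igraph::V(s1)$name <- c("H1", sprintf("a%02d", 1:11))
  s2 <- igraph::make_star(12, mode = "undirected")
  igraph::V(s2)$name <- c("H2", sprintf("b%02d", 1:11))
  net <- as_bionetwork(igraph::disjoint_union(tri, s1, s2))
  de <- c("T1", "T2", "T3", "H1", "H2")
  r <- hub_capture_test(net, de, k_min = 10, n_iter = 199, seed = 5)
  expect_identical(r$observed, 0)
  expect_gt(r$p_empirical, 0.5)
})

test_that("the alternative uniform-nodes null also runs and is seeded", {
  net <- gen_scale_free(150, 3, seed = 21)
  deg <- node_degrees(net)
  de <- unique(c(names(sort(deg, decreasing = TRUE))[1:5],
                 plant_de_set(net, 40, beta = 0, seed = 6)))
  r1 <- hub_capture_test(net, de, k_min = 10, n_iter = 60, seed = 7, null = "uniform_nodes")
  r2 <- hub_capture_test(net, de, k_min = 10, n_iter = 60, seed = 7, null = "uniform_nodes")
  expect_identical(r1$null_values, r2$null_values)
})

test_that("per-condition subnetworks and recurrent nodes tally correctly", {
  net <- merge_pathways(list(p = pathway("p", rbind(
    c("A", "B"), c("B", "C"), c("D", "E")))))
  coll <- toy_de_sets(list(
    D4_10nM = c(a = 1L, b = 1L),
    D9_10nM = c(a = 1L, b = -1L, d = 1L, e = 1L),
    D12_10nM = c(d = 1L)))
  ann <- annotate_de(net, coll)
  reps <- per_condition_subnetworks(ann, k_min = 2)
  expect_identical(length(reps), 3L)
  expect_identical(reps$D4_10nM$giant, c("A", "B"))
  expect_identical(reps$D9_10nM$n_components, 2L)
  expect_identical(reps$D12_10nM$n_components, 0L)   # single DE node is scattered
  rec <- recurrent_nodes(reps, min_conditions = 2)
  expect_setequal(rec$node, c("A", "B"))
  expect_identical(rec$n_conditions, c(2L, 2L))
  rec1 <- recurrent_nodes(reps, min_conditions = 1)
  # brute-force tally
  expect_identical(rec1$n_conditions[rec1$node == "D"], 1L)
  expect_false("C" %in% rec1$node)
})

test_that("identical conditions give identical subnetwork reports", {
  net <- merge_pathways(list(p = pathway("p", rbind(c("A", "B"), c("B", "C")))))
  coll <- toy_de_sets(list(D4_10nM = c(a = 1L, b = 1L), D9_10nM = c(a = 1L, b = 1L)))
  reps <- per_condition_subnetworks(annotate_de(net, coll))
  expect_identical(reps$D4_10nM$components, reps$D9_10nM$components)
})

test_that("subnetwork reports serialize with component ids and sizes", {
  g <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C"), c("X", "Y")),
                                   directed = FALSE)
  rep1 <- subnetwork_report(g, hub_set = "B")
  path <- tempfile(fileext = ".tsv")
  write_subnetwork_report(rep1, path)
  tab <- utils::read.delim(path)
  expect_identical(nrow(tab), 5L)
  expect_identical(sort(tab$node[tab$component_id == 1]), c("A", "B", "C"))
  expect_identical(tab$component_size[tab$node == "X"], 2L)
})
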