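test_that("SIF parsing deduplicates undirected edges and drops self-loops", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tA", "C pp D", "E"), path)
  p <- read_sif(path)
  expect_identical(nrow(p$edges), 2L)
  expect_setequal(p$nodes, c("A", "B", "C", "D", "E"))
  expect_true(all(p$edges[, 1] <= p$edges[, 2]))  # canonical orientation

  loop <- tempfile(fileext = ".sif")
  writeLines("A\tpp\tA", loop)
  expect_warning(pl <- read_sif(loop), "self-loop")
  expect_identical(nrow(pl$edges), 0L)
  expect_identical(pl$nodes, "A")

  empty <- tempfile(fileext = ".sif")
  writeLines(character(0), empty)
  pe <- read_sif(empty)
  expect_identical(length(pe$nodes), 0L)

  bad <- tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "X\tY"), bad)
  expect_error(read_sif(bad), "line 2")
})

test_that("SIF multi-target lines expand to one edge per target", {
  path <- tempfile(fileext = ".sif")
  writeLines("A\tpp\tB\tC\tD", path)
  p <- read_sif(path)
  expect_identical(nrow(p$edges), 3L)
})

test_that("gene symbols are case-folded so Vav1 and VAV1 merge", {
  path <- tempfile(fileext = ".sif")
  writeLines(c("Vav1\tpp\tBtk", "VAV1\tpp\tBTK"), path)
  p <- read_sif(path)
  expect_identical(nrow(p$edges), 1L)
  expect_setequal(p$nodes, c("VAV1", "BTK"))
})

test_that("XGMML parsing matches SIF on the same graph", {
  xg <- tempfile(fileext = ".xgmml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<graph label="toy">',
    '  <node id="1" label="A"/><node id="2" label="B"/><node id="3" label="C"/>',
    '  <edge source="1" target="2"/><edge source="2" target="1"/>',
    '  <edge source="2" target="3"/>',
    '</graph>'), xg)
  px <- read_xgmml(xg, id = "toy")
  expect_identical(nrow(px$edges), 2L)      # duplicate edge collapsed
  sf <- tempfile(fileext = ".sif")
  writeLines(c("A\tpp\tB", "B\tpp\tC"), sf)
  ps <- read_sif(sf, id = "toy")
  expect_identical(px$edges, ps$edges)
  expect_identical(px$nodes, ps$nodes)
  bad <- tempfile(fileext = ".xgmml")
  writeLines("<graph><node", bad)
  expect_error(read_xgmml(bad), "unparseable")
})

test_that("pathways round-trip through write_sif", {
  p <- pathway("p1", rbind(c("A", "B"), c("B", "C")), nodes = "LONER")
  path <- tempfile(fileext = ".sif")
  write_sif(p, path)
  back <- read_sif(path, id = "p1")
  expect_identical(back$edges, p$edges)
  expect_identical(back$nodes, p$nodes)
})

test_that("select_pathways keeps exactly the pathways hit by DE genes", {
  coll <- list(
    p1 = pathway("p1", rbind(c("A", "B"))),
    p2 = pathway("p2", rbind(c("C", "D"))),
    p3 = pathway("p3", rbind(c("B", "C"))))
  expect_identical(names(select_pathways(coll, "A")), "p1")
  expect_identical(names(select_pathways(coll, c("b"))), c("p1", "p3"))
  expect_identical(length(select_pathways(coll, "ZZZ")), 0L)
  # brute-force oracle on random fixtures
  set.seed(13)
  for (rep in 1:10) {
    rcoll <- lapply(1:6, function(i) {
      m <- matrix(sample(LETTERS[1:12], 8, TRUE), ncol = 2)
      pathway(paste0("r", i), m[m[, 1] != m[, 2], , drop = FALSE])
    })
    names(rcoll) <- paste0("r", 1:6)
    de <- sample(LETTERS[1:12], 3)
    got <- names(select_pathways(rcoll, de))
    want <- names(rcoll)[vapply(rcoll, function(p) length(intersect(p$nodes, de)) > 0, TRUE)]
    expect_identical(got, want)
  }
})

test_that("merging pathways unions nodes/edges and tracks provenance", {
  p1 <- pathway("p1", rbind(c("A", "B")))
  p2 <- pathway("p2", rbind(c("B", "C"), c("A", "B")))
  net <- merge_pathways(list(p1 = p1, p2 = p2))
  expect_setequal(network_nodes(net), c("A", "B", "C"))
  e <- network_edges(net)
  expect_identical(nrow(e), 2L)
  prov <- igraph::E(net$graph)$pathways
  key <- paste(e[, 1], e[, 2])
  expect_setequal(prov[[which(key == "A B")]], c("p1", "p2"))
  expect_identical(prov[[which(key == "B C")]], "p2")
  expect_error(merge_pathways(list()), "empty")
})

test_that("merging is idempotent and order-invariant", {
  set.seed(17)
  coll <- lapply(1:5, function(i) {
    m <- matrix(sample(LETTERS[1:15], 12, TRUE), ncol = 2)
    m <- m[m[, 1] != m[, 2], , drop = FALSE]
    pathway(paste0("p", i), m)
  })
  names(coll) <- paste0("p", 1:5)
  net <- merge_pathways(coll)
  # idempotent: re-merge the merged edge set presented as one pathway
  key <- function(n) sort(paste(network_edges(n)[, 1], network_edges(n)[, 2]))
  again <- merge_pathways(list(all = pathway("all", network_edges(net),
                                             nodes = network_nodes(net))))
  expect_identical(key(again), key(net))
  expect_identical(network_nodes(again), network_nodes(net))
  # order-invariant
  net2 <- merge_pathways(coll[sample(5)])
  expect_identical(key(net2), key(net))
  expect_identical(network_nodes(net2), network_nodes(net))
  # edge count bounded by the sum of pathway edge counts
  expect_lte(igraph::ecount(net$graph), sum(vapply(coll, function(p) nrow(p$edges), 0L)))
})

test_that("adjacency is symmetric with an empty diagonal", {
  set.seed(19)
  net <- random_bionetwork(20, 0.2)
  a <- as.matrix(igraph::as_adjacency_matrix(net$graph))
  expect_identical(a, t(a))
  expect_true(all(diag(a) == 0))
})

test_that("annotate_de flags mapped genes and reports unmapped ones", {
  net <- merge_pathways(list(p = pathway("p", rbind(c("A", "B"), c("B", "C")))))
  coll <- toy_de_sets(list(D4_10nM = c(a = 1L, zz = -1L)))
  ann <- annotate_de(net, coll)
  expect_true(ann$de_flags["A", "D4_10nM"])
  expect_false(ann$de_flags["B", "D4_10nM"])
  expect_identical(ann$unmapped$D4_10nM, "ZZ")
  # conservation: mapped + unmapped = |DE set|
  expect_identical(sum(ann$de_flags[, 1]) + length(ann$unmapped$D4_10nM),
                   length(coll$sets$D4_10nM))
  expect_identical(network_nodes(ann), network_nodes(net))  # no isolates added
})

test_that("pathway membership counts match a brute-force scan", {
  coll <- list(
    p1 = pathway("p1", rbind(c("A", "B"))),
    p2 = pathway("p2", rbind(c("A", "C"))),
    p3 = pathway("p3", rbind(c("A", "D"), c("B", "D"))))
  pg <- pathways_per_gene(coll, c("A", "B", "ZZ"))
  expect_identical(unname(pg$per_gene), c(3L, 2L, 0L))
  expect_identical(pg$pathways_hit, 3L)
  set.seed(23)
  genes <- sample(LETTERS, 5)
  got <- pathways_per_gene(coll, genes)
  want <- vapply(genes, function(g) sum(vapply(coll, function(p) g %in% p$nodes, TRUE)), 0L)
  expect_identical(unname(got$per_gene), unname(want))
})

test_that("networks round-trip through write_network / read_network", {
  set.seed(29)
  net <- random_bionetwork(15, 0.25)
  sif <- tempfile(fileext = ".sif"); attrs <- tempfile(fileext = ".tsv")
  prov <- tempfile(fileext = ".tsv")
  write_network(net, sif, attrs, prov)
  back <- read_network(sif)
  expect_setequal(network_nodes(back), network_nodes(net))
  key <- function(e) sort(paste(e[, 1], e[, 2]))
  expect_identical(key(network_edges(back)), key(network_edges(net)))
  at <- utils::read.delim(attrs)
  expect_identical(sort(at$node), sort(network_nodes(net)))
  expect_identical(at$degree[order(at$node)],
                   unname(node_degrees(net)[sort(network_nodes(net))]))
})

test_that("pathway manifests load SIF and XGMML files alike", {
  dir <- tempfile(); dir.create(dir)
  writeLines("A\tpp\tB", file.path(dir, "p1.sif"))
  writeLines(c('<graph><node id="1" label="B"/><node id="2" label="C"/>',
               '<edge source="1" target="2"/></graph>'),
             file.path(dir, "p2.xgmml"))
  man <- data.frame(pathway_id = c("p1", "p2"), name = c("one", "two"),
                    file = c("p1.sif", "p2.xgmml"))
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  coll <- read_pathway_collection(mpath)
  expect_identical(names(coll), c("p1", "p2"))
  net <- merge_pathways(coll)
  expect_setequal(network_nodes(net), c("A", "B", "C"))
  expect_identical(igraph::ecount(net$graph), 2)
})
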