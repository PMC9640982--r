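# Independent oracles and fixture builders used across the suite.

# Union-find with path compression: partitions `nodes` under `edges`
# (2-column character matrix). Returns list(components = size >= 2 groups,
# scattered = singletons), each group sorted, components sorted by
# decreasing size then lexicographically smallest member.
uf_partition <- function(nodes, edges) {
  parent <- seq_along(nodes)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  if (nrow(edges)) {
    ia <- match(edges[, 1L], nodes); ib <- match(edges[, 2L], nodes)
    for (r in seq_len(nrow(edges))) {
      a <- find(ia[r]); b <- find(ib[r])
      if (a != b) parent[a] <- b
    }
  }
  root <- vapply(seq_along(nodes), find, 0L)
  groups <- split(nodes, root)
  sizes <- lengths(groups)
  comp <- lapply(groups[sizes >= 2L], sort)
  if (length(comp)) {
    first <- vapply(comp, `[[`, "", 1L)
    comp <- unname(comp[order(-lengths(comp), first)])
  } else comp <- list()
  sc <- unlist(groups[sizes == 1L], use.names = FALSE)
  list(components = comp,
       scattered = if (is.null(sc)) character(0) else sort(sc))
}

# Random G(n, p) graph as a bionetwork with letter-ish node names.
random_bionetwork <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  as_bionetwork(g)
}

# Small deterministic count fixture.
toy_counts <- function() {
  m <- matrix(c(10L, 20L, 5L,
                20L, 40L, 10L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m
}

# Signed DE set collection over the default dose-time grid.
toy_de_sets <- function(sets) de_set_collection(sets)

# Write a temporary TSV and return its path.
write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
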