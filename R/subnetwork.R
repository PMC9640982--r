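#' Subgraph induced by a DE node set
#'
#' Nodes are the DE genes present in the network; edges are the network edges
#' with both endpoints DE.
#'
#' @param net A `bionetwork`.
#' @param de_set Character vector of node names (must all exist in the
#'   network; unmapped genes are removed beforehand by [annotate_de()]).
#' @return An igraph graph.
#' @export
de_induced_subgraph <- function(net, de_set) {
  stopifnot(inherits(net, "bionetwork"))
  de_set <- unique(de_set)
  missing <- setdiff(de_set, network_nodes(net))
  if (length(missing)) stop("node(s) not in network: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  igraph::induced_subgraph(net$graph, de_set)
}

#' Connected-component report of a (sub)graph
#'
#' Components of size >= 2 are the subnetworks, sorted by decreasing size
#' with ties broken by the lexicographically smallest member; singletons are
#' reported separately as scattered nodes. The giant subnetwork is the first
#' component.
#'
#' @param g An igraph graph (typically from [de_induced_subgraph()]).
#' @param hub_set Optional character vector of hub names, used to fill
#'   `hubs_in_giant`.
#' @return Object of class `subnetwork_report`: list with `components`
#'   (list of sorted node-name vectors), `giant`, `scattered`,
#'   `edge_counts` (per component), `hubs_in_giant` and `n_components`.
#' @export
subnetwork_report <- function(g, hub_set = character()) {
  if (igraph::vcount(g) == 0) {
    return(structure(list(components = list(), giant = character(0),
                          scattered = character(0), edge_counts = integer(0),
                          hubs_in_giant = character(0), n_components = 0L),
                     class = "subnetwork_report"))
  }
  cl <- igraph::components(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  groups <- split(nodes, cl$membership)
  sizes <- lengths(groups)
  comp <- lapply(groups[sizes >= 2L], sort)
  scattered <- sort(unlist(groups[sizes == 1L], use.names = FALSE))
  if (length(comp)) {
    first <- vapply(comp, `[[`, "", 1L)
    ord <- order(-lengths(comp), first)
    comp <- unname(comp[ord])
    ec <- vapply(comp, function(nd)
      igraph::ecount(igraph::induced_subgraph(g, nd)), 0)
  } else {
    comp <- list(); ec <- numeric(0)
  }
  giant <- if (length(comp)) comp[[1L]] else character(0)
  structure(list(components = comp, giant = giant,
                 scattered = if (is.null(scattered)) character(0) else scattered,
                 edge_counts = as.integer(ec),
                 hubs_in_giant = intersect(giant, hub_set),
                 n_components = length(comp)),
            class = "subnetwork_report")
}

#' @export
print.subnetwork_report <- function(x, ...) {
  cat(sprintf("Subnetworks: %d component(s) of size >= 2, %d scattered node(s)\n",
              x$n_components, length(x$scattered)))
  if (x$n_components)
    cat(sprintf("  giant: %d nodes, %d edges, %d hub(s)\n",
                length(x$giant), x$edge_counts[1L], length(x$hubs_in_giant)))
  invisible(x)
}

# Integer edge list of a network, used by the permutation nulls to avoid
# rebuilding igraph subgraphs from names.
edge_index <- function(net) {
  el <- igraph::as_edgelist(net$graph, names = FALSE)
  storage.mode(el) <- "integer"
  list(el = el, n = igraph::vcount(net$graph))
}

# Largest component size (among components of size >= 2) of the subgraph
# induced by the flagged nodes; 0 when the induced subgraph has no edges.
giant_size_flagged <- function(ei, flag) {
  keep <- flag[ei$el[, 1L]] & flag[ei$el[, 2L]]
  if (!any(keep)) return(0L)
  sub <- igraph::graph_from_edgelist(ei$el[keep, , drop = FALSE], directed = FALSE)
  as.integer(max(igraph::components(sub)$csize))
}

#' Permutation test for the size of the giant DE subnetwork
#'
#' Observed statistic: size (node count) of the largest connected component
#' of the DE-induced subgraph. Null: the same statistic for uniformly
#' sampled node sets of size `|de_set|`. Default side "less" — the question
#' is whether the DE core is smaller than expected by chance.
#'
#' @inheritParams degree_bias_test
#' @param side Alternative hypothesis (default "less").
#' @return A `perm_result`.
#' @export
subnetwork_size_test <- function(net, de_set, n_iter = 1000L, seed = NULL,
                                 side = c("less", "greater", "two.sided")) {
  side <- match.arg(side)
  nodes <- network_nodes(net)
  de_set <- unique(de_set)
  if (!length(de_set)) stop("DE set is empty")
  missing <- setdiff(de_set, nodes)
  if (length(missing)) stop("node(s) not in network: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  ei <- edge_index(net)
  n <- ei$n; n_de <- length(de_set)
  flag <- nodes %in% de_set
  observed <- giant_size_flagged(ei, flag)
  null_values <- vapply(seq_len(n_iter), function(i) {
    f <- logical(n)
    f[sample.int(n, n_de)] <- TRUE
    giant_size_flagged(ei, f)
  }, 0L)
  perm_result(as.numeric(observed), as.numeric(null_values), side, n_iter, seed,
              "giant DE-subnetwork size")
}

#' Permutation test for hub capture by the giant DE subnetwork
#'
#' Observed statistic: number of DE hubs (degree >= `k_min`) inside the giant
#' component of the DE-induced subgraph. Two selectable nulls:
#' `"giant_membership"` (default) conditions on the DE set and the giant
#' size, sampling giant membership uniformly from the DE set — it isolates
#' "do hubs concentrate in the connected core" from the degree bias of the
#' DE set itself; `"uniform_nodes"` redraws node sets of size `|de_set|` and
#' re-derives their giant component.
#'
#' @inheritParams degree_bias_test
#' @param k_min Hub degree threshold (default 20).
#' @param null Null model, see Details.
#' @param side Alternative (default "greater").
#' @return A `perm_result`.
#' @export
hub_capture_test <- function(net, de_set, k_min = 20L, n_iter = 1000L,
                             seed = NULL, null = c("giant_membership", "uniform_nodes"),
                             side = c("greater", "less", "two.sided")) {
  side <- match.arg(side); null <- match.arg(null)
  nodes <- network_nodes(net)
  de_set <- unique(de_set)
  missing <- setdiff(de_set, nodes)
  if (length(missing)) stop("node(s) not in network: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  deg <- node_degrees(net)
  hub_set <- hubs(deg, k_min)
  de_hubs <- intersect(de_set, hub_set)
  if (!length(de_hubs)) stop("DE set contains no hub (degree >= ", k_min, ")")
  if (!is.null(seed)) set.seed(seed)
  ei <- edge_index(net)
  flag <- nodes %in% de_set
  sub <- subnetwork_report(de_induced_subgraph(net, de_set), hub_set)
  giant <- sub$giant
  observed <- length(sub$hubs_in_giant)
  if (null == "giant_membership") {
    is_hub_de <- de_set %in% hub_set
    n_de <- length(de_set); g_size <- length(giant)
    null_values <- vapply(seq_len(n_iter), function(i)
      sum(is_hub_de[sample.int(n_de, g_size)]), 0L)
  } else {
    n <- ei$n; n_de <- length(de_set)
    hub_flag <- nodes %in% hub_set
    null_values <- vapply(seq_len(n_iter), function(i) {
      idx <- sample.int(n, n_de)
      f <- logical(n); f[idx] <- TRUE
      keep <- f[ei$el[, 1L]] & f[ei$el[, 2L]]
      if (!any(keep)) return(0L)
      sg <- igraph::graph_from_edgelist(ei$el[keep, , drop = FALSE], directed = FALSE)
      cl <- igraph::components(sg)
      gi <- which.max(cl$csize)
      members <- which(cl$membership == gi)
      members <- members[members %in% which(f)]  # vertices 1..max id; keep flagged
      sum(hub_flag[members])
    }, 0L)
  }
  perm_result(as.numeric(observed), as.numeric(null_values), side, n_iter, seed,
              sprintf("DE hubs (k >= %d) in giant subnetwork [null: %s]", k_min, null))
}

#' Per-condition DE subnetwork reports
#'
#' @param net An annotated `bionetwork` (see [annotate_de()]).
#' @param k_min Hub degree threshold used for `hubs_in_giant`.
#' @return Named list of `subnetwork_report`, one per condition.
#' @export
per_condition_subnetworks <- function(net, k_min = 20L) {
  stopifnot(inherits(net, "bionetwork"))
  if (is.null(net$de_flags)) stop("network is not DE-annotated; run annotate_de() first")
  hub_set <- hubs(node_degrees(net), k_min)
  out <- lapply(colnames(net$de_flags), function(cn) {
    de <- rownames(net$de_flags)[net$de_flags[, cn]]
    subnetwork_report(de_induced_subgraph(net, de), hub_set)
  })
  names(out) <- colnames(net$de_flags)
  out
}

#' Nodes recurrent across per-condition subnetworks
#'
#' Counts, for every node, the number of conditions in which it belongs to a
#' subnetwork component (size >= 2); reports the nodes reaching
#' `min_conditions`.
#'
#' @param reports Named list of `subnetwork_report` (one per condition).
#' @param min_conditions Minimum number of conditions (default 1).
#' @return data.frame (node, n_conditions) sorted by decreasing count.
#' @export
recurrent_nodes <- function(reports, min_conditions = 1L) {
  if (!length(reports)) stop("need >= 1 report")
  tallies <- table(unlist(lapply(reports, function(r)
    unique(unlist(r$components, use.names = FALSE))), use.names = FALSE))
  df <- data.frame(node = names(tallies), n_conditions = as.integer(tallies))
  df <- df[df$n_conditions >= min_conditions, , drop = FALSE]
  df[order(-df$n_conditions, df$node), , drop = FALSE]
}

#' Write a subnetwork report as TSV
#'
#' One row per node placed in a component: node, component id, component
#' size, hub status.
#'
#' @param report A `subnetwork_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subnetwork_report <- function(report, path) {
  stopifnot(inherits(report, "subnetwork_report"))
  rows <- lapply(seq_along(report$components), function(i) {
    nd <- report$components[[i]]
    data.frame(node = nd, component_id = i, component_size = length(nd),
               is_hub = nd %in% report$hubs_in_giant)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = character(), component_id = integer(),
               component_size = integer(), is_hub = logical())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
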