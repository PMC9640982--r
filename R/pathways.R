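#' Construct a pathway graph
#'
#' A pathway is a small undirected simple graph: a set of gene symbols and a
#' set of unordered gene pairs. Self-loops are dropped with a warning and
#' duplicate edges collapsed. Gene symbols are case-folded to upper case by
#' default so that mixed capitalisations (Vav1 / VAV1) match.
#'
#' @param id Pathway identifier.
#' @param edges Two-column character matrix (or data.frame) of endpoints;
#'   may have zero rows.
#' @param nodes Extra (possibly isolated) node symbols.
#' @param name Human-readable pathway name.
#' @param edge_type Optional interaction-type token per edge (kept as
#'   metadata, ignored by all computations).
#' @param case_fold Upper-case all symbols (default TRUE).
#' @return Object of class `pathway`.
#' @export
pathway <- function(id, edges = matrix(character(), ncol = 2L), nodes = character(),
                    name = id, edge_type = NULL, case_fold = TRUE) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "character"
  if (case_fold) {
    edges[] <- toupper(edges)
    nodes <- toupper(nodes)
  }
  dimnames(edges) <- NULL
  nodes <- c(nodes, as.vector(edges))   # loop endpoints stay as nodes
  if (nrow(edges)) {
    loops <- edges[, 1L] == edges[, 2L]
    if (any(loops)) {
      warning(sprintf("pathway '%s': dropped %d self-loop(s)", id, sum(loops)))
      if (!is.null(edge_type)) edge_type <- edge_type[!loops]
      edges <- edges[!loops, , drop = FALSE]
    }
    # canonical orientation, then dedupe
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L), drop = FALSE]
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    keep <- !duplicated(key)
    edges <- edges[keep, , drop = FALSE]
    if (!is.null(edge_type)) edge_type <- edge_type[keep]
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  structure(list(id = id, name = name, nodes = nodes, edges = edges,
                 edge_type = edge_type), class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("Pathway %s (%s): %d nodes, %d edges\n",
              x$id, x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a pathway from a SIF file
#'
#' Accepts the tab-delimited dialect `nodeA<TAB>interaction<TAB>nodeB` (and
#' the space-delimited variant). Single-token lines declare isolated nodes.
#' Edges are undirected and deduplicated; self-loops are dropped with a
#' warning.
#'
#' @param path SIF file path.
#' @param id,name Pathway identifier and name (default: file basename).
#' @param case_fold Upper-case symbols (default TRUE).
#' @return A `pathway`.
#' @export
read_sif <- function(path, id = sub("\\.sif$", "", basename(path)), name = id,
                     case_fold = TRUE) {
  if (!file.exists(path)) stop("SIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  from <- character(0); to <- character(0); type <- character(0); iso <- character(0)
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "[\t ]+")[[1L]]
    if (length(tok) == 1L) {
      iso <- c(iso, tok)
    } else if (length(tok) >= 3L) {
      # one source, one relation, >= 1 targets (multi-target SIF lines)
      from <- c(from, rep(tok[1L], length(tok) - 2L))
      type <- c(type, rep(tok[2L], length(tok) - 2L))
      to <- c(to, tok[-(1:2)])
    } else {
      stop(sprintf("malformed SIF line %d in %s: '%s'", k, path, lines[k]))
    }
  }
  pathway(id, cbind(from, to), nodes = iso, name = name,
          edge_type = if (length(type)) type else NULL, case_fold = case_fold)
}

#' Write a pathway (or network edge list) as SIF
#' @param x A `pathway` or `bionetwork`.
#' @param path Output path.
#' @param default_type Interaction token used when none is stored.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path, default_type = "pp") {
  if (inherits(x, "bionetwork")) {
    e <- igraph::as_edgelist(x$graph)
    type <- rep(default_type, nrow(e))
    nodes <- igraph::V(x$graph)$name
  } else {
    e <- x$edges
    type <- if (!is.null(x$edge_type)) x$edge_type else rep(default_type, nrow(e))
    nodes <- x$nodes
  }
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(e)) writeLines(paste(e[, 1L], type, e[, 2L], sep = "\t"), con)
  iso <- setdiff(nodes, as.vector(e))
  if (length(iso)) writeLines(iso, con)
  invisible(path)
}

#' Read a pathway from a minimal XGMML document
#'
#' Consumes only `node` labels (falling back to the id attribute) and `edge`
#' source/target attributes; everything else in the document is ignored.
#'
#' @inheritParams read_sif
#' @return A `pathway` with the same contract as [read_sif()].
#' @export
read_xgmml <- function(path, id = sub("\\.xgmml$", "", basename(path)), name = id,
                       case_fold = TRUE) {
  if (!file.exists(path)) stop("XGMML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("unparseable XGMML document ", path, ": ", conditionMessage(e)))
  ns <- xml2::xml_ns_strip(doc)
  node_el <- xml2::xml_find_all(doc, ".//node")
  edge_el <- xml2::xml_find_all(doc, ".//edge")
  nid <- xml2::xml_attr(node_el, "id")
  nlab <- xml2::xml_attr(node_el, "label")
  nlab[is.na(nlab)] <- nid[is.na(nlab)]
  label_of <- stats::setNames(nlab, nid)
  src <- xml2::xml_attr(edge_el, "source")
  tgt <- xml2::xml_attr(edge_el, "target")
  if (length(edge_el) && (anyNA(src) | anyNA(tgt)))
    stop("XGMML edge without source/target in ", path)
  resolve <- function(x) ifelse(x %in% names(label_of), label_of[x], x)
  pathway(id, cbind(resolve(src), resolve(tgt)), nodes = nlab, name = name,
          case_fold = case_fold)
}

#' Read a pathway collection from a manifest
#'
#' The manifest is a TSV with columns `pathway_id`, `name`, `file`; file
#' paths are resolved relative to the manifest location. Format is inferred
#' from the extension (.sif or .xgmml).
#'
#' @param manifest Path to the manifest TSV.
#' @param case_fold Upper-case symbols (default TRUE).
#' @return Named list of `pathway` objects (a pathway collection).
#' @export
read_pathway_collection <- function(manifest, case_fold = TRUE) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  df <- utils::read.delim(manifest, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("pathway_id", "name", "file")
  if (!all(need %in% colnames(df))) stop("manifest needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$pathway_id)) stop("duplicate pathway ids in manifest")
  base <- dirname(manifest)
  coll <- lapply(seq_len(nrow(df)), function(i) {
    f <- df$file[i]
    if (!file.exists(f)) f <- file.path(base, df$file[i])
    if (grepl("\\.xgmml$", f, ignore.case = TRUE))
      read_xgmml(f, id = df$pathway_id[i], name = df$name[i], case_fold = case_fold)
    else read_sif(f, id = df$pathway_id[i], name = df$name[i], case_fold = case_fold)
  })
  names(coll) <- df$pathway_id
  coll
}

#' Keep the pathways containing at least one DE gene
#'
#' @param coll Pathway collection (named list of `pathway`).
#' @param de_genes_set Character vector of DE gene symbols.
#' @param case_fold Upper-case the query genes before matching (default TRUE).
#' @return The filtered collection, input order preserved.
#' @export
select_pathways <- function(coll, de_genes_set, case_fold = TRUE) {
  if (case_fold) de_genes_set <- toupper(de_genes_set)
  keep <- vapply(coll, function(p) any(p$nodes %in% de_genes_set), TRUE)
  coll[keep]
}

#' Merge a pathway collection into one biological network
#'
#' Node set = union of pathway node sets; edge set = deduplicated union of
#' pathway edges. Every edge records the set of pathways that contributed it
#' (provenance). The result is an undirected simple graph, equivalent to a
#' triangular adjacency matrix.
#'
#' @param coll Non-empty pathway collection.
#' @return Object of class `bionetwork`: list with `graph` (igraph, vertex
#'   names = gene symbols, edge attribute `pathways` = provenance list),
#'   `de_flags` (NULL until [annotate_de()]), `unmapped` (NULL).
#' @export
merge_pathways <- function(coll) {
  if (!length(coll)) stop("empty pathway collection")
  ids <- vapply(coll, `[[`, "", "id")
  edges <- do.call(rbind, lapply(coll, `[[`, "edges"))
  pid <- rep(ids, vapply(coll, function(p) nrow(p$edges), 0L))
  nodes <- sort(unique(unlist(lapply(coll, `[[`, "nodes"), use.names = FALSE)))
  if (is.null(edges)) edges <- matrix(character(), ncol = 2L)
  if (nrow(edges)) {
    key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
    prov <- split(pid, key)
    uk <- !duplicated(key)
    edges <- edges[uk, , drop = FALSE]
    prov <- lapply(prov[key[uk]], unique)
  } else prov <- list()
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1L], to = edges[, 2L], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::E(g)$pathways <- unname(prov)
  structure(list(graph = g, de_flags = NULL, unmapped = NULL), class = "bionetwork")
}

#' Wrap an igraph graph as a bionetwork
#' @param g Undirected igraph with vertex names.
#' @return A `bionetwork` (self-loops and multi-edges are simplified away).
#' @export
as_bionetwork <- function(g) {
  stopifnot(igraph::is_igraph(g))
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  structure(list(graph = g, de_flags = NULL, unmapped = NULL), class = "bionetwork")
}

#' @export
print.bionetwork <- function(x, ...) {
  cat(sprintf("Biological network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  if (!is.null(x$de_flags))
    cat(sprintf("  annotated with %d condition(s); %d unmapped DE gene(s)\n",
                ncol(x$de_flags), length(x$unmapped)))
  invisible(x)
}

#' Network node names
#' @param net A `bionetwork`.
#' @return Character vector of node symbols.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' Network edge list
#' @param net A `bionetwork`.
#' @return Two-column character matrix, canonically ordered within rows.
#' @export
network_edges <- function(net) {
  e <- igraph::as_edgelist(net$graph)
  if (nrow(e)) {
    swap <- e[, 1L] > e[, 2L]
    e[swap, ] <- e[swap, c(2L, 1L), drop = FALSE]
  }
  e
}

#' Annotate network nodes with per-condition DE flags
#'
#' DE genes absent from the network are reported in the `unmapped` field,
#' never added as isolated nodes (artificial isolates would distort degree
#' statistics).
#'
#' @param net A `bionetwork`.
#' @param coll A `de_sets` collection (genes are case-folded to match).
#' @param case_fold Upper-case DE genes before matching (default TRUE).
#' @return The annotated `bionetwork` with `de_flags` (node x condition
#'   logical matrix) and `unmapped` (named list condition -> missing genes).
#' @export
annotate_de <- function(net, coll, case_fold = TRUE) {
  stopifnot(inherits(net, "bionetwork"), inherits(coll, "de_sets"))
  nodes <- network_nodes(net)
  flags <- matrix(FALSE, length(nodes), length(coll$sets),
                  dimnames = list(nodes, names(coll$sets)))
  unmapped <- list()
  for (cn in names(coll$sets)) {
    g <- names(coll$sets[[cn]])
    if (case_fold) g <- toupper(g)
    flags[, cn] <- nodes %in% g
    unmapped[[cn]] <- setdiff(g, nodes)
  }
  net$de_flags <- flags
  net$unmapped <- unmapped
  net
}

#' Pathway membership counts per gene
#'
#' @param coll Pathway collection.
#' @param genes Gene symbols to query (case-folded to match).
#' @param case_fold Upper-case the query genes (default TRUE).
#' @return List with `per_gene` (named integer vector: pathways containing
#'   each gene) and `pathways_hit` (number of pathways containing >= 1 query
#'   gene).
#' @export
pathways_per_gene <- function(coll, genes, case_fold = TRUE) {
  if (case_fold) genes <- toupper(genes)
  member <- vapply(coll, function(p) genes %in% p$nodes, logical(length(genes)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(genes))
  per_gene <- stats::setNames(as.integer(rowSums(member)), genes)
  list(per_gene = per_gene, pathways_hit = sum(colSums(member) > 0))
}

#' Write a network to disk
#'
#' Writes a SIF edge file plus a TSV of node attributes (degree and, when
#' annotated, the per-condition DE flags), and optionally an edge-provenance
#' TSV (edge -> contributing pathway ids).
#'
#' @param net A `bionetwork`.
#' @param sif_path Edge-list SIF output path.
#' @param attr_path Node-attribute TSV output path.
#' @param provenance_path Optional provenance TSV output path.
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, sif_path, attr_path, provenance_path = NULL) {
  stopifnot(inherits(net, "bionetwork"))
  write_sif(net, sif_path)
  deg <- igraph::degree(net$graph)
  df <- data.frame(node = names(deg), degree = as.integer(deg))
  if (!is.null(net$de_flags)) df <- cbind(df, as.data.frame(net$de_flags[df$node, , drop = FALSE]))
  utils::write.table(df, attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(sif = sif_path, attrs = attr_path)
  if (!is.null(provenance_path)) {
    e <- network_edges(net)
    prov <- igraph::E(net$graph)$pathways
    pd <- data.frame(
      from = e[, 1L], to = e[, 2L],
      pathways = vapply(seq_len(nrow(e)), function(i)
        paste(sort(prov[[i]]), collapse = ","), ""))
    utils::write.table(pd, provenance_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, provenance = provenance_path)
  }
  invisible(paths)
}

#' Read a network back from a SIF edge file
#' @param sif_path SIF file.
#' @param case_fold Upper-case symbols (default TRUE).
#' @return A `bionetwork` (without provenance).
#' @export
read_network <- function(sif_path, case_fold = TRUE) {
  p <- read_sif(sif_path, case_fold = case_fold)
  merge_pathways(list(p))
}
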