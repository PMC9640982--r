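#' Read gene-set annotations from a GMT file
#'
#' Standard GMT: one term per line, `term<TAB>description<TAB>gene1<TAB>...`.
#' Duplicate genes within a term are collapsed; duplicate term ids are an
#' error.
#'
#' @param path GMT file path.
#' @param case_fold Upper-case gene symbols (default TRUE).
#' @return Named list of terms: each `list(name =, genes =)`.
#' @export
read_gmt <- function(path, case_fold = TRUE) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list()
  for (k in seq_along(lines)) {
    tok <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 3L)
      stop(sprintf("malformed GMT line %d (need term, description, >=1 gene)", k))
    id <- tok[1L]
    if (!is.null(terms[[id]])) stop("duplicate term id: ", id)
    genes <- unique(tok[-(1:2)])
    if (case_fold) genes <- toupper(genes)
    terms[[id]] <- list(name = tok[2L], genes = genes)
  }
  terms
}

#' Write gene-set annotations as GMT
#' @param terms Named list as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(id)
    paste(c(id, terms[[id]]$name, terms[[id]]$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Two-list gene-set enrichment (enrichment fold + hypergeometric tail)
#'
#' For each term, counts b = target genes in the term, n = target size,
#' B = background genes in the term, N = background size; the enrichment fold
#' is E = (b/n) / (B/N) and the p-value the exact hypergeometric upper tail
#' P(X >= b) for n draws from N with B successes. Term gene sets are
#' intersected with the background before counting. Benjamini-Hochberg
#' q-values are computed over the emitted records.
#'
#' @param target Character vector, the gene list of interest (must be a
#'   subset of `background`).
#' @param background Character vector, the gene universe.
#' @param terms Term annotation (named list of `list(name, genes)`).
#' @param min_b Minimum target overlap for a term to be emitted (default 3).
#' @param case_fold Upper-case both lists (default TRUE).
#' @return data.frame with columns term, name, b, n, B, N, E, p, q, sorted by
#'   p ascending.
#' @export
enrich <- function(target, background, terms, min_b = 3L, case_fold = TRUE) {
  if (case_fold) { target <- toupper(target); background <- toupper(background) }
  target <- unique(target); background <- unique(background)
  if (!length(background)) stop("background is empty")
  out_of_bg <- setdiff(target, background)
  if (length(out_of_bg)) stop("target gene(s) not in background: ",
                              paste(utils::head(out_of_bg, 5L), collapse = ", "))
  n <- length(target); N <- length(background)
  rec <- lapply(names(terms), function(id) {
    tgenes <- if (case_fold) toupper(terms[[id]]$genes) else terms[[id]]$genes
    tg <- intersect(tgenes, background)
    B <- length(tg)
    b <- length(intersect(tg, target))
    if (b < min_b) return(NULL)
    E <- (b / n) / (B / N)
    p <- stats::phyper(b - 1L, B, N - B, n, lower.tail = FALSE)
    data.frame(term = id, name = terms[[id]]$name, b = b, n = n, B = B, N = N,
               E = E, p = p, stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, rec)
  if (is.null(rec))
    return(data.frame(term = character(), name = character(), b = integer(),
                      n = integer(), B = integer(), N = integer(),
                      E = numeric(), p = numeric(), q = numeric()))
  rec$q <- stats::p.adjust(rec$p, method = "BH")
  rec <- rec[order(rec$p, rec$term), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Terms recurrently enriched across conditions
#'
#' @param tables Named list of enrichment data.frames (one per condition,
#'   from [enrich()]).
#' @param q_max Significance threshold on the BH q-value (default 0.05).
#' @param min_conditions Minimum number of conditions (default 1).
#' @return data.frame (term, n_conditions) sorted by decreasing count.
#' @export
recurrent_terms <- function(tables, q_max = 0.05, min_conditions = 1L) {
  if (!length(tables)) stop("need >= 1 enrichment table")
  hits <- unlist(lapply(tables, function(tb) tb$term[tb$q <= q_max]), use.names = FALSE)
  tal <- table(hits)
  df <- data.frame(term = names(tal), n_conditions = as.integer(tal))
  df <- df[df$n_conditions >= min_conditions, , drop = FALSE]
  df[order(-df$n_conditions, df$term), , drop = FALSE]
}
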