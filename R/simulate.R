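#' Generate a scale-free network by preferential attachment
#'
#' Classic growth model: `m_attach` isolated seed nodes, then each new node
#' attaches to `m_attach` distinct existing nodes with probability
#' proportional to their current degree (uniform while all degrees are zero,
#' i.e. for the first added node, which links to every seed). The result has
#' exactly `m_attach * (n - m_attach)` edges and is connected.
#'
#' @param n Number of nodes (> m_attach).
#' @param m_attach Edges added per new node (>= 1).
#' @param seed RNG seed (set when non-NULL).
#' @param prefix Node-name prefix (names are zero-padded, e.g. "G0001").
#' @return A `bionetwork`.
#' @export
gen_scale_free <- function(n, m_attach = 3L, seed = NULL, prefix = "G") {
  if (!(n > m_attach && m_attach >= 1L)) stop("need n > m_attach >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(m_attach); n <- as.integer(n)
  deg <- integer(n)
  from <- integer(m * (n - m)); to <- integer(m * (n - m))
  k <- 0L
  for (v in (m + 1L):n) {
    existing <- seq_len(v - 1L)
    tgt <- if (all(deg[existing] == 0L)) existing[seq_len(m)] else
      sample(existing, m, prob = deg[existing])
    idx <- k + seq_len(m)
    from[idx] <- v; to[idx] <- tgt
    deg[v] <- deg[v] + m
    deg[tgt] <- deg[tgt] + 1L
    k <- k + m
  }
  width <- nchar(as.character(n))
  nm <- sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::V(g)$name <- nm
  as_bionetwork(g)
}

#' Decompose a network into overlapping connected pathway files
#'
#' Inverse of [merge_pathways()]: grows `n_pathways` connected edge subsets
#' from random seed edges until every edge is covered. When a growing pathway
#' has no unassigned edge adjacent to it, the shortest path through
#' already-assigned edges is added (so pathways overlap, as real pathway
#' collections do, and stay connected). Extra pathways are appended if the
#' requested number cannot cover the graph. Merging the result reproduces the
#' input graph exactly.
#'
#' @param net A connected `bionetwork`.
#' @param n_pathways Target number of pathways (>= 1).
#' @param size_mean Mean pathway size in edges (Poisson-distributed targets;
#'   default: total edges / n_pathways).
#' @param seed RNG seed.
#' @return Named list of `pathway` objects.
#' @export
gen_pathway_cover <- function(net, n_pathways = 10L, size_mean = NULL, seed = NULL) {
  stopifnot(inherits(net, "bionetwork"))
  if (n_pathways < 1L) stop("n_pathways must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  g <- net$graph
  el <- igraph::as_edgelist(g)                 # character endpoints
  ne <- nrow(el)
  if (!ne) stop("network has no edges")
  if (is.null(size_mean)) size_mean <- max(1, ceiling(ne / n_pathways))
  assigned <- logical(ne)
  # incidence: node name -> edge indices
  inc <- split(rep(seq_len(ne), 2L), c(el[, 1L], el[, 2L]))
  paths <- list()
  p <- 0L
  while (any(!assigned)) {
    p <- p + 1L
    target <- if (p == n_pathways && sum(!assigned) > 0) sum(!assigned) else
      max(1L, stats::rpois(1L, size_mean))
    seed_edge <- sample(which(!assigned), 1L)
    sel <- seed_edge
    assigned[seed_edge] <- TRUE
    nodes_in <- unique(c(el[seed_edge, ]))
    taken <- 1L
    while (taken < target && any(!assigned)) {
      cand <- unique(unlist(inc[nodes_in], use.names = FALSE))
      cand <- cand[!assigned[cand]]
      if (!length(cand)) {
        if (p < n_pathways) break
        # bridge through assigned edges toward the nearest unassigned edge
        rem <- which(!assigned)
        ends <- unique(c(el[rem, ]))
        sp <- igraph::shortest_paths(g, from = nodes_in[1L], to = ends[1L],
                                     output = "epath")
        bridge <- as.integer(sp$epath[[1L]])
        sel <- union(sel, bridge)
        nodes_in <- unique(c(nodes_in, c(el[bridge, ])))
        next
      }
      e <- if (length(cand) == 1L) cand else sample(cand, 1L)
      sel <- c(sel, e)
      assigned[e] <- TRUE
      nodes_in <- unique(c(nodes_in, el[e, ]))
      taken <- taken + 1L
    }
    id <- sprintf("P%03d", p)
    paths[[id]] <- pathway(id, el[sel, , drop = FALSE], name = id, case_fold = FALSE)
  }
  paths
}

#' Plant a degree-biased DE node set
#'
#' Samples `n_de` nodes without replacement with probability proportional to
#' degree^beta: beta = 0 is uniform, beta < 0 biases toward low-connectivity
#' nodes (the bias observed for DE genes in perturbation networks), beta > 0
#' toward hubs.
#'
#' @param net A `bionetwork`.
#' @param n_de Number of nodes to draw (0 < n_de < number of nodes).
#' @param beta Degree-bias exponent.
#' @param seed RNG seed.
#' @return Character vector of node names, length `n_de`.
#' @export
plant_de_set <- function(net, n_de, beta = 0, seed = NULL) {
  stopifnot(inherits(net, "bionetwork"))
  deg <- node_degrees(net)
  if (!(n_de > 0 && n_de < length(deg))) stop("need 0 < n_de < number of nodes")
  if (!is.null(seed)) set.seed(seed)
  w <- pmax(deg, .Machine$double.eps)^beta
  sample(names(deg), n_de, prob = w)
}

#' Default dose-time study design
#'
#' One sample per (timepoint, dose) cell: a baseline timepoint at dose 0 only
#' plus every later timepoint at each dose. The default grid — timepoints
#' D0..D28, doses 0/10/100 nM — has 16 samples.
#'
#' @param timepoints Ordered timepoint labels; the first is baseline (dose 0
#'   only).
#' @param doses Dose levels in nM (must include 0, the control).
#' @return Design data.frame (sample_id, timepoint, dose_nM) as
#'   [read_design()] returns, sample ids `D{t}_{dose}nM`.
#' @export
gen_design <- function(timepoints = c("D0", "D4", "D9", "D12", "D18", "D28"),
                       doses = c(0, 10, 100)) {
  if (!0 %in% doses) stop("doses must include the control dose 0")
  rows <- list(data.frame(timepoint = timepoints[1L], dose_nM = 0))
  for (tp in timepoints[-1L]) for (d in sort(doses))
    rows[[length(rows) + 1L]] <- data.frame(timepoint = tp, dose_nM = d)
  df <- do.call(rbind, rows)
  df$sample_id <- sprintf("%s_%gnM", df$timepoint, df$dose_nM)
  validate_design(df[, c("sample_id", "timepoint", "dose_nM")], timepoints)
}

#' Write a design table as TSV
#' @param design Design data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a replicate-free negative-binomial count matrix with planted
#' effects
#'
#' Baseline per-gene means are log-normal; counts are negative binomial with
#' variance mu + dispersion * mu^2 (Poisson at dispersion 0), scaled by
#' per-sample size factors. A fraction of genes receives planted log2 fold
#' changes (random sign) in randomly chosen treated conditions; a further
#' class of "temporal shift" genes carries its high-dose effect at timepoint
#' i and the same-signed effect at the low dose only at a later timepoint.
#' Ground truth is returned for recovery tests.
#'
#' @param design Design data.frame from [gen_design()] (one or more doses
#'   plus dose 0 controls at each treated timepoint).
#' @param n_genes Number of genes (default 10000).
#' @param de_fraction Fraction of genes planted DE per treated condition
#'   (default 0.05).
#' @param planted_lfc Absolute planted log2 fold change (default 2).
#' @param shift_fraction Fraction of the union of planted genes re-assigned
#'   to the temporal-shift class (default 0.05).
#' @param dispersion Negative-binomial dispersion alpha >= 0 (default 0.05).
#' @param size_factor_range Range of per-sample size factors (log-uniform;
#'   default c(0.7, 1.4)).
#' @param meanlog,sdlog Log-normal baseline mean parameters (defaults
#'   log(200), 1).
#' @param dose_high,dose_low Doses used for the temporal-shift class
#'   (defaults 100 and 10).
#' @param seed RNG seed.
#' @return List with `counts` (integer matrix), `design`, and `truth`
#'   (planted lfc matrix genes x conditions, logical `de` matrix,
#'   `shifted_genes`, baseline `mu`, `size_factors`, `seed`).
#' @export
gen_counts <- function(design, n_genes = 10000L, de_fraction = 0.05,
                       planted_lfc = 2, shift_fraction = 0.05,
                       dispersion = 0.05, size_factor_range = c(0.7, 1.4),
                       meanlog = log(200), sdlog = 1,
                       dose_high = 100, dose_low = 10, seed = NULL) {
  if (de_fraction < 0 || de_fraction > 1 || shift_fraction < 0 || shift_fraction > 1)
    stop("fractions must be in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  mu <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  treated <- design[design$dose_nM > 0, , drop = FALSE]
  treated <- treated[order(treated$timepoint, treated$dose_nM), , drop = FALSE]
  conds <- sprintf("%s_%gnM", treated$timepoint, treated$dose_nM)
  lfc_true <- matrix(0, n_genes, length(conds), dimnames = list(genes, conds))
  n_de <- round(de_fraction * n_genes)
  for (j in seq_along(conds)) {
    idx <- sample.int(n_genes, n_de)
    lfc_true[idx, j] <- planted_lfc * sample(c(-1, 1), n_de, replace = TRUE)
  }
  # temporal-shift class: wipe other effects, then plant (high, t_i) and
  # (low, t_j>i) with matching sign, leaving (low, t_i) clean
  shifted_genes <- character(0)
  tps <- unique(as.character(treated$timepoint[order(treated$timepoint)]))
  hi_cols <- match(sprintf("%s_%gnM", tps, dose_high), conds)
  lo_cols <- match(sprintf("%s_%gnM", tps, dose_low), conds)
  can_shift <- length(tps) >= 2L && !anyNA(hi_cols) && !anyNA(lo_cols)
  if (shift_fraction > 0 && can_shift) {
    planted_any <- which(rowSums(lfc_true != 0) > 0)
    n_shift <- round(shift_fraction * length(planted_any))
    if (n_shift > 0) {
      sh <- sample(planted_any, n_shift)
      shifted_genes <- genes[sh]
      lfc_true[sh, ] <- 0
      for (g in sh) {
        i <- sample.int(length(tps) - 1L, 1L)
        j <- if (i + 1L == length(tps)) length(tps) else sample((i + 1L):length(tps), 1L)
        s <- sample(c(-1, 1), 1L)
        lfc_true[g, hi_cols[i]] <- planted_lfc * s
        lfc_true[g, lo_cols[j]] <- planted_lfc * s
      }
    }
  }
  sf <- exp(stats::runif(nrow(design), log(size_factor_range[1L]), log(size_factor_range[2L])))
  names(sf) <- design$sample_id
  counts <- matrix(0L, n_genes, nrow(design), dimnames = list(genes, design$sample_id))
  for (s in seq_len(nrow(design))) {
    cn <- sprintf("%s_%gnM", design$timepoint[s], design$dose_nM[s])
    eff <- if (cn %in% conds) 2^lfc_true[, cn] else 1
    m <- mu * eff * sf[s]
    counts[, s] <- if (dispersion == 0) stats::rpois(n_genes, m) else
      stats::rnbinom(n_genes, mu = m, size = 1 / dispersion)
  }
  list(counts = counts, design = design,
       truth = list(lfc = lfc_true, de = lfc_true != 0,
                    shifted_genes = shifted_genes, mu = mu,
                    size_factors = sf, planted_lfc = planted_lfc,
                    dispersion = dispersion, seed = seed))
}

#' Simulate term annotations with one planted enriched term
#'
#' Random terms draw genes uniformly from the universe; the planted term
#' covers a stated fraction of a target subset and a (lower) fraction of the
#' rest of the universe, so its true enrichment fold is
#' `coverage_target / coverage_background`.
#'
#' @param universe Gene universe (character).
#' @param target Target subset of the universe.
#' @param n_terms Number of random terms (default 50).
#' @param coverage_target Fraction of the target covered by the planted term
#'   (default 0.3).
#' @param coverage_background Fraction of the non-target universe covered
#'   (default 0.05).
#' @param size_range Size range of the random terms (default c(10, 100)).
#' @param seed RNG seed.
#' @return List with `terms` (GMT-style named list, planted term id
#'   "PLANTED") and `truth` (planted genes and the true fold).
#' @export
gen_terms <- function(universe, target, n_terms = 50L, coverage_target = 0.3,
                      coverage_background = 0.05, size_range = c(10L, 100L),
                      seed = NULL) {
  if (coverage_target <= 0 || coverage_target >= 1 ||
      coverage_background <= 0 || coverage_background >= 1)
    stop("coverage fractions must be in (0, 1)")
  if (!all(target %in% universe)) stop("target must be a subset of the universe")
  if (!is.null(seed)) set.seed(seed)
  bg <- setdiff(universe, target)
  planted <- c(sample(target, max(1L, round(coverage_target * length(target)))),
               sample(bg, max(1L, round(coverage_background * length(bg)))))
  terms <- list(PLANTED = list(name = "planted enriched term", genes = sort(planted)))
  for (i in seq_len(n_terms)) {
    sz <- sample(size_range[1L]:size_range[2L], 1L)
    terms[[sprintf("T%04d", i)]] <- list(name = sprintf("random term %d", i),
                                         genes = sort(sample(universe, min(sz, length(universe)))))
  }
  list(terms = terms,
       truth = list(planted_id = "PLANTED", planted_genes = sort(planted),
                    true_fold = coverage_target / coverage_background,
                    coverage_target = coverage_target,
                    coverage_background = coverage_background, seed = seed))
}

#' Write a full synthetic study to disk
#'
#' Generates and writes every input the pipeline consumes: count TSV, design
#' TSV, pathway SIF files + manifest, GMT annotation, and a ground-truth
#' JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master RNG seed.
#' @param n_genes,n_nodes,m_attach,n_pathways,de_fraction,planted_lfc,shift_fraction,dispersion
#'   Simulation scale parameters (defaults mirror a desk-scale dose-time
#'   study: 10000 genes, a 4000-node / m = 4 scale-free network).
#' @return Invisibly, a list of file paths plus the in-memory truth.
#' @export
write_simulation <- function(dir, seed = 1L, n_genes = 10000L, n_nodes = 4000L,
                             m_attach = 4L, n_pathways = 160L,
                             de_fraction = 0.05, planted_lfc = 2,
                             shift_fraction = 0.05, dispersion = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- gen_design()
  sim <- gen_counts(design, n_genes = n_genes, de_fraction = de_fraction,
                    planted_lfc = planted_lfc, shift_fraction = shift_fraction,
                    dispersion = dispersion, seed = seed)
  if (n_nodes > n_genes) stop("n_nodes cannot exceed n_genes")
  net <- gen_scale_free(n_nodes, m_attach, seed = seed + 1L)
  # network nodes are a random subset of the count-table genes, so DE calls
  # map onto the network (degree uncorrelated with gene index by shuffling)
  igraph::V(net$graph)$name <- sample(rownames(sim$counts), n_nodes)
  paths <- gen_pathway_cover(net, n_pathways = n_pathways, seed = seed + 2L)
  pw_dir <- file.path(dir, "pathways")
  dir.create(pw_dir, showWarnings = FALSE)
  manifest <- data.frame(pathway_id = names(paths),
                         name = names(paths),
                         file = file.path("pathways", paste0(names(paths), ".sif")))
  for (id in names(paths)) write_sif(paths[[id]], file.path(pw_dir, paste0(id, ".sif")))
  utils::write.table(manifest, file.path(dir, "pathways_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # term annotation over the count-gene universe, enriched in planted DE genes
  de_any <- rownames(sim$truth$de)[rowSums(sim$truth$de) > 0]
  tm <- gen_terms(rownames(sim$counts), de_any, seed = seed + 3L)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_design(design, file.path(dir, "design.tsv"))
  write_gmt(tm$terms, file.path(dir, "terms.gmt"))
  truth <- list(de_genes_per_condition = apply(sim$truth$de, 2L, function(z)
    rownames(sim$truth$de)[z], simplify = FALSE),
    shifted_genes = sim$truth$shifted_genes,
    planted_lfc = planted_lfc, dispersion = dispersion,
    planted_term = tm$truth, seed = seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(counts = file.path(dir, "counts.tsv"),
                 design = file.path(dir, "design.tsv"),
                 manifest = file.path(dir, "pathways_manifest.tsv"),
                 gmt = file.path(dir, "terms.gmt"),
                 truth_json = file.path(dir, "truth.json"),
                 truth = truth, sim = sim, network = net, pathways = paths))
}
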