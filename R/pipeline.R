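#' Pipeline configuration
#'
#' Central parameter object for [run_stage()]. The statistical defaults are
#' the study's printed operating points: DE threshold 1 on |log2FC|, hub
#' degree 20, reference connectivity 25, 1000 permutation iterations.
#'
#' @param counts,design,pathway_manifest,gmt Input file paths (any may be
#'   NULL when the corresponding stage is not run, or when `simulate` is run
#'   first, which fills them in under `outdir/inputs`).
#' @param outdir Output directory.
#' @param pseudocount Pseudocount for log-normalisation (default 1).
#' @param de_threshold DE threshold on |log2FC| (default 1).
#' @param k_min Hub degree threshold (default 20).
#' @param k_ref Reference degree for the ECDF comparison (default 25).
#' @param n_iter Permutation iterations (default 1000).
#' @param seed Master RNG seed (default 1).
#' @param min_b Minimum term overlap for enrichment (default 3).
#' @param q_max Enrichment significance threshold (default 0.05).
#' @param degree_bias_side,size_test_side,hub_test_side Test sidedness.
#' @param sim Named list of simulation overrides passed to
#'   [write_simulation()] (e.g. `list(n_genes = 2000)`).
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(counts = NULL, design = NULL, pathway_manifest = NULL,
                            gmt = NULL, outdir = "perturbnet_out",
                            pseudocount = 1, de_threshold = 1, k_min = 20L,
                            k_ref = 25L, n_iter = 1000L, seed = 1L,
                            min_b = 3L, q_max = 0.05,
                            degree_bias_side = "greater",
                            size_test_side = "less",
                            hub_test_side = "greater",
                            sim = list()) {
  cfg <- list(counts = counts, design = design, pathway_manifest = pathway_manifest,
              gmt = gmt, outdir = outdir, pseudocount = pseudocount,
              de_threshold = de_threshold, k_min = as.integer(k_min),
              k_ref = as.integer(k_ref), n_iter = as.integer(n_iter),
              seed = as.integer(seed), min_b = as.integer(min_b), q_max = q_max,
              degree_bias_side = degree_bias_side,
              size_test_side = size_test_side, hub_test_side = hub_test_side,
              sim = sim)
  for (f in c("pseudocount", "de_threshold", "k_min", "k_ref", "n_iter", "min_b", "q_max"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("invalid config field '", f, "': must be a single positive number")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(formals(pipeline_config)))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

log_info <- function(...) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))

require_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing ", what, " file: ", if (is.null(path)) "<not set>" else path)
  path
}

write_manifest <- function(cfg, stage, outputs) {
  man <- list(stage = stage, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              parameters = unclass(cfg)[c("pseudocount", "de_threshold", "k_min",
                                          "k_ref", "n_iter", "seed", "min_b", "q_max",
                                          "degree_bias_side", "size_test_side",
                                          "hub_test_side")],
              inputs = unclass(cfg)[c("counts", "design", "pathway_manifest", "gmt")],
              outputs = as.list(outputs),
              output_md5 = as.list(tools::md5sum(unlist(outputs))))
  jsonlite::write_json(man, file.path(cfg$outdir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `simulate` (write synthetic inputs under `outdir/inputs` and point
#' the config at them), `de` (size factors, log2 fold changes, DE calls,
#' distances, PCA), `sets` (Venn/overlap/union/always-DE/temporal shift),
#' `network` (select + merge pathways, annotate), `topology` (degree table,
#' hubs, power-law diagnostic, degree-bias and mean-degree permutation
#' tests), `subnet` (giant subnetwork, size and hub-capture tests,
#' per-condition subnetworks, recurrent nodes), `enrich` (subnetwork genes vs
#' annotated network background), `all` (everything in order). Every stage
#' writes a JSON run manifest with parameters, inputs and output checksums.
#'
#' @param stage One of simulate, de, sets, network, topology, subnet, enrich,
#'   all.
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_stage <- function(stage = c("all", "simulate", "de", "sets", "network",
                                "topology", "subnet", "enrich"),
                      cfg) {
  stage <- match.arg(stage)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "de", "sets", "network", "topology", "subnet", "enrich") else stage
  if (stage == "all" && !is.null(cfg$counts)) stages <- setdiff(stages, "simulate")
  res <- list()
  for (st in stages) {
    res <- switch(st,
      simulate = stage_simulate(cfg, res),
      de = stage_de(cfg, res),
      sets = stage_sets(cfg, res),
      network = stage_network(cfg, res),
      topology = stage_topology(cfg, res),
      subnet = stage_subnet(cfg, res),
      enrich = stage_enrich(cfg, res))
    cfg <- res$cfg %||% cfg
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_simulate <- function(cfg, res) {
  indir <- file.path(cfg$outdir, "inputs")
  args <- c(list(dir = indir, seed = cfg$seed), cfg$sim)
  sim <- do.call(write_simulation, args)
  log_info("simulate: wrote synthetic study under %s", indir)
  cfg$counts <- sim$counts; cfg$design <- sim$design
  cfg$pathway_manifest <- sim$manifest; cfg$gmt <- sim$gmt
  write_manifest(cfg, "simulate",
                 c(counts = sim$counts, design = sim$design,
                   manifest = sim$manifest, gmt = sim$gmt,
                   truth = sim$truth_json))
  res$cfg <- cfg; res$sim <- sim
  res
}

stage_de <- function(cfg, res) {
  counts <- read_counts(require_file(cfg$counts, "count"))
  design <- read_design(require_file(cfg$design, "design"))
  log_info("de: %d genes x %d samples read", nrow(counts), ncol(counts))
  sf <- size_factors(counts)
  m <- normalize_log(counts, sf, cfg$pseudocount)
  dist_m <- sample_distance_matrix(m)
  pca <- expression_pca(m, n_components = min(4L, ncol(m)))
  lfc <- log2_fold_changes(counts, default_contrasts(design),
                           pseudocount = cfg$pseudocount, sf = sf)
  profile <- call_de(lfc, cfg$de_threshold)
  log_info("de: %s DE genes per condition",
           paste(range(colSums(profile$de)), collapse = "-"))
  out <- c(de_table = file.path(cfg$outdir, "de_table.tsv"),
           distances = file.path(cfg$outdir, "sample_distances.tsv"),
           pca = file.path(cfg$outdir, "pca_scores.tsv"))
  write_de_table(profile, out["de_table"])
  utils::write.table(data.frame(sample = rownames(dist_m), dist_m, check.names = FALSE),
                     out["distances"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = rownames(pca$scores), pca$scores,
                                check.names = FALSE),
                     out["pca"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "de", out)
  res$counts <- counts; res$design <- design; res$profile <- profile
  res$distances <- dist_m; res$pca <- pca
  res
}

stage_sets <- function(cfg, res) {
  if (is.null(res$profile)) stop("stage 'sets' needs the 'de' stage results")
  coll <- de_set_collection(res$profile)
  ov <- overlap_matrix(coll)
  uc <- union_categories(coll)
  ts <- temporal_shift_fraction(coll)
  log_info("sets: union %d genes (%s both doses); temporal shift %d/%d",
           length(uc$union), uc$counts[["both_doses"]], ts$count, ts$denominator)
  out <- c(de_sets = file.path(cfg$outdir, "de_sets.tsv"),
           overlap = file.path(cfg$outdir, "overlap_matrix.tsv"),
           categories = file.path(cfg$outdir, "union_categories.tsv"))
  write_de_sets(coll, out["de_sets"])
  utils::write.table(data.frame(condition = rownames(ov), ov, check.names = FALSE),
                     out["overlap"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(uc$category), category = uc$category),
                     out["categories"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "sets", out)
  res$de_sets <- coll; res$overlap <- ov; res$union_categories <- uc
  res$temporal_shift <- ts
  res
}

stage_network <- function(cfg, res) {
  if (is.null(res$de_sets)) stop("stage 'network' needs the 'sets' stage results")
  coll <- read_pathway_collection(require_file(cfg$pathway_manifest, "pathway manifest"))
  de_all <- de_union(res$de_sets)
  kept <- select_pathways(coll, de_all)
  log_info("network: %d of %d pathways contain >= 1 DE gene", length(kept), length(coll))
  net <- annotate_de(merge_pathways(kept), res$de_sets)
  log_info("network: merged %d nodes, %d edges",
           igraph::vcount(net$graph), igraph::ecount(net$graph))
  out <- c(sif = file.path(cfg$outdir, "network.sif"),
           attrs = file.path(cfg$outdir, "network_nodes.tsv"),
           provenance = file.path(cfg$outdir, "network_provenance.tsv"))
  write_network(net, out["sif"], out["attrs"], out["provenance"])
  write_manifest(cfg, "network", out)
  res$network <- net
  res
}

network_de_nodes <- function(net) {
  rownames(net$de_flags)[rowSums(net$de_flags) > 0]
}

stage_topology <- function(cfg, res) {
  if (is.null(res$network)) stop("stage 'topology' needs the 'network' stage results")
  net <- res$network
  deg <- node_degrees(net)
  de_nodes <- network_de_nodes(net)
  pl <- tryCatch(powerlaw_diagnostic(deg), error = function(e) NULL)
  bias <- degree_bias_test(net, de_nodes, k_ref = cfg$k_ref, n_iter = cfg$n_iter,
                           seed = cfg$seed, side = cfg$degree_bias_side)
  md <- mean_degree_test(net, de_nodes, n_iter = cfg$n_iter, seed = cfg$seed + 1L)
  log_info("topology: %d hubs; degree-bias z = %.2f (emp p %.4g)",
           length(hubs(deg, cfg$k_min)), bias$z_score, bias$p_empirical)
  out <- c(degrees = file.path(cfg$outdir, "degree_table.tsv"),
           bias_json = file.path(cfg$outdir, "degree_bias_test.json"),
           mean_json = file.path(cfg$outdir, "mean_degree_test.json"))
  write_degree_table(deg, out["degrees"], cfg$k_min)
  write_perm_result(bias, json_path = out["bias_json"])
  write_perm_result(md, json_path = out["mean_json"])
  write_manifest(cfg, "topology", out)
  res$degrees <- deg; res$degree_bias <- bias; res$mean_degree <- md
  res$powerlaw <- pl
  res
}

stage_subnet <- function(cfg, res) {
  if (is.null(res$network)) stop("stage 'subnet' needs the 'network' stage results")
  net <- res$network
  de_nodes <- network_de_nodes(net)
  hub_set <- hubs(node_degrees(net), cfg$k_min)
  report <- subnetwork_report(de_induced_subgraph(net, de_nodes), hub_set)
  size_t <- subnetwork_size_test(net, de_nodes, n_iter = cfg$n_iter,
                                 seed = cfg$seed + 2L, side = cfg$size_test_side)
  hub_t <- tryCatch(hub_capture_test(net, de_nodes, k_min = cfg$k_min,
                                     n_iter = cfg$n_iter, seed = cfg$seed + 3L,
                                     side = cfg$hub_test_side),
                    error = function(e) NULL)
  percond <- per_condition_subnetworks(net, cfg$k_min)
  rec <- recurrent_nodes(percond, min_conditions = max(1L, length(percond) - 1L))
  log_info("subnet: giant %d nodes; size-test z = %.2f (emp p %.4g)",
           length(report$giant), size_t$z_score, size_t$p_empirical)
  out <- c(report = file.path(cfg$outdir, "subnetwork_report.tsv"),
           size_json = file.path(cfg$outdir, "subnetwork_size_test.json"),
           recurrent = file.path(cfg$outdir, "recurrent_nodes.tsv"))
  write_subnetwork_report(report, out["report"])
  write_perm_result(size_t, json_path = out["size_json"])
  utils::write.table(rec, out["recurrent"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(hub_t)) {
    out <- c(out, hub_json = file.path(cfg$outdir, "hub_capture_test.json"))
    write_perm_result(hub_t, json_path = out["hub_json"])
  }
  write_manifest(cfg, "subnet", out)
  res$subnetwork <- report; res$size_test <- size_t; res$hub_test <- hub_t
  res$per_condition <- percond; res$recurrent_nodes <- rec
  res
}

stage_enrich <- function(cfg, res) {
  if (is.null(res$subnetwork) || is.null(res$network))
    stop("stage 'enrich' needs the 'subnet' stage results")
  terms <- read_gmt(require_file(cfg$gmt, "GMT"))
  background <- network_nodes(res$network)
  target <- intersect(res$subnetwork$giant, background)
  if (!length(target)) stop("giant subnetwork is empty; nothing to enrich")
  tab <- enrich(target, background, terms, min_b = cfg$min_b)
  log_info("enrich: %d terms emitted, %d at q <= %g",
           nrow(tab), sum(tab$q <= cfg$q_max), cfg$q_max)
  out <- c(enrichment = file.path(cfg$outdir, "enrichment.tsv"))
  utils::write.table(tab, out["enrichment"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(cfg, "enrich", out)
  res$enrichment <- tab
  res
}
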