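#' Node degrees of a network
#'
#' @param net A `bionetwork`.
#' @return Named integer vector (node -> degree); satisfies the handshake
#'   identity sum(degrees) = 2 * |edges|.
#' @export
node_degrees <- function(net) {
  stopifnot(inherits(net, "bionetwork"))
  d <- igraph::degree(net$graph)
  stats::setNames(as.integer(d), names(d))
}

#' Network hubs
#'
#' Hubs are high-connectivity nodes, degree k >= `k_min` (inclusive; default
#' 20).
#'
#' @param degrees Named degree vector from [node_degrees()].
#' @param k_min Minimum degree (>= 1).
#' @return Character vector of hub node names.
#' @export
hubs <- function(degrees, k_min = 20L) {
  if (k_min < 1) stop("k_min must be >= 1")
  out <- names(degrees)[degrees >= k_min]
  if (is.null(out)) character(0) else out
}

#' Empirical cumulative distribution at a point
#'
#' Fraction of the values less than or equal to `x` (weak inequality, the
#' standard ECDF convention).
#'
#' @param values Non-empty numeric vector.
#' @param x Evaluation point(s).
#' @return Numeric in `[0, 1]`, one per `x`.
#' @export
ecdf_at <- function(values, x) {
  if (!length(values)) stop("empty values")
  vapply(x, function(xi) mean(values <= xi), 0)
}

# Shared permutation-result constructor: add-one empirical p plus a
# z-score-based normal-tail p (the two reporting styles used in practice).
perm_result <- function(observed, null_values, side, n_iter, seed, statistic) {
  null_mean <- mean(null_values)
  null_sd <- stats::sd(null_values)
  z <- if (is.na(null_sd) || null_sd == 0) NA_real_ else (observed - null_mean) / null_sd
  extreme <- switch(side,
    greater = sum(null_values >= observed),
    less = sum(null_values <= observed),
    two.sided = sum(abs(null_values - null_mean) >= abs(observed - null_mean)))
  p_emp <- (1 + extreme) / (1 + n_iter)
  p_norm <- if (is.na(z)) NA_real_ else switch(side,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  structure(list(statistic = statistic, observed = observed,
                 null_values = null_values, null_mean = null_mean,
                 null_sd = null_sd, z_score = z, p_empirical = p_emp,
                 p_normal = p_norm, n_iter = n_iter, seed = seed, side = side),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test: %s (side = %s, %d iterations, seed %s)\n",
              x$statistic, x$side, x$n_iter, format(x$seed)))
  cat(sprintf("  observed = %.4g; null mean = %.4g (sd %.4g)\n",
              x$observed, x$null_mean, x$null_sd))
  if (is.na(x$z_score)) {
    cat(sprintf("  z undefined (degenerate null); empirical p = %.4g\n", x$p_empirical))
  } else {
    cat(sprintf("  z = %.3f; empirical p = %.4g; normal-tail p = %.3g\n",
                x$z_score, x$p_empirical, x$p_normal))
  }
  invisible(x)
}

#' @export
plot.perm_result <- function(x, ...) {
  graphics::hist(x$null_values, breaks = 30, col = "grey85", border = "white",
                 main = paste("Null distribution:", x$statistic),
                 xlab = x$statistic, ...)
  graphics::abline(v = x$observed, col = "firebrick", lwd = 2)
}

#' Write a permutation result as TSV + JSON
#' @param x A `perm_result`.
#' @param tsv_path,json_path Output paths (either may be NULL to skip).
#' @return Invisibly, the paths written.
#' @export
write_perm_result <- function(x, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "perm_result"))
  rec <- list(statistic = x$statistic, observed = x$observed,
              null_mean = x$null_mean, null_sd = x$null_sd,
              z_score = x$z_score, p_empirical = x$p_empirical,
              p_normal = x$p_normal, n_iter = x$n_iter, seed = x$seed,
              side = x$side)
  if (!is.null(tsv_path)) {
    df <- as.data.frame(lapply(rec, function(v) if (is.null(v)) NA else v))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(rec, json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(c(tsv = tsv_path, json = json_path))
}

check_de_subset <- function(nodes, de_set) {
  de_set <- unique(de_set)
  if (!length(de_set)) stop("DE set is empty")
  missing <- setdiff(de_set, nodes)
  if (length(missing)) stop("DE set contains node(s) not in the network: ",
                            paste(utils::head(missing, 5L), collapse = ", "))
  if (length(de_set) >= length(nodes)) stop("DE set must be a proper subset of the nodes")
  de_set
}

#' Degree-bias permutation test (ECDF difference at a reference degree)
#'
#' Observed statistic: ECDF of DE-node degrees minus ECDF of non-DE-node
#' degrees, both evaluated at `k_ref` (default 25). A positive value means
#' DE nodes have lower overall connectivity. The null redraws `|de_set|`
#' node labels uniformly among all nodes.
#'
#' @param net A `bionetwork`.
#' @param de_set Character vector of DE node names (non-empty proper subset).
#' @param k_ref Reference degree at which the ECDFs are compared.
#' @param n_iter Number of permutations (default 1000).
#' @param seed RNG seed (set when non-NULL).
#' @param side Alternative: "greater" (default), "less" or "two.sided".
#' @return A `perm_result`.
#' @export
degree_bias_test <- function(net, de_set, k_ref = 25L, n_iter = 1000L,
                             seed = NULL, side = c("greater", "less", "two.sided")) {
  side <- match.arg(side)
  deg <- node_degrees(net)
  de_set <- check_de_subset(names(deg), de_set)
  if (!is.null(seed)) set.seed(seed)
  low <- deg <= k_ref                     # indicator: degree within k_ref
  n <- length(deg); n_de <- length(de_set)
  tot_low <- sum(low)
  stat <- function(is_de) {
    s <- sum(low[is_de])
    s / n_de - (tot_low - s) / (n - n_de)
  }
  observed <- stat(names(deg) %in% de_set)
  null_values <- vapply(seq_len(n_iter), function(i) {
    idx <- sample.int(n, n_de)
    s <- sum(low[idx])
    s / n_de - (tot_low - s) / (n - n_de)
  }, 0)
  perm_result(observed, null_values, side, n_iter, seed,
              sprintf("ECDF_DE(%d) - ECDF_nonDE(%d)", k_ref, k_ref))
}

#' Mean-degree permutation test
#'
#' Observed statistic: mean degree of DE nodes minus mean degree of non-DE
#' nodes; null by uniform label shuffling. Two-sided by default.
#'
#' @inheritParams degree_bias_test
#' @return A `perm_result`.
#' @export
mean_degree_test <- function(net, de_set, n_iter = 1000L, seed = NULL,
                             side = c("two.sided", "greater", "less")) {
  side <- match.arg(side)
  deg <- node_degrees(net)
  de_set <- check_de_subset(names(deg), de_set)
  if (!is.null(seed)) set.seed(seed)
  n <- length(deg); n_de <- length(de_set)
  tot <- sum(deg)
  stat_from_sum <- function(s) s / n_de - (tot - s) / (n - n_de)
  observed <- stat_from_sum(sum(deg[names(deg) %in% de_set]))
  null_values <- vapply(seq_len(n_iter), function(i)
    stat_from_sum(sum(deg[sample.int(n, n_de)])), 0)
  perm_result(observed, null_values, side, n_iter, seed,
              "mean degree(DE) - mean degree(non-DE)")
}

#' Log-log power-law diagnostic of the degree distribution
#'
#' Least-squares slope of log10(frequency) against log10(degree) over a
#' logarithmically binned degree histogram. A clearly negative slope is the
#' qualitative signature of a scale-free network; this is a diagnostic, not
#' a rigorous maximum-likelihood power-law fit.
#'
#' @param degrees Named degree vector.
#' @param n_bins Number of logarithmic bins (default 20).
#' @return List with `slope`, `r_squared` and `n_points` (bins used).
#' @export
powerlaw_diagnostic <- function(degrees, n_bins = 20L) {
  d <- degrees[degrees > 0]
  if (length(unique(d)) < 3L) stop("need >= 3 distinct positive degrees")
  brk <- unique(10^seq(log10(min(d)), log10(max(d)), length.out = n_bins + 1L))
  brk[1L] <- brk[1L] - 1e-9
  h <- graphics::hist(d, breaks = brk, plot = FALSE)
  dens <- h$counts / diff(brk)              # per-unit-degree frequency
  keep <- h$counts > 0
  x <- log10(h$mids[keep]); y <- log10(dens[keep])
  if (sum(keep) < 3L) stop("too few occupied bins for a slope")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       r_squared = summary(fit)$r.squared,
       n_points = sum(keep))
}

#' Write a degree table (node, degree, is_hub) as TSV
#' @param degrees Named degree vector.
#' @param path Output path.
#' @param k_min Hub threshold (default 20).
#' @return `path`, invisibly.
#' @export
write_degree_table <- function(degrees, path, k_min = 20L) {
  df <- data.frame(node = names(degrees), degree = as.integer(degrees),
                   is_hub = degrees >= k_min)
  df <- df[order(-df$degree, df$node), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
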