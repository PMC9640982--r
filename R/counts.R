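#' Read a gene-by-sample count table
#'
#' Reads a TSV whose first column (`gene_id`) holds gene identifiers and whose
#' remaining columns hold non-negative integer read counts, one column per
#' sample. Row and column order are preserved exactly as in the file.
#'
#' @param path Path to a tab-separated count table.
#' @return Integer matrix (genes x samples) with gene identifiers as rownames
#'   and sample identifiers as colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a gene_id column plus >=1 sample column")
  genes <- as.character(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  samples <- colnames(df)[-1L]
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count (negative, missing or non-integer) at gene '%s', sample '%s'",
                 genes[bad[1L, 1L]], samples[bad[1L, 2L]]))
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, samples)
  m
}

#' Write a count matrix as TSV
#' @param counts Integer count matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a study design table
#'
#' Reads a TSV with columns `sample_id`, `timepoint`, `dose_nM`. Timepoints
#' are coerced to a factor over the ordered vocabulary of day labels.
#'
#' @param path Path to the design TSV.
#' @param timepoint_levels Ordered vocabulary of timepoint labels.
#' @return data.frame with columns sample_id, timepoint (ordered factor),
#'   dose_nM (numeric).
#' @export
read_design <- function(path, timepoint_levels = c("D0", "D4", "D9", "D12", "D18", "D28")) {
  if (!file.exists(path)) stop("design file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "timepoint", "dose_nM")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("design table missing column(s): ", paste(miss, collapse = ", "))
  validate_design(df[, need], timepoint_levels)
}

validate_design <- function(df, timepoint_levels) {
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicate sample id(s) in design: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(df$timepoint), timepoint_levels)
  if (length(bad)) stop("timepoint label(s) outside vocabulary: ", paste(bad, collapse = ", "))
  df$timepoint <- factor(df$timepoint, levels = timepoint_levels, ordered = TRUE)
  df$dose_nM <- as.numeric(df$dose_nM)
  df
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants from the median-of-ratios scheme:
#' reference genes are the rows with all-positive counts; each sample's factor
#' is the median over reference genes of the count divided by that gene's
#' geometric mean across samples.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  ref <- rowSums(counts <= 0) == 0
  if (!any(ref)) stop("no all-positive gene row: size factors undefined")
  lc <- log(counts[ref, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(exp(lc - geo), 2L, stats::median)
  names(sf) <- colnames(counts)
  sf
}

#' Log2-transform normalised counts
#'
#' @param counts Count matrix.
#' @param sf Size factors (defaults to [size_factors()] of `counts`).
#' @param pseudocount Positive constant added before the log (default 1).
#' @return Real matrix of `log2(count / sf + pseudocount)`, same shape.
#' @export
normalize_log <- function(counts, sf = size_factors(counts), pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (any(sf <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2L, sf, "/") + pseudocount)
}

#' Correlation-based distance between samples
#'
#' `1 - cor` between sample columns of a (log-normalised) expression matrix:
#' 0 for identical samples, 2 for perfectly anticorrelated ones.
#'
#' @param m Expression matrix (genes x samples), >= 2 samples.
#' @param method "pearson" (default) or "spearman".
#' @return Symmetric distance matrix with exact zero diagonal.
#' @export
sample_distance_matrix <- function(m, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  v <- apply(m, 2L, stats::var)
  if (any(v == 0)) stop("zero-variance sample column(s): ",
                        paste(colnames(m)[v == 0], collapse = ", "))
  d <- 1 - stats::cor(m, method = method)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Principal components of an expression matrix
#'
#' Singular decomposition of the gene-centred matrix; returns per-sample
#' scores and the fraction of variance carried by each component.
#'
#' @param m Expression matrix (genes x samples).
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x n_components) and `var_frac`
#'   (fraction of total variance per returned component; the full set over
#'   all components sums to 1).
#' @export
expression_pca <- function(m, n_components = 4L) {
  rank_bound <- min(nrow(m), ncol(m))
  if (n_components > rank_bound)
    stop("n_components (", n_components, ") exceeds min(genes, samples) = ", rank_bound)
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       var_frac = vf[seq_len(n_components)],
       var_frac_all = vf)
}

#' Build the default dose-vs-control contrasts from a design
#'
#' One contrast per treated (timepoint, dose) pair against the dose-0 sample
#' at the same timepoint, named `D{t}_{dose}nM`. `mode = "time"` instead
#' contrasts each untreated timepoint against the earliest timepoint
#' (spontaneous differentiation).
#'
#' @param design Design data.frame as from [read_design()].
#' @param mode "dose" (default) or "time".
#' @return Named list of contrasts, each `list(treated =, control =)` sample
#'   id vectors.
#' @export
default_contrasts <- function(design, mode = c("dose", "time")) {
  mode <- match.arg(mode)
  out <- list()
  if (mode == "dose") {
    tps <- levels(design$timepoint)
    for (tp in tps) {
      ctrl <- design$sample_id[design$timepoint == tp & design$dose_nM == 0]
      if (!length(ctrl)) next
      for (d in sort(setdiff(unique(design$dose_nM[design$timepoint == tp]), 0))) {
        tr <- design$sample_id[design$timepoint == tp & design$dose_nM == d]
        if (!length(tr)) next
        out[[sprintf("%s_%gnM", tp, d)]] <- list(treated = tr, control = ctrl)
      }
    }
  } else {
    base_tp <- levels(design$timepoint)[1L]
    ctrl <- design$sample_id[design$timepoint == base_tp & design$dose_nM == 0]
    if (!length(ctrl)) stop("no dose-0 sample at baseline timepoint ", base_tp)
    for (tp in setdiff(levels(design$timepoint), base_tp)) {
      tr <- design$sample_id[design$timepoint == tp & design$dose_nM == 0]
      if (!length(tr)) next
      out[[sprintf("%s_vs_%s", tp, base_tp)]] <- list(treated = tr, control = ctrl)
    }
  }
  if (!length(out)) stop("design yields no contrasts in mode '", mode, "'")
  out
}

#' Per-gene log2 fold changes over a list of contrasts
#'
#' Counts are normalised by median-of-ratios size factors, shifted by a
#' pseudocount and log2-transformed; the fold change of a contrast is the
#' mean over treated samples minus the mean over control samples. Well
#' defined with a single sample per group.
#'
#' @param counts Count matrix.
#' @param contrasts Named list of `list(treated =, control =)` sample sets,
#'   e.g. from [default_contrasts()].
#' @param pseudocount Positive constant (default 1).
#' @param sf Optional precomputed size factors.
#' @return Matrix (genes x contrasts) of log2 fold changes.
#' @export
log2_fold_changes <- function(counts, contrasts, pseudocount = 1,
                              sf = size_factors(counts)) {
  if (!length(contrasts)) stop("empty contrast list")
  all_ids <- unique(unlist(lapply(contrasts, function(ct) c(ct$treated, ct$control))))
  unknown <- setdiff(all_ids, colnames(counts))
  if (length(unknown)) stop("unknown sample id(s) in contrasts: ",
                            paste(unknown, collapse = ", "))
  m <- normalize_log(counts, sf = sf, pseudocount = pseudocount)
  lfc <- vapply(contrasts, function(ct) {
    if (!length(ct$treated) || !length(ct$control))
      stop("contrast with empty treated or control set")
    rowMeans(m[, ct$treated, drop = FALSE]) - rowMeans(m[, ct$control, drop = FALSE])
  }, numeric(nrow(counts)))
  if (is.null(dim(lfc))) lfc <- matrix(lfc, ncol = 1L, dimnames = list(rownames(counts), names(contrasts)))
  lfc
}

#' Call differential expression from fold changes
#'
#' A gene is differentially expressed in a condition when the absolute log2
#' fold change reaches the threshold (inclusive, default 1).
#'
#' @param lfc Matrix (genes x conditions) of log2 fold changes.
#' @param threshold Positive DE threshold on |log2FC| (default 1).
#' @return Object of class `de_profile`: list with `lfc`, logical `de`,
#'   integer `sign` (+1/-1 where DE, 0 otherwise) and `threshold`.
#' @export
call_de <- function(lfc, threshold = 1) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  lfc <- as.matrix(lfc)
  de <- abs(lfc) >= threshold
  sg <- matrix(0L, nrow(lfc), ncol(lfc), dimnames = dimnames(lfc))
  sg[de] <- ifelse(lfc[de] > 0, 1L, -1L)
  structure(list(lfc = lfc, de = de, sign = sg, threshold = threshold),
            class = "de_profile")
}

#' @export
print.de_profile <- function(x, ...) {
  cat(sprintf("DE profile: %d genes x %d conditions, |log2FC| >= %g\n",
              nrow(x$lfc), ncol(x$lfc), x$threshold))
  n <- colSums(x$de)
  for (j in seq_along(n)) cat(sprintf("  %-12s %5d DE\n", colnames(x$de)[j], n[j]))
  invisible(x)
}

#' Write a fold-change / DE table as TSV
#'
#' One row per gene; per condition a `<cond>_lfc` and `<cond>_de` column.
#' @param profile A `de_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(profile, path) {
  stopifnot(inherits(profile, "de_profile"))
  conds <- colnames(profile$lfc)
  df <- data.frame(gene_id = rownames(profile$lfc))
  for (cn in conds) {
    df[[paste0(cn, "_lfc")]] <- profile$lfc[, cn]
    df[[paste0(cn, "_de")]] <- profile$de[, cn]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract marker-panel fold changes in panel order
#'
#' Subsets a fold-change matrix to an ordered marker panel, preserving panel
#' order; panel genes absent from the table are reported, never silently
#' dropped.
#'
#' @param lfc Matrix (genes x conditions).
#' @param panel Character vector of marker genes, in display order.
#' @return List with `matrix` (markers x conditions, panel order) and
#'   `missing` (panel genes absent from `lfc`).
#' @export
marker_panel_matrix <- function(lfc, panel) {
  if (!length(panel)) stop("empty marker panel")
  if (!ncol(as.matrix(lfc))) stop("fold-change table has no conditions")
  lfc <- as.matrix(lfc)
  present <- panel[panel %in% rownames(lfc)]
  missing <- setdiff(panel, rownames(lfc))
  list(matrix = lfc[present, , drop = FALSE], missing = missing)
}
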