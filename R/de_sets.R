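#' Per-condition DE gene sets
#'
#' Bundles one signed gene set per experimental condition. Conditions are
#' named `D{t}_{dose}nM`; each set is a named integer vector (names = genes,
#' values = sign in {-1, +1}).
#'
#' @param sets Named list of signed gene sets, or a `de_profile` (signs are
#'   taken from its `sign` matrix).
#' @param timepoint_levels Ordered timepoint vocabulary used to order
#'   conditions.
#' @return Object of class `de_sets`: list with `sets`, `conditions`
#'   (data.frame condition / timepoint / dose_nM) and `timepoint_levels`.
#' @export
de_set_collection <- function(sets, timepoint_levels = c("D0", "D4", "D9", "D12", "D18", "D28")) {
  if (inherits(sets, "de_profile")) {
    sg <- sets$sign
    sets <- lapply(seq_len(ncol(sg)), function(j) {
      v <- sg[, j]
      v[v != 0L]
    })
    names(sets) <- colnames(sg)
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("condition names must be unique and non-empty")
  sets <- lapply(sets, function(s) {
    if (is.null(names(s))) stop("each set must be a named vector (gene -> sign)")
    if (anyDuplicated(names(s))) stop("duplicate gene within a condition set")
    if (!all(s %in% c(-1L, 1L))) stop("signs must be -1 or +1")
    storage.mode(s) <- "integer"
    s
  })
  cond <- parse_conditions(names(sets), timepoint_levels)
  structure(list(sets = sets, conditions = cond, timepoint_levels = timepoint_levels),
            class = "de_sets")
}

# "D4_10nM" -> (timepoint D4, dose 10); unparseable names get NA metadata
parse_conditions <- function(nms, timepoint_levels) {
  m <- regmatches(nms, regexec("^(D[0-9]+)_([0-9.]+)nM$", nms))
  tp <- vapply(m, function(x) if (length(x) == 3L) x[2L] else NA_character_, "")
  dose <- vapply(m, function(x) if (length(x) == 3L) as.numeric(x[3L]) else NA_real_, 0)
  tp[!tp %in% timepoint_levels] <- NA
  data.frame(condition = nms,
             timepoint = factor(tp, levels = timepoint_levels, ordered = TRUE),
             dose_nM = dose, stringsAsFactors = FALSE)
}

#' @export
print.de_sets <- function(x, ...) {
  cat(sprintf("DE set collection: %d conditions\n", length(x$sets)))
  for (cn in names(x$sets)) cat(sprintf("  %-12s %5d genes\n", cn, length(x$sets[[cn]])))
  invisible(x)
}

#' Gene names of one condition's DE set
#' @param coll A `de_sets` collection.
#' @param condition Condition name.
#' @return Character vector of gene identifiers.
#' @export
de_genes <- function(coll, condition) {
  stopifnot(inherits(coll, "de_sets"))
  names(coll$sets[[condition]])
}

#' Union of all DE genes across conditions
#' @param coll A `de_sets` collection.
#' @return Character vector (non-redundant union).
#' @export
de_union <- function(coll) {
  stopifnot(inherits(coll, "de_sets"))
  unique(unlist(lapply(coll$sets, names), use.names = FALSE))
}

#' Two-set Venn partition with overlap percentage
#'
#' Partitions two gene sets into exclusive and shared counts and reports the
#' overlap as a percentage of the union, `100 * |A n B| / |A u B|`.
#'
#' @param a,b Character vectors of gene identifiers.
#' @return List with `only_a`, `shared`, `only_b`, `overlap_pct` and
#'   `empty_union` (TRUE when both sets are empty, in which case
#'   `overlap_pct` is 0).
#' @export
venn_partition <- function(a, b) {
  a <- unique(a); b <- unique(b)
  shared <- length(intersect(a, b))
  only_a <- length(a) - shared
  only_b <- length(b) - shared
  un <- only_a + shared + only_b
  list(only_a = only_a, shared = shared, only_b = only_b,
       overlap_pct = if (un > 0) 100 * shared / un else 0,
       empty_union = un == 0L)
}

#' All-by-all overlap percentage matrix
#'
#' @param coll A `de_sets` collection with >= 2 conditions.
#' @param sign_aware If TRUE, genes only match when DE with the same sign.
#' @return Symmetric matrix of overlap percentages; diagonal 100 for
#'   non-empty sets.
#' @export
overlap_matrix <- function(coll, sign_aware = FALSE) {
  stopifnot(inherits(coll, "de_sets"))
  if (length(coll$sets) < 2L) stop("need >= 2 conditions")
  keys <- lapply(coll$sets, function(s)
    if (sign_aware) paste0(names(s), "/", s) else names(s))
  n <- length(keys)
  out <- matrix(0, n, n, dimnames = list(names(keys), names(keys)))
  for (i in seq_len(n)) for (j in i:n) {
    out[i, j] <- out[j, i] <- venn_partition(keys[[i]], keys[[j]])$overlap_pct
  }
  out
}

#' Non-redundant DE union with dose categories
#'
#' Classifies every gene of the non-redundant DE union by the doses at which
#' it is ever called DE: at both doses (possibly at different timepoints),
#' only at the low dose, or only at the high dose.
#'
#' @param coll A `de_sets` collection containing both doses.
#' @param dose_low,dose_high The two treatment doses (defaults 10 and 100 nM).
#' @return List with `union` (character), `category` (named factor over
#'   `both_doses`, `only_low`, `only_high`) and `counts` (table).
#' @export
union_categories <- function(coll, dose_low = 10, dose_high = 100) {
  stopifnot(inherits(coll, "de_sets"))
  cond <- coll$conditions
  low_sets <- coll$sets[cond$condition[!is.na(cond$dose_nM) & cond$dose_nM == dose_low]]
  high_sets <- coll$sets[cond$condition[!is.na(cond$dose_nM) & cond$dose_nM == dose_high]]
  if (!length(low_sets) || !length(high_sets))
    stop("both doses ", dose_low, " and ", dose_high, " must be present")
  in_low <- unique(unlist(lapply(low_sets, names), use.names = FALSE))
  in_high <- unique(unlist(lapply(high_sets, names), use.names = FALSE))
  un <- union(in_low, in_high)
  cat_ <- ifelse(un %in% in_low & un %in% in_high, "both_doses",
                 ifelse(un %in% in_low, "only_low", "only_high"))
  category <- factor(cat_, levels = c("both_doses", "only_low", "only_high"))
  names(category) <- un
  list(union = un, category = category, counts = table(category))
}

#' Genes DE at every timepoint for one dose
#'
#' @param coll A `de_sets` collection.
#' @param dose Dose whose conditions are intersected.
#' @param sign_aware If TRUE, the sign must also be constant across
#'   timepoints.
#' @return Character vector of always-DE genes.
#' @export
always_de <- function(coll, dose, sign_aware = FALSE) {
  stopifnot(inherits(coll, "de_sets"))
  cond <- coll$conditions
  sets <- coll$sets[cond$condition[!is.na(cond$dose_nM) & cond$dose_nM == dose]]
  if (!length(sets)) stop("dose ", dose, " not present")
  keys <- lapply(sets, function(s) if (sign_aware) paste0(names(s), "/", s) else names(s))
  out <- Reduce(intersect, keys)
  if (sign_aware) out <- unique(sub("/[-0-9]+$", "", out))
  out
}

#' Temporal-shift fraction between two doses
#'
#' A gene counts as "shifted" when its response at the high dose appears at
#' the low dose only later: it is DE at the high dose at some non-final
#' timepoint i, not DE at the low dose at i, and DE with the same sign at the
#' low dose at some strictly later timepoint. The denominator is the number
#' of genes DE at the high dose at any non-final timepoint. The rule is
#' configurable and echoed in the output metadata.
#'
#' @param coll A `de_sets` collection.
#' @param dose_high,dose_low The reference (high) and shifted (low) doses.
#' @param sign_matched Require the same sign at the later low-dose timepoint
#'   (default TRUE).
#' @param require_absent_at_i Require the gene NOT DE at the low dose at the
#'   earlier timepoint (default TRUE).
#' @return List with `shifted` (character), `count`, `denominator`,
#'   `fraction` and `definition` (the rule parameters used).
#' @export
temporal_shift_fraction <- function(coll, dose_high = 100, dose_low = 10,
                                    sign_matched = TRUE, require_absent_at_i = TRUE) {
  stopifnot(inherits(coll, "de_sets"))
  cond <- coll$conditions
  pick <- function(dose) {
    rows <- !is.na(cond$dose_nM) & cond$dose_nM == dose & !is.na(cond$timepoint)
    cs <- cond[rows, ]
    cs <- cs[order(cs$timepoint), ]
    coll$sets[cs$condition]
  }
  high <- pick(dose_high); low <- pick(dose_low)
  if (!length(high) || !length(low)) stop("both doses must be present")
  if (length(high) < 2L || length(low) < 2L) stop("need >= 2 timepoints per dose")
  tp_n <- length(high)  # assumes matched timepoint grids; indices align by order
  denom_genes <- unique(unlist(lapply(high[seq_len(tp_n - 1L)], names), use.names = FALSE))
  shifted <- character(0)
  for (g in denom_genes) {
    hit <- FALSE
    for (i in seq_len(tp_n - 1L)) {
      s_hi <- high[[i]][g]
      if (is.na(s_hi)) next
      if (require_absent_at_i && i <= length(low) && !is.na(low[[i]][g])) next
      if (i + 1L > length(low)) next
      for (j in seq(i + 1L, length(low))) {
        s_lo <- low[[j]][g]
        if (is.na(s_lo)) next
        if (!sign_matched || s_lo == s_hi) { hit <- TRUE; break }
      }
      if (hit) break
    }
    if (hit) shifted <- c(shifted, g)
  }
  list(shifted = shifted, count = length(shifted), denominator = length(denom_genes),
       fraction = if (length(denom_genes)) length(shifted) / length(denom_genes) else 0,
       definition = list(sign_matched = sign_matched,
                         require_absent_at_i = require_absent_at_i,
                         dose_high = dose_high, dose_low = dose_low))
}

#' Write a DE set collection as a long TSV
#' @param coll A `de_sets` collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_sets <- function(coll, path) {
  stopifnot(inherits(coll, "de_sets"))
  rows <- lapply(names(coll$sets), function(cn) {
    s <- coll$sets[[cn]]
    if (!length(s)) return(NULL)
    data.frame(condition = cn, gene = names(s), sign = as.integer(s))
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(condition = character(), gene = character(), sign = integer())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DE set collection from a long TSV
#' @param path TSV with columns condition, gene and optional sign.
#' @param timepoint_levels Ordered timepoint vocabulary.
#' @return A `de_sets` collection.
#' @export
read_de_sets <- function(path, timepoint_levels = c("D0", "D4", "D9", "D12", "D18", "D28")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("condition", "gene") %in% colnames(df)))
    stop("DE set table needs columns condition, gene")
  if (is.null(df$sign)) df$sign <- 1L
  sets <- lapply(split(df, df$condition), function(d) {
    stats::setNames(as.integer(d$sign), d$gene)
  })
  de_set_collection(sets, timepoint_levels)
}
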