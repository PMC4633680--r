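#' Intersect the two quantitation branches into substrate candidates
#'
#' A protein is a substrate candidate only if it passes the quantifiability
#' filters, the fold-change cutoff and the p-value cutoff in BOTH branches,
#' and accumulates in the knockout (log2 fold change positive in both):
#' substrates of the E3 are degraded in wild-type cells, so depletion is
#' never a substrate signature. Candidates are sorted by the smaller of the
#' two per-branch log2 fold changes, descending.
#'
#' @param diff_pai,diff_lfq `differential_table`s from the two branches,
#'   built under identical thresholds.
#' @return data.frame with one row per candidate: `protein_id`,
#'   `log2_fc_pai`, `p_pai`, `log2_fc_lfq`, `p_lfq`.
#' @export
intersect_candidates <- function(diff_pai, diff_lfq) {
  th_a <- attr(diff_pai, "thresholds")
  th_b <- attr(diff_lfq, "thresholds")
  if (!identical(unclass(th_a), unclass(th_b))) {
    stop("the two branches were built under different thresholds")
  }
  passing <- function(d) {
    d$protein_id[d$passes_filters & d$passes_fc & d$passes_p & d$log2_fc > 0]
  }
  ids <- intersect(passing(diff_pai), passing(diff_lfq))
  a <- diff_pai[match(ids, diff_pai$protein_id), ]
  b <- diff_lfq[match(ids, diff_lfq$protein_id), ]
  out <- data.frame(protein_id = ids,
                    log2_fc_pai = a$log2_fc, p_pai = a$p_value,
                    log2_fc_lfq = b$log2_fc, p_lfq = b$p_value)
  out <- out[order(-pmin(out$log2_fc_pai, out$log2_fc_lfq)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Venn counts of two protein id sets
#'
#' @param ids_a,ids_b character vectors (treated as sets).
#' @return named integer vector `c(only_a, only_b, common)`.
#' @export
venn_counts <- function(ids_a, ids_b) {
  ids_a <- unique(ids_a)
  ids_b <- unique(ids_b)
  common <- length(intersect(ids_a, ids_b))
  c(only_a = length(ids_a) - common, only_b = length(ids_b) - common,
    common = common)
}

#' Replicate-correlation QC
#'
#' Pearson correlation of log2 normalized protein abundances for every
#' within-condition run pair, computed over the proteins quantified in both
#' runs of the pair. Pairs sharing fewer than 3 proteins get `NA` with a
#' warning. High within-genotype correlations (>= 0.95) indicate a
#' reproducible label-free quantification.
#'
#' @param table a `protein_quant` (normalized).
#' @param design a [study_design].
#' @return run-by-run matrix; entries outside within-condition pairs are `NA`,
#'   the diagonal is 1.
#' @export
replicate_correlation <- function(table, design) {
  stopifnot(inherits(table, "protein_quant"))
  check_design_matches(design, colnames(table$abundance))
  runs <- colnames(table$abundance)
  ab <- log2(table$abundance)
  out <- matrix(NA_real_, length(runs), length(runs),
                dimnames = list(runs, runs))
  diag(out) <- 1
  cond <- design$condition[match(runs, design$run_id)]
  for (i in seq_along(runs)) {
    for (j in seq_along(runs)) {
      if (j <= i || cond[i] != cond[j]) next
      shared <- !is.na(ab[, i]) & !is.na(ab[, j])
      if (sum(shared) < 3) {
        warning("runs ", runs[i], " and ", runs[j],
                " share fewer than 3 quantified proteins")
        next
      }
      out[i, j] <- out[j, i] <- stats::cor(ab[shared, i], ab[shared, j])
    }
  }
  out
}

#' Detect condition-absent marker proteins
#'
#' Flags proteins with at least one quantified peptide ion in every run of
#' one condition and zero quantified peptide ions in every run of the other
#' (e.g. the knocked-out protein itself, to which no peptide is attributed in
#' the knockout). Such proteins fail the completeness filter of the
#' differential tables; this is where they surface.
#'
#' @param x an [ion_matrix] (raw or normalized).
#' @param design a [study_design].
#' @return data.frame with columns `protein_id`, `absent_in`,
#'   `n_peptides_absent` (quantified peptides in the absent condition, zero
#'   by construction) and `n_peptides_present` (in the other condition).
#' @export
detect_absent_markers <- function(x, design) {
  stopifnot(inherits(x, "ion_matrix"))
  check_design_matches(design, run_ids(x))
  proteins <- unique(x$annotations$protein_id)
  obs <- !is.na(x$intensity)
  out <- data.frame(protein_id = character(0), absent_in = character(0),
                    n_peptides_absent = integer(0),
                    n_peptides_present = integer(0))
  prot_f <- factor(x$annotations$protein_id, proteins)
  # per protein x run: number of quantified peptide ions
  counts <- rowsum(obs + 0L, prot_f)
  for (cond_absent in c("WT", "KO")) {
    other <- setdiff(c("WT", "KO"), cond_absent)
    absent_runs <- condition_runs(design, cond_absent)
    present_runs <- condition_runs(design, other)
    hit <- rowSums(counts[, absent_runs, drop = FALSE] > 0) == 0 &
      rowSums(counts[, present_runs, drop = FALSE] > 0) == length(present_runs)
    if (any(hit)) {
      out <- rbind(out, data.frame(
        protein_id = rownames(counts)[hit],
        absent_in = cond_absent,
        n_peptides_absent = as.integer(
          rowSums(counts[hit, absent_runs, drop = FALSE])),
        n_peptides_present = as.integer(apply(
          counts[hit, present_runs, drop = FALSE], 1, max))
      ))
    }
  }
  rownames(out) <- NULL
  out
}
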