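#' Merge per-run ion tables into one cross-run matrix
#'
#' Ions carrying the same `(protein_id, peptide_seq, charge)` key are merged
#' across runs directly. Rows whose peptide sequence is unknown in a run
#' (empty or `NA` `peptide_seq`, e.g. an XIC picked up without an MS/MS
#' identification) can still be matched to an identified ion of the same
#' protein when their m/z agree within `mz_tol_ppm` and their retention times
#' within `rt_window`; the closest m/z wins. Unmatched ions are kept with
#' missing cells in the other runs. Full chromatographic re-alignment and
#' retention-time prediction are upstream, raw-data concerns and are out of
#' scope here.
#'
#' @param matrices list of single-run [ion_matrix] objects (one intensity
#'   column each), named or with distinct column names.
#' @param mz_tol_ppm m/z tolerance for keyless matching, parts per million.
#'   The default mirrors the usual high-resolution MS survey tolerance.
#' @param rt_window retention-time tolerance, minutes.
#' @return an [ion_matrix] spanning all runs.
#' @export
match_ions <- function(matrices, mz_tol_ppm = 5, rt_window = 0.5) {
  stopifnot(length(matrices) >= 1, mz_tol_ppm > 0, rt_window > 0)
  for (m in matrices) {
    stopifnot(inherits(m, "ion_matrix"))
    if (ncol(m$intensity) != 1) stop("each input must cover exactly one run")
  }
  all_runs <- vapply(matrices, function(m) colnames(m$intensity), "")
  if (anyDuplicated(all_runs)) stop("duplicate run identifiers across inputs")

  # conflicting protein assignment: same (peptide_seq, charge) under two
  # proteins anywhere in the inputs is ambiguous and rejected
  ann_all <- do.call(rbind, lapply(matrices, function(m) m$annotations))
  seqd <- ann_all[!is.na(ann_all$peptide_seq) & nzchar(ann_all$peptide_seq), ]
  pep_key <- paste0(seqd$peptide_seq, "/", seqd$charge)
  n_prot <- if (nrow(seqd) > 0) {
    tapply(seqd$protein_id, pep_key, function(p) length(unique(p)))
  } else {
    integer(0)
  }
  if (any(n_prot > 1)) {
    stop("conflicting protein assignment for peptide ion(s): ",
         paste(names(n_prot)[n_prot > 1][1:min(3, sum(n_prot > 1))],
               collapse = "; "))
  }

  ann <- matrices[[1]]$annotations
  intensity <- matrix(NA_real_, nrow(ann), length(all_runs),
                      dimnames = list(NULL, all_runs))
  intensity[, 1] <- matrices[[1]]$intensity[, 1]
  keyed <- function(a) !is.na(a$peptide_seq) & nzchar(a$peptide_seq)
  key_of <- function(a) paste0(a$protein_id, "|", a$peptide_seq, "/", a$charge)

  for (m in matrices[-1]) {
    run <- colnames(m$intensity)
    a <- m$annotations
    v <- m$intensity[, 1]
    target <- rep(NA_integer_, nrow(a))
    has_key_new <- keyed(a)
    has_key_ref <- keyed(ann)
    # exact key merge
    target[has_key_new] <- match(key_of(a)[has_key_new],
                                 ifelse(has_key_ref, key_of(ann), NA))
    # keyless rows: same protein, m/z within ppm, RT within window
    for (i in which(!has_key_new)) {
      cand <- which(ann$protein_id == a$protein_id[i] &
                      abs(ann$mz - a$mz[i]) / a$mz[i] * 1e6 <= mz_tol_ppm &
                      abs(ann$rt - a$rt[i]) <= rt_window)
      if (length(cand) > 0) {
        target[i] <- cand[which.min(abs(ann$mz[cand] - a$mz[i]))]
      }
    }
    hit <- !is.na(target)
    intensity[target[hit], run] <- v[hit]
    if (any(!hit)) {
      ann <- rbind(ann, a[!hit, , drop = FALSE])
      extra <- matrix(NA_real_, sum(!hit), ncol(intensity),
                      dimnames = list(NULL, colnames(intensity)))
      extra[, run] <- v[!hit]
      intensity <- rbind(intensity, extra)
    }
  }
  rownames(ann) <- NULL
  ion_matrix(ann, intensity)
}
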