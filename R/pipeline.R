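#' Run the full dual-branch substrate-discovery pipeline
#'
#' Orchestrates the end-to-end analysis: median-of-ratios ion normalization,
#' Top-3 PAI roll-up of the normalized matrix, pairwise-ratio LFQ roll-up of
#' the raw matrix followed by protein-level median normalization,
#' quantifiability filtering and Welch testing per branch, dual-branch
#' candidate intersection, and QC (quantified-protein Venn counts,
#' within-genotype replicate correlations, absent-marker detection). The run
#' is deterministic given the inputs (and, when simulating, the seed).
#'
#' @param ions an [ion_matrix], or `NULL` to simulate from `config`.
#' @param design a [study_design]; derived from `config` when simulating.
#' @param config a [generator_config] used when `ions` is `NULL`.
#' @param th a [thresholds] object.
#' @param reference_run reference run for ion normalization (see
#'   [compute_normalization()]).
#' @param out_dir if non-`NULL`, writes `candidates.tsv`, `diff_pai.tsv`,
#'   `diff_lfq.tsv`, `qc_correlations.tsv` and `report.json` there.
#' @return a `candidate_report`: list with `candidates`, `diff_pai`,
#'   `diff_lfq`, `venn` (quantifiable-protein overlap between branches),
#'   `replicate_correlation` (per branch), `absent_markers`, `depleted`
#'   (informational: proteins passing both branches on the depleted side),
#'   `thresholds`, `normalization`, `provenance`, and (when simulating)
#'   `truth`.
#' @export
#' @examples
#' cfg <- generator_config(n_background_proteins = 50, seed = 7)
#' rep <- run_pipeline(config = cfg)
#' rep$candidates$protein_id
run_pipeline <- function(ions = NULL, design = NULL, config = NULL,
                         th = thresholds(), reference_run = "auto",
                         out_dir = NULL) {
  truth <- NULL
  if (is.null(ions)) {
    if (is.null(config)) stop("provide either an ion matrix or a generator config")
    sim <- generate_dataset(config)
    ions <- sim$ions
    design <- sim$design
    truth <- sim$truth
  }
  if (is.null(design)) stop("a study design is required")
  check_design_matches(design, run_ids(ions))

  norm <- compute_normalization(ions, reference_run)
  ions_norm <- apply_normalization(ions, norm)

  quant_pai <- quantify_proteins(ions_norm, branch = "pai")
  quant_lfq <- suppressWarnings(quantify_proteins(ions, branch = "lfq"))
  quant_lfq <- normalize_lfq_table(quant_lfq)

  filt_pai <- suppressMessages(filter_quantifiable(quant_pai, design, th))
  filt_lfq <- suppressMessages(filter_quantifiable(quant_lfq, design, th))
  diff_pai <- build_differential_table(filt_pai, design, th)
  diff_lfq <- build_differential_table(filt_lfq, design, th)

  candidates <- intersect_candidates(diff_pai, diff_lfq)
  depleted_ids <- intersect(
    diff_pai$protein_id[diff_pai$passes_filters & diff_pai$passes_fc &
                          diff_pai$passes_p & diff_pai$log2_fc < 0],
    diff_lfq$protein_id[diff_lfq$passes_filters & diff_lfq$passes_fc &
                          diff_lfq$passes_p & diff_lfq$log2_fc < 0])

  report <- structure(list(
    candidates = candidates,
    diff_pai = diff_pai,
    diff_lfq = diff_lfq,
    venn = venn_counts(diff_pai$protein_id, diff_lfq$protein_id),
    replicate_correlation = list(
      PAI = replicate_correlation(filt_pai, design),
      LFQ = replicate_correlation(filt_lfq, design)),
    absent_markers = detect_absent_markers(ions, design),
    depleted = depleted_ids,
    thresholds = th,
    normalization = norm,
    truth = truth,
    provenance = pipeline_provenance(ions, design, config, th)
  ), class = "candidate_report")

  if (!is.null(out_dir)) write_candidate_report(report, out_dir)
  report
}

pipeline_provenance <- function(ions, design, config, th) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_ion_table(ions, tmp)
  list(
    ion_table_md5 = unname(tools::md5sum(tmp)),
    n_ions = n_ions(ions),
    runs = run_ids(ions),
    conditions = stats::setNames(design$condition, design$run_id),
    seed = if (!is.null(config)) config$seed,
    thresholds = unclass(th),
    package_version = as.character(utils::packageVersion("e3lfq"))
  )
}

#' @rdname run_pipeline
#' @param report a `candidate_report`.
#' @export
write_candidate_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.table(report$candidates, p("candidates.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)
  write_differential_table(report$diff_pai, p("diff_pai.tsv"))
  write_differential_table(report$diff_lfq, p("diff_lfq.tsv"))
  corr <- do.call(rbind, lapply(names(report$replicate_correlation), function(b) {
    m <- report$replicate_correlation[[b]]
    idx <- which(upper.tri(m) & !is.na(m), arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(branch = b, run_a = rownames(m)[idx[, 1]],
               run_b = colnames(m)[idx[, 2]], pearson_r = m[idx])
  }))
  utils::write.table(corr, p("qc_correlations.tsv"), sep = "\t",
                     quote = FALSE, na = "", row.names = FALSE)
  json <- list(
    candidates = report$candidates,
    venn = as.list(report$venn),
    absent_markers = report$absent_markers,
    depleted = report$depleted,
    replicate_correlation = corr,
    thresholds = report$provenance$thresholds,
    provenance = report$provenance[c("ion_table_md5", "n_ions", "runs",
                                     "seed", "package_version")]
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("Substrate-candidate report\n")
  cat(sprintf("  quantified proteins: PAI-only %d, LFQ-only %d, common %d\n",
              x$venn["only_a"], x$venn["only_b"], x$venn["common"]))
  if (nrow(x$candidates) == 0) {
    cat("  no candidates pass both branches\n")
  } else {
    cat(sprintf("  %d candidate(s) accumulating in KO (both branches):\n",
                nrow(x$candidates)))
    print(x$candidates, row.names = FALSE, digits = 3)
  }
  if (nrow(x$absent_markers) > 0) {
    cat("  condition-absent markers:\n")
    print(x$absent_markers, row.names = FALSE)
  }
  rr <- x$replicate_correlation$PAI
  rmin <- suppressWarnings(min(rr[upper.tri(rr)], na.rm = TRUE))
  if (is.finite(rmin)) {
    cat(sprintf("  min within-genotype replicate correlation (PAI): %.3f\n", rmin))
  }
  invisible(x)
}
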