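#' Median-of-ratios run normalization
#'
#' Corrects systematic run-to-run intensity differences (sample loading,
#' spray efficiency) by the classic median-of-ratios rule: for each run, take
#' every peptide ion observed in both that run and a reference run, form the
#' raw intensity ratios run/reference, and use the reciprocal of their median
#' as the run's scale factor. The reference run's factor is exactly 1.
#' Ratios are taken on raw (not log) intensities and summarized with
#' [stats::median()], i.e. the midpoint convention for even counts.
#'
#' @param x an [ion_matrix].
#' @param reference_run `"auto"` (default) picks the run with the most
#'   quantified ions, ties broken by the lexicographically smallest run id;
#'   otherwise a run id.
#' @return an object of class `normalization_result`: list with
#'   `reference_run`, named `factors`, and named `n_shared` (ions shared with
#'   the reference per run).
#' @export
#' @examples
#' ann <- data.frame(protein_id = "P1", peptide_seq = c("AAK", "CCK", "DDK"),
#'                   charge = 2L, mz = 400, rt = 10)
#' x <- ion_matrix(ann, cbind(A = c(10, 20, 30), B = c(20, 40, 60)))
#' compute_normalization(x, "A")$factors  # B observed at 2x: factor 0.5
compute_normalization <- function(x, reference_run = "auto") {
  stopifnot(inherits(x, "ion_matrix"))
  runs <- run_ids(x)
  if (identical(reference_run, "auto")) {
    n_quant <- colSums(!is.na(x$intensity))
    best <- n_quant == max(n_quant)
    reference_run <- sort(runs[best])[1]
  }
  if (!reference_run %in% runs) {
    stop("reference run '", reference_run, "' not in the matrix")
  }
  ref <- x$intensity[, reference_run]
  factors <- stats::setNames(numeric(length(runs)), runs)
  n_shared <- stats::setNames(integer(length(runs)), runs)
  for (run in runs) {
    shared <- !is.na(ref) & !is.na(x$intensity[, run])
    n_shared[run] <- sum(shared)
    if (n_shared[run] == 0) {
      stop("run '", run, "' shares no quantified ions with reference '",
           reference_run, "'")
    }
    factors[run] <- 1 / stats::median(x$intensity[shared, run] / ref[shared])
  }
  factors[reference_run] <- 1  # exact, not 1/median of ones
  structure(
    list(reference_run = reference_run, factors = factors, n_shared = n_shared),
    class = "normalization_result"
  )
}

#' @rdname compute_normalization
#' @param result a `normalization_result` whose factors cover all runs of `x`.
#' @return `apply_normalization()`: the normalized [ion_matrix]; missing cells
#'   stay missing, nothing is imputed.
#' @export
apply_normalization <- function(x, result) {
  stopifnot(inherits(x, "ion_matrix"), inherits(result, "normalization_result"))
  runs <- run_ids(x)
  absent <- setdiff(runs, names(result$factors))
  if (length(absent) > 0) {
    stop("no normalization factor for run(s): ", paste(absent, collapse = ", "))
  }
  intensity <- sweep(x$intensity, 2, result$factors[runs], `*`)
  ion_matrix(x$annotations, intensity, normalized = TRUE)
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("median-of-ratios normalization; reference run:", x$reference_run, "\n")
  print(data.frame(run = names(x$factors), factor = unname(x$factors),
                   shared_ions = unname(x$n_shared[names(x$factors)])),
        row.names = FALSE)
  invisible(x)
}
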