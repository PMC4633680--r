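#' Peptide-ion intensity matrix
#'
#' An `ion_matrix` holds one row per peptide ion (a `(protein_id, peptide_seq,
#' charge)` key, with its monoisotopic m/z and retention time) and one column
#' of XIC areas per LC-MS run. Absent values are `NA`; zero is not a valid
#' intensity, because in label-free data the absence of a signal is a missing
#' observation, not a measured zero.
#'
#' @param annotations data.frame with columns `protein_id`, `peptide_seq`,
#'   `charge` (positive integer), `mz` (positive, Thomson), `rt` (non-negative,
#'   minutes). One row per peptide ion.
#' @param intensity numeric matrix, `nrow(annotations)` rows, one named column
#'   per run. Values strictly positive or `NA`.
#' @param normalized logical flag recording whether run-level normalization has
#'   been applied (provenance only).
#'
#' @return An object of class `ion_matrix`: a list with elements
#'   `annotations`, `intensity` and `normalized`.
#' @export
#' @examples
#' ann <- data.frame(protein_id = "P1", peptide_seq = c("AAK", "CCK"),
#'                   charge = 2L, mz = c(400.2, 500.3), rt = c(10, 20))
#' ion_matrix(ann, cbind(WT_1 = c(100, 200), KO_1 = c(110, NA)))
ion_matrix <- function(annotations, intensity, normalized = FALSE) {
  annotations <- as.data.frame(annotations)
  required <- c("protein_id", "peptide_seq", "charge", "mz", "rt")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols) > 0) {
    stop("annotations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  annotations <- annotations[required]
  annotations$protein_id <- as.character(annotations$protein_id)
  annotations$peptide_seq <- as.character(annotations$peptide_seq)
  annotations$charge <- as.integer(annotations$charge)
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  if (nrow(intensity) != nrow(annotations)) {
    stop("annotations and intensity disagree on the number of ions")
  }
  if (is.null(colnames(intensity)) || anyDuplicated(colnames(intensity))) {
    stop("intensity columns must carry distinct run identifiers")
  }
  x <- structure(
    list(annotations = annotations, intensity = intensity,
         normalized = isTRUE(normalized)),
    class = "ion_matrix"
  )
  validate_ion_matrix(x)
}

validate_ion_matrix <- function(x) {
  keys <- ion_keys(x)
  # unsequenced ions carry no peptide key; uniqueness applies to keyed rows
  has_key <- !is.na(x$annotations$peptide_seq) & nzchar(x$annotations$peptide_seq)
  dup <- duplicated(keys) & has_key
  if (any(dup)) {
    stop("duplicate ion key(s): ", paste(utils::head(keys[dup], 3), collapse = "; "))
  }
  bad <- which(!is.na(x$intensity) & x$intensity <= 0)
  if (length(bad) > 0) {
    stop("non-positive intensity found; encode absent values as NA, not 0")
  }
  if (any(x$annotations$mz <= 0) || any(x$annotations$rt < 0)) {
    stop("m/z must be positive and retention time non-negative")
  }
  x
}

#' @rdname ion_matrix
#' @param x an `ion_matrix`.
#' @export
run_ids <- function(x) colnames(x$intensity)

#' @rdname ion_matrix
#' @export
n_ions <- function(x) nrow(x$intensity)

# "protein|peptide/charge" string keys; unique per matrix by construction
ion_keys <- function(x) {
  paste0(x$annotations$protein_id, "|", x$annotations$peptide_seq, "/",
         x$annotations$charge)
}

#' @export
print.ion_matrix <- function(x, ...) {
  cat(sprintf("ion_matrix: %d peptide ions x %d runs (%s)\n",
              n_ions(x), length(run_ids(x)),
              if (x$normalized) "normalized" else "raw"))
  cat("  runs:", paste(run_ids(x), collapse = ", "), "\n")
  cat(sprintf("  proteins: %d; missing cells: %d\n",
              length(unique(x$annotations$protein_id)),
              sum(is.na(x$intensity))))
  invisible(x)
}

#' Study design: run-to-condition mapping
#'
#' @param run_id character vector of run identifiers, matching the intensity
#'   columns of the ion matrix.
#' @param condition character/factor, one of `"WT"` or `"KO"` per run.
#' @param replicate integer replicate index within condition.
#'
#' @return data.frame of class `study_design` with columns `run_id`,
#'   `condition`, `replicate`.
#' @export
study_design <- function(run_id, condition, replicate) {
  condition <- as.character(condition)
  if (!all(condition %in% c("WT", "KO"))) {
    stop("condition must be 'WT' or 'KO'")
  }
  if (anyDuplicated(run_id)) stop("duplicate run_id in study design")
  counts <- table(condition)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("study design needs at least 2 runs in each of WT and KO")
  }
  structure(
    data.frame(run_id = as.character(run_id), condition = condition,
               replicate = as.integer(replicate)),
    class = c("study_design", "data.frame")
  )
}

# runs of one condition, in design order
condition_runs <- function(design, condition) {
  design$run_id[design$condition == condition]
}

check_design_matches <- function(design, run_names) {
  if (!setequal(design$run_id, run_names)) {
    stop("study design runs do not match the data columns: design has {",
         paste(design$run_id, collapse = ", "), "}, data has {",
         paste(run_names, collapse = ", "), "}")
  }
  invisible(design)
}
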