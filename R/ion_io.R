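#' Read and write peptide-ion tables
#'
#' The on-disk dialect is a UTF-8 TSV with header
#' `protein_id  peptide_seq  charge  mz  rt  intensity:<run>...`, one row per
#' peptide ion, one `intensity:` column per run, and empty cells for missing
#' intensities. `read_ion_table()` refuses zero or negative intensities,
#' duplicate ion keys and unknown columns, reporting the offending row.
#'
#' @param path file path.
#' @return `read_ion_table()`: an [ion_matrix]. `write_ion_table()`: `path`,
#'   invisibly.
#' @export
read_ion_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, sep = "\t",
                           colClasses = "character", na.strings = "")
  fixed <- c("protein_id", "peptide_seq", "charge", "mz", "rt")
  missing_cols <- setdiff(fixed, names(tab))
  if (length(missing_cols) > 0) {
    stop("ion table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  other <- setdiff(names(tab), fixed)
  is_int <- startsWith(other, "intensity:")
  if (any(!is_int)) {
    stop("unknown column(s) in ion table: ", paste(other[!is_int], collapse = ", "))
  }
  runs <- sub("^intensity:", "", other)
  if (length(runs) == 0) stop("ion table has no intensity columns")
  intensity <- matrix(NA_real_, nrow(tab), length(runs),
                      dimnames = list(NULL, runs))
  for (j in seq_along(runs)) {
    raw <- tab[[other[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric intensity '%s' in column '%s', data row %d",
                   raw[bad[1]], other[j], bad[1]))
    }
    zero <- which(!is.na(val) & val <= 0)
    if (length(zero) > 0) {
      stop(sprintf(
        "non-positive intensity in column '%s', data row %d: absence must be an empty cell",
        other[j], zero[1]))
    }
    intensity[, j] <- val
  }
  ann <- data.frame(protein_id = tab$protein_id, peptide_seq = tab$peptide_seq,
                    charge = as.integer(tab$charge), mz = as.numeric(tab$mz),
                    rt = as.numeric(tab$rt))
  key <- paste0(ann$protein_id, "|", ann$peptide_seq, "/", ann$charge)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate ion key '%s' at data row %d", key[dup[1]], dup[1]))
  }
  ion_matrix(ann, intensity)
}

#' @rdname read_ion_table
#' @param x an [ion_matrix].
#' @export
write_ion_table <- function(x, path) {
  stopifnot(inherits(x, "ion_matrix"))
  out <- x$annotations
  intensity <- x$intensity
  colnames(intensity) <- paste0("intensity:", colnames(intensity))
  out <- cbind(out, as.data.frame(intensity))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write study-design tables
#'
#' TSV with columns `run_id`, `condition` (WT/KO), `replicate`.
#'
#' @param path file path.
#' @return `read_study_design()`: a [study_design]. `write_study_design()`:
#'   `path`, invisibly.
#' @export
read_study_design <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", colClasses = "character")
  study_design(tab$run_id, tab$condition, as.integer(tab$replicate))
}

#' @rdname read_study_design
#' @param design a [study_design].
#' @export
write_study_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
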