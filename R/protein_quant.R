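#' Select Top-3 reference peptides of a protein
#'
#' The protein abundance index (PAI) of a protein is computed from at most
#' three "reference" peptide ions: the ones with the highest intensities
#' across the samples, operationalized as the highest mean intensity over the
#' runs in which they were observed (so a peptide missed in one run is not
#' penalized). The same reference set is used for every run of the protein.
#' Exact ties are broken by the smaller `(protein_id, peptide_seq, charge)`
#' tuple, which makes the selection invariant under row shuffling.
#'
#' @param x an [ion_matrix].
#' @param protein a protein id present in `x`.
#' @param k maximum number of reference peptides (default 3).
#' @return data.frame of the selected ion keys (`protein_id`, `peptide_seq`,
#'   `charge`), in decreasing order of mean intensity.
#' @export
select_reference_peptides <- function(x, protein, k = 3) {
  stopifnot(inherits(x, "ion_matrix"), k >= 1)
  rows <- which(x$annotations$protein_id == protein)
  if (length(rows) == 0) stop("no quantified ions for protein '", protein, "'")
  ann <- x$annotations[rows, , drop = FALSE]
  m <- rowMeans(x$intensity[rows, , drop = FALSE], na.rm = TRUE)
  if (all(is.nan(m))) stop("no quantified ions for protein '", protein, "'")
  ord <- order(-m, ann$peptide_seq, ann$charge)
  sel <- ord[seq_len(min(k, sum(!is.nan(m))))]
  out <- ann[sel, c("protein_id", "peptide_seq", "charge")]
  rownames(out) <- NULL
  out
}

#' Top-3 protein abundance index (PAI)
#'
#' Per run, the PAI is the arithmetic mean of the XIC areas of the reference
#' peptides observed in that run; `NA` if none of them was observed. For
#' proteins with only one or two quantified peptides the PAI is the mean of
#' what is there. PAI is intended to be computed on normalized intensities
#' (see [apply_normalization()]); normalization precedes the roll-up.
#'
#' @inheritParams select_reference_peptides
#' @param reference data.frame of reference ion keys, as returned by
#'   [select_reference_peptides()]; `NULL` selects them first.
#' @return named numeric vector of per-run abundances.
#' @export
#' @examples
#' ann <- data.frame(protein_id = "P1", peptide_seq = c("AK", "CK", "DK"),
#'                   charge = 2L, mz = 400, rt = 10)
#' x <- ion_matrix(ann, cbind(A = c(100, 80, 60)))
#' compute_pai(x, "P1")  # mean of 100, 80, 60 = 80
compute_pai <- function(x, protein, reference = NULL, k = 3) {
  if (is.null(reference)) reference <- select_reference_peptides(x, protein, k)
  keys <- ion_keys(x)
  ref_keys <- paste0(reference$protein_id, "|", reference$peptide_seq, "/",
                     reference$charge)
  rows <- match(ref_keys, keys)
  if (anyNA(rows)) stop("reference peptide not found in the matrix")
  colMeans(x$intensity[rows, , drop = FALSE], na.rm = TRUE) |>
    replace_nan_na()
}

replace_nan_na <- function(v) { v[is.nan(v)] <- NA_real_; v }

#' Pairwise-ratio least-squares protein profile (LFQ branch)
#'
#' Emulates the delayed-normalization LFQ construction: for every pair of
#' runs sharing at least one peptide of the protein, the protein-level log2
#' ratio is the median over shared peptides of the peptide log2 ratios; the
#' per-run log2 abundances are then the least-squares solution of the system
#' `x_a - x_b = r_ab` over all supported pairs. The free additive constant is
#' fixed so that the summed linear abundance equals the summed observed
#' peptide intensity of the protein. If the run graph is disconnected, only
#' the largest connected component (ties: the one containing the earliest
#' run) is profiled and the other runs are returned as `NA` with a warning.
#'
#' @inheritParams select_reference_peptides
#' @return named numeric vector of per-run linear-scale abundances.
#' @export
compute_lfq_profile <- function(x, protein) {
  stopifnot(inherits(x, "ion_matrix"))
  rows <- which(x$annotations$protein_id == protein)
  if (length(rows) == 0) stop("no quantified ions for protein '", protein, "'")
  lfq_profile_core(x$intensity[rows, , drop = FALSE], protein)
}

lfq_profile_core <- function(mat, protein = "?") {
  runs <- colnames(mat)
  n_run <- length(runs)
  out <- stats::setNames(rep(NA_real_, n_run), runs)
  obs <- !is.na(mat)
  if (sum(colSums(obs) > 0) < 2) {
    warning("protein '", protein, "' observed in fewer than 2 runs; ",
            "no LFQ profile")
    return(out)
  }
  L <- log2(mat)
  pairs <- utils::combn(n_run, 2)
  r <- rep(NA_real_, ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    shared <- obs[, a] & obs[, b]
    if (any(shared)) r[p] <- stats::median(L[shared, a] - L[shared, b])
  }
  sup <- !is.na(r)
  if (!any(sup)) {
    warning("protein '", protein, "' has no run pair with shared peptides")
    return(out)
  }
  comp <- connected_components(n_run, pairs[, sup, drop = FALSE])
  sizes <- tabulate(comp)
  main <- which.max(sizes)  # ties: earliest-run component wins
  in_main <- comp == main
  if (!all(in_main[colSums(obs) > 0])) {
    warning("protein '", protein, "' has a disconnected run graph; ",
            "profiling only the largest component (",
            paste(runs[in_main], collapse = ", "), ")")
  }
  use <- sup & in_main[pairs[1, ]] & in_main[pairs[2, ]]
  idx <- which(in_main)
  # least squares on the component via its graph Laplacian, pinned to sum 0
  k <- length(idx)
  pos <- match(seq_len(n_run), idx)
  lap <- matrix(0, k, k)
  rhs <- numeric(k)
  for (p in which(use)) {
    a <- pos[pairs[1, p]]; b <- pos[pairs[2, p]]
    lap[a, a] <- lap[a, a] + 1; lap[b, b] <- lap[b, b] + 1
    lap[a, b] <- lap[a, b] - 1; lap[b, a] <- lap[b, a] - 1
    rhs[a] <- rhs[a] + r[p];    rhs[b] <- rhs[b] - r[p]
  }
  sol <- solve(lap + 1 / k, rhs)
  # anchor: summed linear abundance = summed observed intensity in component
  total <- sum(mat[, idx], na.rm = TRUE)
  sol <- sol + log2(total / sum(2^sol))
  out[idx] <- 2^sol
  out
}

# components of an undirected graph given a 2 x m edge index matrix
connected_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (e in seq_len(ncol(edges))) {
      a <- edges[1, e]; b <- edges[2, e]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

#' Roll a full ion matrix up to protein abundances
#'
#' Runs one quantitation branch over every protein of the matrix:
#' `branch = "pai"` computes the Top-3 PAI (expects normalized intensities);
#' `branch = "lfq"` computes pairwise-ratio least-squares profiles on the raw
#' matrix, to be normalized afterwards with [normalize_lfq_table()].
#' Proteins with no LFQ-profilable run pair keep `NA` profiles and a single
#' summary warning is emitted.
#'
#' @param x an [ion_matrix].
#' @param branch `"pai"` or `"lfq"`.
#' @param k reference-peptide cap for the PAI branch.
#' @return a `protein_quant` object: list with `abundance` (protein x run
#'   matrix), `n_peptides` (named integer: quantified peptide ions per
#'   protein), `branch`, `reference_peptides` (PAI branch) and `normalized`.
#' @export
quantify_proteins <- function(x, branch = c("pai", "lfq"), k = 3) {
  stopifnot(inherits(x, "ion_matrix"))
  branch <- match.arg(branch)
  ann <- x$annotations
  proteins <- unique(ann$protein_id)
  runs <- run_ids(x)
  quantified <- rowSums(!is.na(x$intensity)) > 0
  rows_by_prot <- split(seq_len(nrow(ann)), factor(ann$protein_id, proteins))
  abundance <- matrix(NA_real_, length(proteins), length(runs),
                      dimnames = list(proteins, runs))
  n_pep <- stats::setNames(integer(length(proteins)), proteins)
  refs <- if (branch == "pai") stats::setNames(vector("list", length(proteins)),
                                               proteins)
  n_unprofiled <- 0
  for (i in seq_along(proteins)) {
    rows <- rows_by_prot[[i]]
    n_pep[i] <- sum(quantified[rows])
    mat <- x$intensity[rows, , drop = FALSE]
    if (branch == "pai") {
      a <- ann[rows, , drop = FALSE]
      m <- rowMeans(mat, na.rm = TRUE)
      ord <- order(-m, a$peptide_seq, a$charge)
      sel <- ord[seq_len(min(k, sum(!is.nan(m))))]
      refs[[i]] <- a[sel, c("protein_id", "peptide_seq", "charge")]
      abundance[i, ] <- replace_nan_na(colMeans(mat[sel, , drop = FALSE],
                                                na.rm = TRUE))
    } else {
      prof <- withCallingHandlers(
        lfq_profile_core(mat, proteins[i]),
        warning = function(w) {
          n_unprofiled <<- n_unprofiled + 1
          invokeRestart("muffleWarning")
        }
      )
      abundance[i, ] <- prof
    }
  }
  if (branch == "lfq" && n_unprofiled > 0) {
    warning(n_unprofiled, " protein(s) could not be fully profiled ",
            "(single-run or disconnected run graph)")
  }
  structure(
    list(abundance = abundance, n_peptides = n_pep,
         branch = toupper(branch), reference_peptides = refs,
         normalized = if (branch == "pai") x$normalized else FALSE),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf("protein_quant [%s branch]: %d proteins x %d runs (%s)\n",
              x$branch, nrow(x$abundance), ncol(x$abundance),
              if (x$normalized) "normalized" else "not normalized"))
  invisible(x)
}

#' Median normalization of an LFQ protein table
#'
#' Equalizes the per-run medians of the LFQ protein abundances: each run's
#' values are divided by (run median / grand median of the run medians), the
#' protein-level analogue of normalizing intensities by the median of all
#' values of each experiment.
#'
#' @param table a `protein_quant` object from the LFQ branch.
#' @return the normalized `protein_quant`.
#' @export
normalize_lfq_table <- function(table) {
  stopifnot(inherits(table, "protein_quant"))
  if (table$branch != "LFQ") stop("median normalization applies to the LFQ branch")
  med <- apply(table$abundance, 2, stats::median, na.rm = TRUE)
  if (anyNA(med)) {
    stop("run(s) with no quantified proteins: ",
         paste(colnames(table$abundance)[is.na(med)], collapse = ", "))
  }
  grand <- stats::median(med)
  table$abundance <- sweep(table$abundance, 2, med / grand, `/`)
  table$normalized <- TRUE
  table
}

#' Write a protein quantification table
#'
#' TSV with columns `protein_id`, `branch`, `n_peptides`, then one
#' `abundance:<run>` column per run; missing abundances are empty cells.
#'
#' @param table a `protein_quant`.
#' @param path file path.
#' @export
write_protein_table <- function(table, path) {
  ab <- table$abundance
  colnames(ab) <- paste0("abundance:", colnames(ab))
  out <- cbind(data.frame(protein_id = rownames(table$abundance),
                          branch = table$branch,
                          n_peptides = unname(table$n_peptides)),
               as.data.frame(ab, row.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
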