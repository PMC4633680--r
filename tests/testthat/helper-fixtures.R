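# Build a small ion matrix from an intensity matrix; one row per peptide ion.
# Defaults invent unique peptide sequences and plausible m/z / RT values.
toy_matrix <- function(intensity, proteins = "P1", seqs = NULL,
                       charges = 2L, mz = NULL, rt = NULL) {
  intensity <- as.matrix(intensity)
  n <- nrow(intensity)
  if (is.null(colnames(intensity))) {
    colnames(intensity) <- paste0("R", seq_len(ncol(intensity)))
  }
  if (is.null(seqs)) seqs <- sprintf("PEP%03d", seq_len(n))
  ann <- data.frame(
    protein_id = rep_len(proteins, n),
    peptide_seq = seqs,
    charge = rep_len(charges, n),
    mz = if (is.null(mz)) 400 + seq_len(n) else rep_len(mz, n),
    rt = if (is.null(rt)) 10 * seq_len(n) else rep_len(rt, n)
  )
  ion_matrix(ann, intensity)
}

# 3-vs-3 design matching the simulator's run naming
toy_design <- function(n_rep = 3) {
  study_design(c(paste0("WT_", 1:n_rep), paste0("KO_", 1:n_rep)),
               rep(c("WT", "KO"), each = n_rep), rep(1:n_rep, 2))
}

# small, fast generator configuration for pipeline-level tests
small_config <- function(n_background_proteins = 150, ...) {
  generator_config(n_background_proteins = n_background_proteins, ...)
}
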