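#' Configuration for the knockout-vs-wild-type spike-in simulator
#'
#' Describes a bottom-up label-free experiment comparing knockout (KO) and
#' wild-type (WT) proteomes: a log-normal background proteome in which almost
#' every protein is unchanged, a small set of "spiked" proteins that truly
#' accumulate in the knockout (emulating E3-ligase substrates such as the
#' filamins FLNa/FLNb), and an optional marker protein with no signal at all
#' in one condition (emulating the knocked-out protein itself). Peptide-ion
#' intensities are built as
#' `protein abundance x 2^(true log2 FC, KO runs only) x peptide response
#' factor x run scale factor x log-normal technical noise`,
#' with cells removed at `missing_rate`.
#'
#' Default sizes mirror a 3-vs-3 dendritic-cell comparison quantifying on the
#' order of 2,000 proteins; the default spikes carry the filamin-sized fold
#' changes 7.10 and 5.90 (linear KO/WT scale).
#'
#' @param n_background_proteins number of unchanged background proteins.
#' @param peptides_per_protein integer vector `c(min, max)` (uniform draw) or
#'   a single fixed count.
#' @param n_replicates_per_condition replicates per genotype, at least 2.
#' @param base_abundance_log_mean,base_abundance_log_sd natural-log mean/sd of
#'   the log-normal protein abundance background (XIC-area scale).
#' @param peptide_response_log_sd natural-log sd of the fixed per-peptide
#'   response ("flyability") factor, identical across runs.
#' @param technical_cv coefficient of variation of the multiplicative
#'   per-measurement noise (log-normal, unit mean).
#' @param run_scale_factors positive per-run loading biases, length
#'   `2 * n_replicates_per_condition` (WT runs first); `NULL` draws them
#'   log-uniformly from `[0.5, 2]`.
#' @param missing_rate probability that an observed cell is dropped.
#' @param missing_mode `"mcar"` (default: missing completely at random) or
#'   `"censored"` (left-censored: low-intensity cells more likely missing,
#'   overall rate still approximately `missing_rate`).
#' @param spikes data.frame with columns `protein_id`, `true_log2_fc`
#'   (KO over WT) and optionally `n_peptides` (default 12, a filamin-sized
#'   peptide yield).
#' @param absent_markers data.frame with columns `protein_id`, `absent_in`
#'   (`"KO"` or `"WT"`) and optionally `n_peptides` (default 5).
#' @param seed integer seed; `generate_dataset()` is bit-reproducible given
#'   the same config and seed. `NULL` uses the current RNG stream.
#'
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_background_proteins = 2000,
                             peptides_per_protein = c(2L, 12L),
                             n_replicates_per_condition = 3,
                             base_abundance_log_mean = log(1e7),
                             base_abundance_log_sd = 1.5,
                             peptide_response_log_sd = 1.0,
                             technical_cv = 0.20,
                             run_scale_factors = NULL,
                             missing_rate = 0.05,
                             missing_mode = c("mcar", "censored"),
                             spikes = default_spikes(),
                             absent_markers = default_absent_markers(),
                             seed = NULL) {
  missing_mode <- match.arg(missing_mode)
  spikes <- normalize_protein_list(spikes, default_n_peptides = 12L,
                                   fc_column = "true_log2_fc")
  absent_markers <- normalize_protein_list(absent_markers,
                                           default_n_peptides = 5L,
                                           fc_column = NULL)
  cfg <- structure(
    list(n_background_proteins = as.integer(n_background_proteins),
         peptides_per_protein = as.integer(peptides_per_protein),
         n_replicates_per_condition = as.integer(n_replicates_per_condition),
         base_abundance_log_mean = base_abundance_log_mean,
         base_abundance_log_sd = base_abundance_log_sd,
         peptide_response_log_sd = peptide_response_log_sd,
         technical_cv = technical_cv,
         run_scale_factors = run_scale_factors,
         missing_rate = missing_rate,
         missing_mode = missing_mode,
         spikes = spikes,
         absent_markers = absent_markers,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @export
default_spikes <- function() {
  data.frame(protein_id = c("FLNA_like", "FLNB_like"),
             true_log2_fc = log2(c(7.10, 5.90)),
             n_peptides = c(12L, 12L))
}

#' @rdname generator_config
#' @export
default_absent_markers <- function() {
  data.frame(protein_id = "ASB2A_like", absent_in = "KO", n_peptides = 5L)
}

normalize_protein_list <- function(x, default_n_peptides, fc_column) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    out <- data.frame(protein_id = character(0), n_peptides = integer(0))
    if (!is.null(fc_column)) out[[fc_column]] <- numeric(0)
    else out$absent_in <- character(0)
    return(out)
  }
  x <- as.data.frame(x)
  if (is.null(x$n_peptides)) x$n_peptides <- default_n_peptides
  x$n_peptides <- as.integer(x$n_peptides)
  x$protein_id <- as.character(x$protein_id)
  x
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_replicates_per_condition < 2) {
      stop("n_replicates_per_condition must be >= 2 (two-sample test needs ",
           ">= 2 values per group)")
    }
    if (n_background_proteins < 1) stop("n_background_proteins must be positive")
    if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
    if (technical_cv < 0 || peptide_response_log_sd < 0) {
      stop("noise parameters must be non-negative")
    }
    if (!is.null(run_scale_factors)) {
      if (length(run_scale_factors) != 2 * n_replicates_per_condition) {
        stop("run_scale_factors must have one entry per run (",
             2 * n_replicates_per_condition, ")")
      }
      if (any(run_scale_factors <= 0)) stop("run scale factors must be positive")
    }
    labels <- c(spikes$protein_id, absent_markers$protein_id)
    if (anyDuplicated(labels)) {
      stop("duplicate protein label among spikes/absent markers: ",
           labels[duplicated(labels)][1])
    }
    if (nrow(absent_markers) > 0 &&
        !all(absent_markers$absent_in %in% c("WT", "KO"))) {
      stop("absent_in must be 'WT' or 'KO'")
    }
  })
  cfg
}

#' Simulate a knockout-vs-wild-type peptide-ion dataset
#'
#' Draws a full peptide-ion intensity table under the model described in
#' [generator_config()], together with the matching [study_design] and a
#' ground-truth table for recovery testing. Absent-marker proteins are encoded
#' as missing cells (never zeros) in every run of their stated condition.
#'
#' @param config a [generator_config].
#' @return list with elements `ions` ([ion_matrix]), `design`
#'   ([study_design]) and `truth` (data.frame: `protein_id`, `true_log2_fc`,
#'   `is_absent_marker`, `absent_in`, `n_peptides`).
#' @export
#' @examples
#' d <- generate_dataset(generator_config(n_background_proteins = 20, seed = 1))
#' d$ions
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) {
    return(withr::with_seed(config$seed, generate_dataset_impl(config)))
  }
  generate_dataset_impl(config)
}

generate_dataset_impl <- function(cfg) {
  n_rep <- cfg$n_replicates_per_condition
  runs <- c(paste0("WT_", seq_len(n_rep)), paste0("KO_", seq_len(n_rep)))
  is_ko <- rep(c(FALSE, TRUE), each = n_rep)
  design <- study_design(runs, ifelse(is_ko, "KO", "WT"),
                         rep(seq_len(n_rep), 2))

  # truth table: background, then spikes, then absent markers
  width <- max(4, nchar(cfg$n_background_proteins))
  bg_ids <- sprintf(paste0("BG%0", width, "d"), seq_len(cfg$n_background_proteins))
  ppp <- cfg$peptides_per_protein
  bg_npep <- if (length(ppp) == 1) rep(ppp, length(bg_ids)) else
    sample(seq(ppp[1], ppp[2]), length(bg_ids), replace = TRUE)
  truth <- rbind(
    data.frame(protein_id = bg_ids, true_log2_fc = 0,
               is_absent_marker = FALSE, absent_in = NA_character_,
               n_peptides = as.integer(bg_npep)),
    if (nrow(cfg$spikes) > 0)
      data.frame(protein_id = cfg$spikes$protein_id,
                 true_log2_fc = cfg$spikes$true_log2_fc,
                 is_absent_marker = FALSE, absent_in = NA_character_,
                 n_peptides = cfg$spikes$n_peptides),
    if (nrow(cfg$absent_markers) > 0)
      data.frame(protein_id = cfg$absent_markers$protein_id,
                 true_log2_fc = 0, is_absent_marker = TRUE,
                 absent_in = cfg$absent_markers$absent_in,
                 n_peptides = cfg$absent_markers$n_peptides)
  )
  rownames(truth) <- NULL

  n_prot <- nrow(truth)
  n_ion <- sum(truth$n_peptides)
  prot_of_ion <- rep.int(seq_len(n_prot), truth$n_peptides)

  base <- exp(stats::rnorm(n_prot, cfg$base_abundance_log_mean,
                           cfg$base_abundance_log_sd))
  response <- exp(stats::rnorm(n_ion, 0, cfg$peptide_response_log_sd))
  scales <- cfg$run_scale_factors
  if (is.null(scales)) scales <- exp(stats::runif(length(runs),
                                                  log(0.5), log(2)))
  # unit-mean log-normal noise with CV = technical_cv
  sdlog <- sqrt(log(1 + cfg$technical_cv^2))
  noise <- matrix(exp(stats::rnorm(n_ion * length(runs), -sdlog^2 / 2, sdlog)),
                  n_ion, length(runs))
  if (cfg$technical_cv == 0) noise[] <- 1

  fc_mult <- 2^truth$true_log2_fc[prot_of_ion]
  signal <- base[prot_of_ion] * response
  intensity <- signal * noise
  intensity[, is_ko] <- intensity[, is_ko] * rep(fc_mult, sum(is_ko))
  intensity <- sweep(intensity, 2, scales, `*`)

  # missingness (drawn for every cell so the RNG stream does not depend on
  # the missing pattern itself)
  u <- matrix(stats::runif(n_ion * length(runs)), n_ion, length(runs))
  if (cfg$missing_rate > 0) {
    if (cfg$missing_mode == "mcar") {
      intensity[u < cfg$missing_rate] <- NA_real_
    } else {
      # left-censored: logistic dropout around the missing_rate quantile of
      # the log intensities (scale 0.5 natural-log units)
      li <- log(intensity)
      thr <- stats::quantile(li, cfg$missing_rate, names = FALSE)
      p_miss <- stats::plogis((thr - li) / 0.5)
      intensity[u < p_miss] <- NA_real_
    }
  }

  # absent markers: no quantified cell in their stated condition
  if (nrow(cfg$absent_markers) > 0) {
    for (i in seq_len(nrow(cfg$absent_markers))) {
      rows <- prot_of_ion ==
        match(cfg$absent_markers$protein_id[i], truth$protein_id)
      cols <- is_ko == (cfg$absent_markers$absent_in[i] == "KO")
      intensity[rows, cols] <- NA_real_
    }
  }
  colnames(intensity) <- runs

  ann <- data.frame(
    protein_id = truth$protein_id[prot_of_ion],
    peptide_seq = sprintf("PEP%06d", seq_len(n_ion)),
    charge = 2L,
    mz = round(stats::runif(n_ion, 350, 1250), 4),
    rt = round(stats::runif(n_ion, 5, 295), 2)
  )
  # drop ions never observed anywhere except for absent markers, whose rows
  # must surface in the table with their observed-condition signal
  keep <- rowSums(!is.na(intensity)) > 0
  list(ions = ion_matrix(ann[keep, , drop = FALSE],
                         intensity[keep, , drop = FALSE]),
       design = design,
       truth = truth)
}

#' Write / read a ground-truth table
#'
#' Plain TSV (`protein_id`, `true_log2_fc`, `is_absent_marker`, `absent_in`,
#' `n_peptides`) that round-trips losslessly.
#'
#' @param truth the `truth` data.frame from [generate_dataset()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  if (is.null(truth) || nrow(truth) == 0) stop("ground truth is empty")
  out <- truth
  out$true_log2_fc <- format(out$true_log2_fc, digits = 17, trim = TRUE,
                             scientific = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", na.strings = "",
                           colClasses = c(protein_id = "character",
                                          true_log2_fc = "numeric",
                                          is_absent_marker = "logical",
                                          absent_in = "character",
                                          n_peptides = "integer"))
  tab
}
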