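#' Thresholds for quantifiability filtering and candidate calling
#'
#' The defaults encode the selection rule used for knockout-vs-wild-type
#' substrate screening: a protein is quantifiable if it was quantified by at
#' least `min_peptides` peptides and has quantitative data in every run
#' (`require_complete`); it is differential if |log2 fold change| exceeds
#' `log2fc_cutoff` (2^0.85 = 1.80, i.e. an over 1.8-fold change) with a
#' two-sample p-value below `p_cutoff`.
#'
#' @param log2fc_cutoff absolute log2 fold-change cutoff (default 0.85).
#' @param p_cutoff p-value cutoff (default 0.05, uncorrected).
#' @param min_peptides minimum quantified peptides per protein (default 2).
#' @param require_complete require an abundance in every run (default TRUE).
#' @return list of class `thresholds`.
#' @export
thresholds <- function(log2fc_cutoff = 0.85, p_cutoff = 0.05,
                       min_peptides = 2, require_complete = TRUE) {
  stopifnot(log2fc_cutoff > 0, p_cutoff > 0, min_peptides >= 1)
  structure(list(log2fc_cutoff = log2fc_cutoff, p_cutoff = p_cutoff,
                 min_peptides = as.integer(min_peptides),
                 require_complete = isTRUE(require_complete)),
            class = "thresholds")
}

#' Keep only quantifiable proteins
#'
#' Retains exactly the proteins with `n_peptides >= min_peptides` and, when
#' `require_complete`, no missing abundance in any run. Exclusion reasons are
#' attached as the `"exclusions"` attribute (a data.frame of `protein_id`,
#' `reason`) and summarized in a message.
#'
#' @param table a `protein_quant`.
#' @param design a [study_design] matching the table's runs.
#' @param th a [thresholds] object.
#' @return the filtered `protein_quant`, with an `"exclusions"` attribute.
#' @export
filter_quantifiable <- function(table, design, th = thresholds()) {
  stopifnot(inherits(table, "protein_quant"), inherits(th, "thresholds"))
  check_design_matches(design, colnames(table$abundance))
  few <- table$n_peptides < th$min_peptides
  incomplete <- if (th$require_complete) {
    rowSums(is.na(table$abundance)) > 0
  } else {
    rep(FALSE, nrow(table$abundance))
  }
  drop <- few | incomplete
  exclusions <- data.frame(
    protein_id = rownames(table$abundance)[drop],
    reason = ifelse(few[drop] & incomplete[drop], "few peptides; incomplete",
                    ifelse(few[drop], "fewer peptides than min_peptides",
                           "missing abundance in at least one run"))
  )
  if (nrow(exclusions) > 0) {
    message(sprintf("filter_quantifiable: excluded %d of %d proteins (%s)",
                    nrow(exclusions), nrow(table$abundance), table$branch))
  }
  keep <- !drop
  table$abundance <- table$abundance[keep, , drop = FALSE]
  table$n_peptides <- table$n_peptides[keep]
  if (!is.null(table$reference_peptides)) {
    table$reference_peptides <- table$reference_peptides[keep]
  }
  attr(table, "exclusions") <- exclusions
  table
}

#' Welch's two-sample test on log2 abundances
#'
#' Two-sided unequal-variance (Welch) t-test of knockout versus wild-type
#' protein abundances, performed on log2-transformed values with the
#' Welch-Satterthwaite degrees of freedom; `var_equal = TRUE` switches to the
#' pooled-variance t-test. Note that with only three replicates per group the
#' Welch test is conservative (its true type-I error at nominal 0.05 is about
#' 0.035 under equal variances); the pooled test is exact there.
#' Degenerate zero-variance groups follow a fixed convention: if both groups
#' have zero variance and equal means, t = 0 and p = 1; if the means differ
#' with zero total variance, p is the smallest representable positive double.
#'
#' @param values_ko,values_wt positive linear-scale abundances, at least 2
#'   per group; log2 is taken internally.
#' @param var_equal use the pooled-variance t-test instead of Welch's.
#' @return list with `t_statistic`, `df` and `p_value` (in (0, 1]).
#' @export
two_sample_test <- function(values_ko, values_wt, var_equal = FALSE) {
  if (length(values_ko) < 2 || length(values_wt) < 2) {
    stop("need at least 2 values per group")
  }
  if (anyNA(c(values_ko, values_wt)) || any(c(values_ko, values_wt) <= 0)) {
    stop("abundances must be positive and non-missing")
  }
  x <- log2(values_ko)
  y <- log2(values_wt)
  n1 <- length(x); n2 <- length(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  delta <- mean(x) - mean(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (delta == 0) {
      return(list(t_statistic = 0, df = n1 + n2 - 2, p_value = 1))
    }
    return(list(t_statistic = sign(delta) * Inf, df = n1 + n2 - 2,
                p_value = .Machine$double.xmin))
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  t_stat <- delta / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_statistic = t_stat, df = df,
       p_value = max(p, .Machine$double.xmin))
}

#' Per-protein differential table
#'
#' For every protein of a (filtered) quantification table, computes the mean
#' log2 abundance per condition, the log2 fold change (KO minus WT, i.e. the
#' log2 knockout-over-wild-type ratio), the Welch test, and the threshold
#' flags. A Benjamini-Hochberg adjusted p-value column is included for
#' information only; candidate calling uses the raw p-value, matching the
#' screening rule.
#'
#' @param table a `protein_quant`, normally after [filter_quantifiable()].
#' @param design a [study_design].
#' @param th a [thresholds] object.
#' @param var_equal use the pooled-variance t-test instead of Welch's
#'   (see [two_sample_test()]).
#' @return data.frame of class `differential_table` with columns
#'   `protein_id`, `branch`, `n_peptides`, `mean_log2_wt`, `mean_log2_ko`,
#'   `log2_fc`, `t_statistic`, `df`, `p_value`, `p_bh`, `passes_fc`,
#'   `passes_p`, `passes_filters`; thresholds and branch kept as attributes.
#' @export
build_differential_table <- function(table, design, th = thresholds(),
                                     var_equal = FALSE) {
  stopifnot(inherits(table, "protein_quant"), inherits(th, "thresholds"))
  check_design_matches(design, colnames(table$abundance))
  ko_runs <- condition_runs(design, "KO")
  wt_runs <- condition_runs(design, "WT")
  ab <- table$abundance
  n <- nrow(ab)
  log2_fc <- t_stat <- dfree <- p_val <- mean_ko <- mean_wt <- rep(NA_real_, n)
  ok <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ko <- ab[i, ko_runs]
    wt <- ab[i, wt_runs]
    ko <- ko[!is.na(ko)]
    wt <- wt[!is.na(wt)]
    if (length(ko) < 2 || length(wt) < 2) next
    ok[i] <- TRUE
    mean_ko[i] <- mean(log2(ko))
    mean_wt[i] <- mean(log2(wt))
    log2_fc[i] <- mean_ko[i] - mean_wt[i]
    tt <- two_sample_test(ko, wt, var_equal = var_equal)
    t_stat[i] <- tt$t_statistic
    dfree[i] <- tt$df
    p_val[i] <- tt$p_value
  }
  out <- data.frame(
    protein_id = rownames(ab),
    branch = table$branch,
    n_peptides = unname(table$n_peptides),
    mean_log2_wt = mean_wt,
    mean_log2_ko = mean_ko,
    log2_fc = log2_fc,
    t_statistic = t_stat,
    df = dfree,
    p_value = p_val,
    p_bh = stats::p.adjust(p_val, method = "BH"),
    passes_fc = !is.na(log2_fc) & abs(log2_fc) > th$log2fc_cutoff,
    passes_p = !is.na(p_val) & p_val < th$p_cutoff,
    passes_filters = ok & table$n_peptides >= th$min_peptides &
      (!th$require_complete | rowSums(is.na(ab)) == 0)
  )
  rownames(out) <- NULL
  structure(out, class = c("differential_table", "data.frame"),
            thresholds = th, branch = table$branch)
}

#' @rdname build_differential_table
#' @param x a `differential_table`.
#' @param path file path for the TSV export.
#' @export
write_differential_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
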