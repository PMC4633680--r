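# independent Welch oracle: direct transcription of the closed form
welch_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  se2 <- var(x) / n1 + var(y) / n2
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

mk_quant <- function(ab, n_pep, branch = "PAI") {
  structure(list(abundance = ab,
                 n_peptides = setNames(as.integer(n_pep), rownames(ab)),
                 branch = branch, reference_peptides = NULL,
                 normalized = TRUE),
            class = "protein_quant")
}

design6 <- toy_design()

test_that("the completeness and min-peptide filters keep exactly the quantifiable proteins", {
  ab <- matrix(1000, 3, 6, dimnames = list(c("one", "two", "five"),
                                           design6$run_id))
  q <- mk_quant(ab, c(1, 2, 5))
  f <- suppressMessages(filter_quantifiable(q, design6))
  expect_identical(rownames(f$abundance), c("two", "five"))
  expect_identical(attr(f, "exclusions")$protein_id, "one")
  # a protein missing in one KO run is excluded under require_complete
  ab2 <- ab
  ab2["five", "KO_2"] <- NA
  f2 <- suppressMessages(filter_quantifiable(mk_quant(ab2, c(1, 2, 5)), design6))
  expect_identical(rownames(f2$abundance), "two")
  expect_match(attr(f2, "exclusions")$reason[2], "missing")
  # but kept when completeness is not required
  f3 <- suppressMessages(filter_quantifiable(
    mk_quant(ab2, c(1, 2, 5)), design6, thresholds(require_complete = FALSE)))
  expect_identical(rownames(f3$abundance), c("two", "five"))
})

test_that("an empty table filters to an empty table without error", {
  ab <- matrix(numeric(0), 0, 6, dimnames = list(NULL, design6$run_id))
  f <- filter_quantifiable(mk_quant(ab, integer(0)), design6)
  expect_identical(nrow(f$abundance), 0L)
})

test_that("Welch test matches an independent closed-form oracle and stats::t.test", {
  ko <- c(10, 11, 12)
  wt <- c(13, 14, 15)
  res <- two_sample_test(2^ko, 2^wt)  # log2 restores the fixture values
  ora <- welch_oracle(ko, wt)
  expect_equal(res$t_statistic, ora$t)
  expect_equal(res$df, ora$df)
  expect_equal(res$p_value, ora$p)
  tt <- t.test(ko, wt)
  expect_equal(res$t_statistic, unname(tt$statistic))
  expect_equal(res$p_value, tt$p.value)
  withr::local_seed(23)
  for (i in 1:20) {
    a <- exp(rnorm(sample(2:6, 1), 8, 1))
    b <- exp(rnorm(sample(2:6, 1), 7, 2))
    res <- two_sample_test(a, b)
    tt <- t.test(log2(a), log2(b))
    expect_equal(res$t_statistic, unname(tt$statistic))
    expect_equal(res$p_value, tt$p.value)
  }
})

test_that("degenerate zero-variance groups follow the documented convention", {
  eq <- two_sample_test(c(4, 4, 4), c(4, 4, 4))
  expect_identical(eq$t_statistic, 0)
  expect_identical(eq$p_value, 1)
  ne <- two_sample_test(c(8, 8, 8), c(4, 4, 4))
  expect_identical(ne$t_statistic, Inf)
  expect_identical(ne$p_value, .Machine$double.xmin)
  expect_error(two_sample_test(c(1, 2), 3), "at least 2")
  expect_error(two_sample_test(c(1, 2), c(-1, 2)), "positive")
})

test_that("type-I error is controlled at 10,000 null proteins, 3 vs 3", {
  withr::local_seed(707)
  n <- 10000
  p_welch <- p_pooled <- numeric(n)
  for (i in seq_len(n)) {
    vals <- 2^rnorm(6, 10, 0.5)
    p_welch[i] <- two_sample_test(vals[1:3], vals[4:6])$p_value
    p_pooled[i] <- two_sample_test(vals[1:3], vals[4:6],
                                   var_equal = TRUE)$p_value
  }
  # Welch never exceeds the nominal level; at 3 replicates per group it is
  # conservative (true size about 0.035 under equal variances)
  expect_lte(mean(p_welch < 0.05), 0.055)
  expect_gte(mean(p_welch < 0.05), 0.025)
  # the pooled-variance test is exact under the equal-variance null
  expect_gte(mean(p_pooled < 0.05), 0.04)
  expect_lte(mean(p_pooled < 0.05), 0.06)
  # Welch never reports smaller p than its pooled counterpart here
  expect_true(all(p_welch >= p_pooled - 1e-12))
})

test_that("fold-change flags realize the over-1.8-fold rule", {
  ab <- rbind(
    doubled = c(1000, 1010, 990, 2000, 2020, 1980),
    mild = c(1000, 1010, 990, 1500, 1515, 1485)
  )
  colnames(ab) <- design6$run_id
  d <- build_differential_table(mk_quant(ab, c(3, 3)), design6)
  expect_equal(d$log2_fc[1], 1, tolerance = 0.01)
  expect_true(d$passes_fc[1])
  # 1.5-fold (log2 ~ 0.585) never passes, whatever the p-value
  expect_false(d$passes_fc[2])
  expect_true(d$passes_p[2])
})

test_that("flags are pure functions of the emitted columns", {
  d <- generate_dataset(small_config(seed = 31))
  q <- quantify_proteins(apply_normalization(d$ions, compute_normalization(d$ions)),
                         "pai")
  th <- thresholds()
  tab <- build_differential_table(
    suppressMessages(filter_quantifiable(q, d$design, th)), d$design, th)
  expect_identical(tab$passes_fc, abs(tab$log2_fc) > th$log2fc_cutoff)
  expect_identical(tab$passes_p, tab$p_value < th$p_cutoff)
})

test_that("swapping condition labels negates log2_fc and preserves p-values", {
  d <- generate_dataset(small_config(seed = 37))
  q <- quantify_proteins(apply_normalization(d$ions, compute_normalization(d$ions)),
                         "pai")
  f <- suppressMessages(filter_quantifiable(q, d$design))
  tab <- build_differential_table(f, d$design)
  swapped <- d$design
  swapped$condition <- ifelse(d$design$condition == "WT", "KO", "WT")
  tab_sw <- build_differential_table(f, swapped)
  expect_equal(tab_sw$log2_fc, -tab$log2_fc)
  expect_equal(tab_sw$p_value, tab$p_value)
})

test_that("raising the fold-change cutoff never adds a passing protein", {
  d <- generate_dataset(small_config(seed = 41))
  q <- quantify_proteins(apply_normalization(d$ions, compute_normalization(d$ions)),
                         "pai")
  f <- suppressMessages(filter_quantifiable(q, d$design))
  cutoffs <- c(0.4, 0.85, 1.5, 2.5)
  passing <- lapply(cutoffs, function(cc) {
    tab <- build_differential_table(f, d$design, thresholds(log2fc_cutoff = cc))
    tab$protein_id[tab$passes_fc & tab$passes_p]
  })
  for (i in seq_along(cutoffs)[-1]) {
    expect_true(all(passing[[i]] %in% passing[[i - 1]]))
  }
})

test_that("an all-null table yields a candidate-rate far below the p cutoff", {
  cfg <- generator_config(n_background_proteins = 400, spikes = NULL,
                          absent_markers = NULL, seed = 43)
  d <- generate_dataset(cfg)
  rep <- run_pipeline(ions = d$ions, design = d$design)
  both <- rep$diff_pai$passes_fc & rep$diff_pai$passes_p
  expect_lt(mean(both), 0.01)
  # raw p-values alone reject at about the nominal rate
  expect_lt(abs(mean(rep$diff_pai$passes_p) - 0.05), 0.04)
})
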