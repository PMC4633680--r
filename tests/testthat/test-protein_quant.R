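# independent Top-3 oracle: sort all peptides of the protein by cross-run
# mean (observed cells only), average the best <=3 per run
pai_oracle <- function(mat) {
  m <- rowMeans(mat, na.rm = TRUE)
  sel <- order(-m)[seq_len(min(3, sum(!is.nan(m))))]
  v <- colMeans(mat[sel, , drop = FALSE], na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  v
}

test_that("the top three peptides by cross-run mean are the reference set", {
  x <- toy_matrix(cbind(A = c(100, 80, 60, 40, 20), B = c(100, 80, 60, 40, 20)),
                  seqs = c("E", "D", "C", "B", "A"))
  ref <- select_reference_peptides(x, "P1")
  expect_identical(ref$peptide_seq, c("E", "D", "C"))
  # one- and two-peptide proteins: everything available is used
  x2 <- toy_matrix(cbind(A = c(5, 9)), seqs = c("A", "B"))
  expect_identical(nrow(select_reference_peptides(x2, "P1")), 2L)
})

test_that("exact ties at rank 3 break on the smaller ion key, stably under shuffling", {
  ints <- cbind(A = c(100, 80, 60, 60, 20))
  seqs <- c("AAK", "BBK", "ZZK", "CCK", "DDK")  # tie between ZZK and CCK
  base <- select_reference_peptides(toy_matrix(ints, seqs = seqs), "P1")
  expect_identical(base$peptide_seq, c("AAK", "BBK", "CCK"))
  withr::local_seed(7)
  for (i in 1:10) {
    perm <- sample(5)
    shuffled <- select_reference_peptides(
      toy_matrix(ints[perm, , drop = FALSE], seqs = seqs[perm]), "P1")
    expect_identical(shuffled, base)
  }
})

test_that("PAI is the run-wise mean of the reference areas and is linear in run scale", {
  x <- toy_matrix(cbind(A = c(100, 80, 60), B = c(200, 160, 120)))
  expect_equal(compute_pai(x, "P1"), c(A = 80, B = 160))
  # single-peptide protein: PAI equals that peptide's area
  x1 <- toy_matrix(cbind(A = 42, B = 17))
  expect_equal(compute_pai(x1, "P1"), c(A = 42, B = 17))
  # scaling a run scales its PAI
  x2 <- toy_matrix(cbind(A = c(100, 80, 60), B = 3 * c(100, 80, 60)))
  p <- compute_pai(x2, "P1")
  expect_equal(p[["B"]], 3 * p[["A"]])
})

test_that("PAI implementation matches the brute-force oracle on 1000 random proteins", {
  withr::local_seed(303)
  for (i in 1:1000) {
    k <- sample(1:8, 1)
    mat <- matrix(exp(rnorm(k * 4, 8, 2)), k,
                  dimnames = list(NULL, paste0("R", 1:4)))
    if (k > 1) mat[runif(length(mat)) < 0.2] <- NA
    mat <- mat[rowSums(!is.na(mat)) > 0, , drop = FALSE]
    if (nrow(mat) == 0) next
    x <- toy_matrix(mat)
    expect_equal(compute_pai(x, "P1"), pai_oracle(mat))
  }
})

test_that("LFQ profile reproduces a consistent peptide ratio exactly", {
  wt <- c(100, 50, 20)
  x <- toy_matrix(cbind(WT = wt, KO = 2 * wt))
  prof <- compute_lfq_profile(x, "P1")
  expect_equal(prof[["KO"]] / prof[["WT"]], 2, tolerance = 1e-9)
  # the anchor: summed linear abundance equals summed observed intensity
  expect_equal(sum(prof), sum(x$intensity), tolerance = 1e-9)
})

test_that("two runs with peptide ratios 2 and 8 give the median-ratio profile 4", {
  x <- toy_matrix(cbind(A = c(20, 80), B = c(10, 10)))
  prof <- compute_lfq_profile(x, "P1")
  expect_equal(prof[["A"]] / prof[["B"]], 4, tolerance = 1e-9)
})

test_that("the pairwise solver matches the analytic 2-run solution and a brute-force grid on 3 runs", {
  # 2-run closed form: log2 ratio = median over shared peptides
  withr::local_seed(11)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    mat <- matrix(exp(rnorm(k * 2, 6, 1)), k, dimnames = list(NULL, c("A", "B")))
    prof <- compute_lfq_profile(toy_matrix(mat), "P1")
    expected <- median(log2(mat[, "A"] / mat[, "B"]))
    expect_equal(log2(prof[["A"]] / prof[["B"]]), expected, tolerance = 1e-9)
  }
  # 3-run instance vs brute-force minimization of the pairwise objective
  mat <- matrix(exp(rnorm(12, 6, 1)), 4, dimnames = list(NULL, c("A", "B", "C")))
  mat[1, 2] <- NA
  prof <- compute_lfq_profile(toy_matrix(mat), "P1")
  r <- c(AB = NA, AC = NA, BC = NA)
  pairs <- list(AB = c(1, 2), AC = c(1, 3), BC = c(2, 3))
  for (p in names(pairs)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    sh <- !is.na(mat[, a]) & !is.na(mat[, b])
    r[p] <- median(log2(mat[sh, a] / mat[sh, b]))
  }
  obj <- function(x) sum((c(x[1] - x[2], x[1] - x[3], x[2] - x[3]) - r)^2)
  fit <- optim(c(0, 0, 0), obj, method = "BFGS",
               control = list(reltol = 1e-14))
  x_hat <- log2(prof) - mean(log2(prof))
  x_ref <- fit$par - mean(fit$par)
  expect_equal(unname(x_hat), x_ref, tolerance = 1e-6)
})

test_that("a disconnected run graph profiles the largest component, others missing", {
  mat <- cbind(A = c(10, NA, NA), B = c(20, NA, NA),
               C = c(NA, 5, 7), D = c(NA, 10, 14), E = c(NA, 20, 28))
  expect_warning(prof <- compute_lfq_profile(toy_matrix(mat), "P1"),
                 "disconnected")
  expect_true(all(is.na(prof[c("A", "B")])))
  expect_equal(prof[["D"]] / prof[["C"]], 2, tolerance = 1e-9)
  expect_equal(prof[["E"]] / prof[["C"]], 4, tolerance = 1e-9)
})

test_that("both branches are ratio-consistent in the noise-free limit", {
  cfg <- generator_config(n_background_proteins = 15, technical_cv = 0,
                          missing_rate = 0, run_scale_factors = rep(1, 6),
                          spikes = data.frame(protein_id = "S",
                                              true_log2_fc = log2(3),
                                              n_peptides = 5),
                          absent_markers = NULL, seed = 13)
  d <- generate_dataset(cfg)
  for (branch in c("pai", "lfq")) {
    q <- quantify_proteins(d$ions, branch)
    ab <- q$abundance["S", ]
    expect_equal(mean(ab[4:6]) / mean(ab[1:3]), 3, tolerance = 1e-9)
  }
})

test_that("quantify_proteins agrees with the per-protein operations", {
  d <- generate_dataset(small_config(seed = 17, n_background_proteins = 30))
  q_pai <- quantify_proteins(d$ions, "pai")
  q_lfq <- suppressWarnings(quantify_proteins(d$ions, "lfq"))
  for (p in sample(rownames(q_pai$abundance), 5)) {
    expect_equal(q_pai$abundance[p, ], compute_pai(d$ions, p))
    expect_equal(q_lfq$abundance[p, ],
                 suppressWarnings(compute_lfq_profile(d$ions, p)))
  }
})

test_that("median normalization of the LFQ table equalizes run medians", {
  d <- generate_dataset(small_config(seed = 19))
  q <- suppressWarnings(quantify_proteins(d$ions, "lfq"))
  qn <- normalize_lfq_table(q)
  med <- apply(qn$abundance, 2, median, na.rm = TRUE)
  expect_lt(max(med) - min(med), 1e-9 * max(med))
  # grand-median convention keeps the overall scale
  expect_equal(median(med), median(apply(q$abundance, 2, median, na.rm = TRUE)),
               tolerance = 1e-9)
  # a uniformly 3x run is divided back onto the others
  m <- q$abundance
  q3 <- q
  q3$abundance[, "KO_1"] <- m[, "KO_1"] * 3
  qn3 <- normalize_lfq_table(q3)
  med3 <- apply(qn3$abundance, 2, median, na.rm = TRUE)
  expect_lt(max(med3) - min(med3), 1e-9 * max(med3))
  # an already-equalized table is unchanged
  expect_equal(normalize_lfq_table(qn)$abundance, qn$abundance,
               tolerance = 1e-12)
  expect_error(normalize_lfq_table(quantify_proteins(d$ions, "pai")),
               "LFQ")
})
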