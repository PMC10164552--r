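# Build a csp_profile directly from values (bypassing tracking) for
# threshold tests.
profile_from <- function(csp, ids = seq_along(csp), status = NULL) {
  if (is.null(status)) status <- ifelse(is.na(csp), "broadened", "observed")
  out <- data.frame(residue_id = as.integer(ids), csp = csp, status = status,
                    significant = NA, stringsAsFactors = FALSE)
  attr(out, "reference_point") <- 1L
  attr(out, "weight_n") <- 0.154
  class(out) <- c("csp_profile", "data.frame")
  out
}

test_that("a single outlier is trimmed from the statistic yet called significant", {
  prof <- profile_from(c(rep(0.01, 9), 0.50))
  res <- significance_threshold(prof)
  expect_equal(res$threshold, 0.01)
  expect_equal(res$trimmed_ids, 10L)
  expect_equal(res$significant_ids, 10L)
  expect_equal(res$n_used, 9L)
})

test_that("the 20-term arithmetic series reproduces the hand-derived threshold", {
  prof <- profile_from(seq(0.01, 0.20, by = 0.01))
  res <- significance_threshold(prof)
  # trim ceil(2) largest -> remainder 0.01..0.18; mean 0.095, SD 0.0518813
  expect_equal(res$trimmed_ids, c(19L, 20L))
  expect_equal(res$threshold, 0.1987626, tolerance = 1e-6)
  expect_equal(res$significant_ids, 20L)
})

test_that("equal CSPs give an empty significant set (strict inequality)", {
  prof <- profile_from(rep(0.05, 12))
  res <- significance_threshold(prof)
  expect_equal(res$threshold, 0.05)
  expect_length(res$significant_ids, 0)
})

test_that("undefined CSPs are excluded entirely and small sets are rejected", {
  prof <- profile_from(c(0.01, 0.02, NA, 0.03, NA))
  res <- significance_threshold(prof)
  expect_equal(res$n_used + length(res$trimmed_ids), 3L)
  expect_error(significance_threshold(profile_from(c(0.1, 0.2, NA, NA))),
               "at least 3")
})

test_that("threshold equals a literal brute-force implementation on random vectors", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(5:300, 1)
    x <- round(stats::rlnorm(n, log(0.03), 1), 6)
    prof <- profile_from(x)
    res <- significance_threshold(prof)
    oracle <- brute_threshold(x, seq_len(n))
    expect_equal(res$threshold, oracle$threshold, tolerance = 1e-12)
    expect_identical(res$significant_ids, oracle$significant_ids)
    expect_equal(res$n_used, oracle$n_used)
  }
})

test_that("threshold is scale-equivariant and the significant set is preserved", {
  set.seed(7)
  x <- stats::rlnorm(40, log(0.02), 0.8)
  res1 <- significance_threshold(profile_from(x))
  for (c_scale in c(0.1, 3, 250)) {
    res2 <- significance_threshold(profile_from(c_scale * x))
    expect_equal(res2$threshold, c_scale * res1$threshold, tolerance = 1e-12)
    expect_identical(res2$significant_ids, res1$significant_ids)
  }
})

test_that("trim-boundary ties retain the lower residue id in the statistic", {
  # ten values; the two largest are tied; ceil(0.1*10) = 1 trimmed
  x <- c(rep(0.01, 8), 0.30, 0.30)
  res <- significance_threshold(profile_from(x))
  expect_equal(res$trimmed_ids, 10L)  # higher id trimmed, lower retained
})

test_that("classify annotates flags and threshold consistently with the result", {
  set.seed(12)
  x <- c(stats::rlnorm(30, log(0.01), 0.4), 0.4, 0.5)
  prof <- profile_from(c(x, NA))
  res <- significance_threshold(prof)
  ann <- classify(prof, res)
  expect_identical(ann$residue_id[which(ann$significant)], res$significant_ids)
  expect_equal(attr(ann, "threshold"), res$threshold)
  expect_true(is.na(ann$significant[is.na(ann$csp)]))
  # a result from a different profile is rejected
  other <- significance_threshold(profile_from(c(1, 2, 3, 4), ids = 101:104))
  expect_error(classify(prof, other), "match")
})

test_that("planted strong binders are always flagged; noise false positives are rare", {
  # With effect >> noise every planted binder must exceed the threshold; a
  # mean + 2 SD rule still admits occasional upper-tail noise crossers, so
  # false positives are bounded, not forbidden.
  sim <- simulate_titration(simulation_config(
    n_residues = 60, binder_fraction = 0.1, true_kd = 0.025,
    ddmax_range = c(0.15, 0.3), broaden_prob = 0, seed = 21))
  b <- run_pipeline(sim, verbose = FALSE)
  planted <- sim$truth$residue_id[sim$truth$binder]
  usable <- b$profile$residue_id[!is.na(b$profile$csp)]
  expect_true(all(sort(intersect(planted, usable)) %in% b$significance$significant_ids))
  false_pos <- setdiff(b$significance$significant_ids, planted)
  expect_lte(length(false_pos), 3L)
  # false positives are marginal crossers, far below the real binders
  if (length(false_pos)) {
    fp_csp <- b$profile$csp[b$profile$residue_id %in% false_pos]
    binder_csp <- b$profile$csp[b$profile$residue_id %in% planted]
    expect_lt(max(fp_csp), min(binder_csp, na.rm = TRUE))
  }
  # at zero noise the equality is exact
  sim0 <- simulate_titration(simulation_config(
    n_residues = 60, binder_fraction = 0.1, true_kd = 0.025,
    ddmax_range = c(0.15, 0.3), noise_h = 0, noise_n = 0,
    broaden_prob = 0, seed = 21))
  b0 <- run_pipeline(sim0, verbose = FALSE)
  expect_identical(b0$significance$significant_ids,
                   sim0$truth$residue_id[sim0$truth$binder])
})
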