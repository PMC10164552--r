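test_that("predict_csp honours its analytic special cases", {
  expect_equal(predict_csp(0.1, 0, kd = 0.5), 0)
  # stoichiometric limit at Kd = 0: piecewise-linear in [L]
  expect_equal(predict_csp(0.1, 0.05, kd = 0, ddmax = 1), 0.5)
  expect_equal(predict_csp(0.1, 0.25, kd = 0, ddmax = 1), 1)
  # frozen hand evaluation of the depletion quadratic
  expect_equal(predict_csp(0.1, 0.1, kd = 0.025, ddmax = 1), 0.6096118, tolerance = 1e-6)
  expect_error(predict_csp(-0.1, 0.1, kd = 0.1), "protein_conc")
  expect_error(predict_csp(0.1, -0.1, kd = 0.1), "ligand_conc")
})

test_that("predict_csp matches the bisection mass-action oracle", {
  for (P in c(0.01, 0.1, 1)) {
    for (ratio in c(0, 0.3, 1, 2.7, 10, 20)) {
      for (kd in c(1e-4, 0.01, 0.3, 10)) {
        expect_equal(predict_csp(P, ratio * P, kd, 1),
                     bisect_bound_fraction(P, ratio * P, kd),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("predict_csp is monotone in [L] and Kd and saturates at ddmax", {
  L <- seq(0, 5, length.out = 80)
  v <- predict_csp(0.1, L, kd = 0.2, ddmax = 0.3)
  expect_true(all(diff(v) >= 0))
  kds <- c(0.01, 0.1, 0.5, 2)
  at <- vapply(kds, function(k) predict_csp(0.1, 0.3, k, 0.3), numeric(1))
  expect_true(all(diff(at) <= 0))
  expect_equal(predict_csp(0.1, 1e6 * 0.2, kd = 0.2, ddmax = 0.3), 0.3,
               tolerance = 1e-6)
})

test_that("weak binding reduces to the non-depleted hyperbola within 2%", {
  P <- 0.1
  kd <- 100 * P
  L <- seq(0.05, 20, length.out = 50)
  full <- predict_csp(P, L, kd, 1)
  hyper <- L / (L + kd)
  expect_true(all(abs(full - hyper) / hyper < 0.02))
})

test_that("noiseless synthetic curves invert to the generating parameters", {
  ratios <- c(0, 0.5, 1, 2, 3, 4, 6, 10)
  P <- 0.1
  csp <- predict_csp(P, ratios * P, kd = 0.12, ddmax = 0.2)
  fit <- fit_csp_curve(csp, P, ratios)
  expect_true(fit$converged)
  expect_equal(fit$kd, 0.12, tolerance = 1e-4)
  expect_equal(fit$ddmax, 0.2, tolerance = 1e-4)
})

test_that("flat trajectories are flagged non-binders, short ones are errors", {
  ratios <- c(0, 0.5, 1, 2, 4, 6)
  flat <- fit_csp_curve(rep(0, length(ratios)), 0.1, ratios)
  expect_true(flat$nonbinder)
  expect_false(flat$converged)
  short <- c(0, 1, 2)
  expect_error(fit_csp_curve(predict_csp(0.1, short * 0.1, 0.1, 0.2), 0.1, short),
               "4 observed points")
})

test_that("aggregate Kd reports mean and sample SD in display form", {
  fits <- data.frame(residue_id = 1:3, kd = c(0.020, 0.025, 0.030),
                     ddmax = 0.2, rss = 0, converged = TRUE, n_points = 8L,
                     nonbinder = FALSE)
  agg <- aggregate_kd(fits, significant_ids = 1:3, protein_conc = 0.1)
  expect_equal(agg$mean_kd, 0.025)
  expect_equal(agg$sd_kd, 0.005)  # hand computation: sqrt(((0.005)^2*2)/2)
  expect_equal(agg$n_residues, 3L)
  expect_equal(agg$display, "0.025 ± 0.005 mM")
})

test_that("a single contributor has no SD and a bare display", {
  fits <- data.frame(residue_id = 7L, kd = 0.12, ddmax = 0.2, rss = 0,
                     converged = TRUE, n_points = 8L, nonbinder = FALSE)
  agg <- aggregate_kd(fits, 7L, 0.1)
  expect_true(is.na(agg$sd_kd))
  expect_equal(agg$display, "0.12 mM")
})

test_that("non-converged significant residues are excluded, empty sets error", {
  fits <- data.frame(residue_id = 1:2, kd = c(0.02, 0.9), ddmax = 0.2, rss = 0,
                     converged = c(TRUE, FALSE), n_points = 8L, nonbinder = FALSE)
  agg <- aggregate_kd(fits, 1:2, 0.1)
  expect_equal(agg$n_residues, 1L)
  expect_equal(agg$excluded_ids, 2L)
  expect_error(aggregate_kd(fits[0, ], 1:2, 0.1), "aggregate")
})

test_that("the upper-limit rule rewrites only means strictly below [P]/10", {
  mk <- function(kd) {
    fits <- data.frame(residue_id = 1L, kd = kd, ddmax = 0.2, rss = 0,
                       converged = TRUE, n_points = 8L, nonbinder = FALSE)
    aggregate_kd(fits, 1L, 0.1)
  }
  tight <- apply_upper_limit(mk(0.005))
  expect_equal(tight$upper_limit, 0.01)
  expect_equal(tight$display, "< 0.01 mM")
  mid <- apply_upper_limit(mk(0.02))
  expect_null(mid$upper_limit)
  expect_equal(mid$display, "0.02 mM")
  boundary <- apply_upper_limit(mk(0.01))  # strict less-than
  expect_null(boundary$upper_limit)
})

test_that("Kd set comparison: fold-change and degenerate identical sets", {
  cmp <- compare_kd_sets(c(1, 1, 1), c(2, 2, 2))
  expect_equal(cmp$fold_change, 0.5)
  same <- compare_kd_sets(c(0.4, 0.41, 0.42), c(0.4, 0.41, 0.42))
  expect_equal(same$fold_change, 1.0)
  expect_equal(same$p_value, 1.0)
  const <- compare_kd_sets(c(1, 1), c(1, 1))
  expect_equal(const$p_value, 1.0)
  expect_error(compare_kd_sets(numeric(0), 1), "nonempty")
})

test_that("Welch test agrees with a hand-coded oracle to 1e-10", {
  a <- c(0.40, 0.41, 0.42)
  b <- c(0.31, 0.32, 0.33)
  cmp <- compare_kd_sets(a, b)
  oracle <- welch_oracle(a, b)
  expect_equal(cmp$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(cmp$df, oracle$df, tolerance = 1e-10)
  expect_equal(cmp$p_value, oracle$p_value, tolerance = 1e-10)
})
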