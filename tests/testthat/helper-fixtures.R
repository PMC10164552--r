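# Shared fixtures and independent oracles. Oracles here are deliberately
# literal (loops, bisection, hand-coded formulas) so they stay independent
# of the package's implementation paths.

# Build a peak list data frame quickly.
pl_df <- function(ids, h, n, status = "observed", name = NA_character_) {
  data.frame(residue_id = ids, residue_name = name, shift_h = h, shift_n = n,
             status = status, stringsAsFactors = FALSE)
}

# A small series where every residue sits still (no binding, no noise).
static_series <- function(n_res = 5, n_pts = 4, protein_conc = 0.1) {
  h <- seq(7, 9, length.out = n_res)
  n <- seq(110, 120, length.out = n_res)
  pls <- replicate(n_pts, pl_df(seq_len(n_res), h, n), simplify = FALSE)
  titration_series(pls, protein_conc = protein_conc,
                   ratios = seq(0, n_pts - 1), label = "static")
}

# Series with one binder moving linearly by the ligand-depletion bound
# fraction; other residues static. Zero noise.
forward_series <- function(kd, ddmax, protein_conc = 0.1,
                           ratios = c(0, 0.1, 0.25, 0.5, 1, 2, 4, 6),
                           angle = 0.7, n_extra = 5, weight_n = 0.154) {
  L <- ratios * protein_conc
  fb <- vapply(L, function(l) bisect_bound_fraction(protein_conc, l, kd), numeric(1))
  ids <- seq_len(n_extra + 1L)
  apo_h <- seq(7, 9.5, length.out = n_extra + 1L)
  apo_n <- seq(108, 126, length.out = n_extra + 1L)
  pls <- lapply(seq_along(ratios), function(p) {
    h <- apo_h; n <- apo_n
    h[1] <- apo_h[1] + fb[p] * ddmax * cos(angle)
    n[1] <- apo_n[1] + fb[p] * ddmax * sin(angle) / weight_n
    pl_df(ids, h, n)
  })
  titration_series(pls, protein_conc = protein_conc, ratios = ratios,
                   label = "forward", weight_n = weight_n)
}

# Oracle: bound fraction from mass action by bisection on the complex
# concentration x in [0, min(P, L)], solving (P - x)(L - x) = Kd * x.
bisect_bound_fraction <- function(P, L, kd) {
  if (L == 0) return(0)
  f <- function(x) (P - x) * (L - x) - kd * x
  lo <- 0
  hi <- min(P, L)
  if (f(hi) == 0) return(hi / P)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / P
}

# Oracle: literal sort/slice/mean/SD threshold rule (population SD).
brute_threshold <- function(csp, ids, trim_fraction = 0.10, k_sd = 2) {
  keep <- !is.na(csp)
  x <- csp[keep]; id <- ids[keep]
  ord <- order(x, id)
  x_sorted <- x[ord]
  n_trim <- ceiling(trim_fraction * length(x))
  kept <- x_sorted[seq_len(length(x) - n_trim)]
  m <- sum(kept) / length(kept)
  s <- sqrt(sum((kept - m)^2) / length(kept))
  thr <- m + k_sd * s
  list(threshold = thr, significant_ids = sort(id[x > thr]),
       n_used = length(kept))
}

# Oracle: hand-coded Welch two-sample t-test (two-sided).
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  list(statistic = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# Noisy single-residue titration CSPs: forward model plus Gaussian peak
# position noise at every point (including apo), reduced to CSPs.
noisy_csp <- function(kd, ddmax, protein_conc, ratios, noise_h, noise_n,
                      angle = 1.1, weight_n = 0.154) {
  L <- ratios * protein_conc
  fb <- predict_csp(protein_conc, L, kd, 1)
  h <- fb * ddmax * cos(angle) + rnorm(length(L), 0, noise_h)
  n <- fb * ddmax * sin(angle) / weight_n + rnorm(length(L), 0, noise_n)
  dh <- h - h[1]
  dn <- n - n[1]
  csp <- sqrt(dh^2 + (weight_n * dn)^2)
  csp[1] <- 0
  csp
}

# Fit a bare (ligand_conc, csp) curve by building a one-residue series.
fit_csp_curve <- function(csp, protein_conc, ratios, noise_floor = 0.002) {
  apo_h <- 8; apo_n <- 115
  pls <- lapply(seq_along(ratios), function(p) {
    pl_df(1L, apo_h + csp[p], apo_n)
  })
  ser <- titration_series(pls, protein_conc = protein_conc, ratios = ratios)
  traj <- track_residues(ser, max_step = Inf, merge_tol = 0)
  fit_residue(traj, ser, residue_id = 1L, noise_floor = noise_floor)
}
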