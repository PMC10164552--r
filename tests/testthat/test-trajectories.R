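test_that("compute_csp reduces to each axis alone and matches the frozen value", {
  expect_equal(compute_csp(0.10, 0), 0.10)
  expect_equal(compute_csp(0, 1.0), 0.154)
  expect_equal(compute_csp(0.03, 0.10), 0.03372180304, tolerance = 1e-9)
})

test_that("compute_csp is nonnegative, sign-symmetric, and rejects bad input", {
  set.seed(42)
  dh <- rnorm(50, 0, 0.1)
  dn <- rnorm(50, 0, 1)
  v <- compute_csp(dh, dn)
  expect_true(all(v >= 0))
  expect_equal(compute_csp(-dh, -dn), v)
  expect_equal(compute_csp(-dh, dn), v)  # each axis enters squared
  expect_error(compute_csp(NA_real_, 0), "finite")
  expect_error(compute_csp(0.1, 0.1, weight_n = 0), "positive")
})

test_that("stationary peaks give zero CSP and all-observed trajectories", {
  ser <- static_series()
  traj <- track_residues(ser)
  expect_true(all(traj$status == "observed"))
  expect_true(all(traj$csp == 0))
})

test_that("a residue that disappears is broadened from that point onward", {
  pls <- lapply(0:5, function(p) {
    ids <- if (p >= 5) 2:4 else 1:4
    pl_df(ids, c(7, 8, 9, 9.5)[ids], c(110, 114, 118, 122)[ids])
  })
  ser <- titration_series(pls, 0.1, ratios = 0:5)
  traj <- track_residues(ser)
  r1 <- traj[traj$residue_id == 1, ]
  expect_equal(r1$status[r1$point < 5], rep("observed", 5))
  expect_equal(r1$status[r1$point == 5], "broadened")
  expect_true(is.na(r1$csp[r1$point == 5]))
})

test_that("peaks closer than merge_tol mark both trajectories overlapped, stickily", {
  # residues 1 and 2 collide at point 3: weighted distance 0.005 < 0.01
  h <- list(c(8.00, 8.50), c(8.00, 8.40), c(8.00, 8.20), c(8.000, 8.005),
            c(8.00, 8.005))
  pls <- lapply(seq_along(h), function(p) pl_df(1:2, h[[p]], c(115, 115)))
  ser <- titration_series(pls, 0.1, ratios = 0:4)
  d3 <- sqrt((h[[4]][1] - h[[4]][2])^2 + (0.154 * 0)^2)  # brute-force distance
  expect_lt(d3, 0.01)
  traj <- track_residues(ser, merge_tol = 0.01)
  for (rid in 1:2) {
    st <- traj$status[traj$residue_id == rid]
    expect_equal(st, c("observed", "observed", "observed", "overlapped", "overlapped"))
  }
})

test_that("residues with no apo assignment are unassigned_apo throughout", {
  pls <- list(pl_df(1:2, c(7, 8), c(110, 115)),
              pl_df(1:3, c(7, 8, 9), c(110, 115, 120)),
              pl_df(1:3, c(7, 8, 9), c(110, 115, 120)),
              pl_df(1:3, c(7, 8, 9), c(110, 115, 120)))
  ser <- titration_series(pls, 0.1, ratios = 0:3)
  traj <- track_residues(ser)
  expect_true(all(traj$status[traj$residue_id == 3] == "unassigned_apo"))
  expect_true(all(is.na(traj$csp[traj$residue_id == 3])))
})

test_that("nearest-neighbour tracking recovers the keyed assignment on clean data", {
  ser <- forward_series(kd = 0.12, ddmax = 0.2)
  keyed <- track_residues(ser)
  # strip assignments from every non-apo point
  pls <- lapply(seq_along(ser$points), function(i) {
    pk <- ser$points[[i]]$peaks
    df <- as.data.frame(pk)
    if (i > 1) df$residue_id <- NA_integer_
    df
  })
  ser2 <- titration_series(pls, ser$protein_conc,
                           vapply(ser$points, `[[`, numeric(1), "molar_ratio"))
  nn <- track_residues(ser2, max_step = 0.05)
  expect_equal(nn$csp, keyed$csp, tolerance = 1e-12)
  expect_equal(nn$status, keyed$status)
})

test_that("zero-noise CSPs are nondecreasing in ligand concentration", {
  ser <- forward_series(kd = 0.3, ddmax = 0.25)
  traj <- track_residues(ser)
  csp1 <- traj$csp[traj$residue_id == 1]
  expect_true(all(diff(csp1) >= -1e-12))
})

test_that("csp_profile matches recomputing the CSP from endpoint displacement", {
  sim <- simulate_titration(simulation_config(n_residues = 25, seed = 3,
                                              broaden_prob = 0))
  traj <- track_residues(sim$series)
  prof <- csp_profile(traj)
  last <- length(sim$series$points) - 1L
  apo <- sim$series$points[[1]]$peaks
  ref <- sim$series$points[[last + 1]]$peaks
  for (i in seq_len(nrow(prof))) {
    rid <- prof$residue_id[i]
    if (is.na(prof$csp[i])) next
    dh <- ref$shift_h[ref$residue_id == rid] - apo$shift_h[apo$residue_id == rid]
    dn <- ref$shift_n[ref$residue_id == rid] - apo$shift_n[apo$residue_id == rid]
    expect_equal(prof$csp[i], compute_csp(dh, dn), tolerance = 1e-12)
  }
})

test_that("broadened residues are excluded from profile values but keep their flag", {
  sim <- simulate_titration(simulation_config(n_residues = 40, binder_fraction = 0.5,
                                              broaden_prob = 0.5, seed = 9))
  traj <- track_residues(sim$series)
  prof <- csp_profile(traj)
  br <- prof$status == "broadened"
  expect_gt(sum(br), 0)  # the fixture is built to broaden some binders
  expect_true(all(is.na(prof$csp[br])))
})

test_that("out-of-range reference points are rejected", {
  ser <- static_series(n_pts = 4)
  traj <- track_residues(ser)
  expect_error(csp_profile(traj, 0), "reference_point")
  expect_error(csp_profile(traj, 4), "reference_point")
  expect_silent(csp_profile(traj, 3))
})
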