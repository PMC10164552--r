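# Seeded two-state fast-exchange titration simulator.
#
# Observed peak positions are population-weighted averages of the free and
# bound shifts, with the bound fraction given by the single-site
# ligand-depletion quadratic; trajectories are therefore strictly linear in
# the (1H, 15N) plane. Gaussian position noise, a configurable binder
# fraction, and broadening dropout emulate the failure modes of real
# titrations. Every quantity is reproducible from the master seed, and each
# residue consumes its own derived random stream, so enlarging the residue
# set does not perturb existing residues.

.run_with_own_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  force(expr)
}

# Derived per-residue seed; stays well below 2^31.
.residue_seed <- function(seed, i) {
  (abs(as.integer(seed)) %% 1000003L) * 2039L + as.integer(i)
}

#' Simulation configuration
#'
#' Defaults describe a typical protein-observed HSQC titration of a
#' ~100-residue domain at 0.1 mM with the eight-point ratio schedule
#' 0, 0.1, 0.25, 0.5, 1, 2, 4, 6 and a tight (0.025 mM) binding site
#' reported by a minority of residues.
#'
#' @param n_residues Number of assigned residues.
#' @param binder_fraction Fraction of residues reporting binding, in `[0, 1]`.
#'   Binder assignment is deterministic and stratified across the sequence,
#'   so `ceiling(binder_fraction * n_residues)` residues are binders exactly.
#' @param true_kd Ground-truth dissociation constant, mM.
#' @param ddmax_range Log-uniform range of per-residue saturation CSPs, ppm.
#' @param protein_conc \[P\], mM.
#' @param ratios Molar-ratio schedule, starting at 0.
#' @param noise_h,noise_n Gaussian SDs of per-point 1H and 15N peak position
#'   noise, ppm.
#' @param broaden_prob Per-point probability that a binder with bound
#'   fraction > 0.5 broadens beyond detection (sticky once it happens).
#' @param weight_n Nitrogen weight of the CSP metric.
#' @param seed Master integer seed.
#' @param label Series label.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_residues = 100L,
                              binder_fraction = 0.15,
                              true_kd = 0.025,
                              ddmax_range = c(0.05, 0.3),
                              protein_conc = 0.1,
                              ratios = c(0, 0.1, 0.25, 0.5, 1, 2, 4, 6),
                              noise_h = 0.005,
                              noise_n = 0.02,
                              broaden_prob = 0.02,
                              weight_n = 0.154,
                              seed = 1L,
                              label = "simulated") {
  cfg <- list(n_residues = as.integer(n_residues),
              binder_fraction = binder_fraction, true_kd = true_kd,
              ddmax_range = as.numeric(ddmax_range), protein_conc = protein_conc,
              ratios = as.numeric(ratios), noise_h = noise_h, noise_n = noise_n,
              broaden_prob = broaden_prob, weight_n = weight_n,
              seed = as.integer(seed), label = label)
  with(cfg, {
    if (is.na(n_residues) || n_residues < 1L) stop("n_residues must be >= 1", call. = FALSE)
    if (binder_fraction < 0 || binder_fraction > 1) {
      stop("binder_fraction must be in [0, 1]", call. = FALSE)
    }
    if (true_kd < 0) stop("true_kd must be >= 0", call. = FALSE)
    if (length(ddmax_range) != 2L || any(ddmax_range <= 0) ||
        ddmax_range[2] < ddmax_range[1]) {
      stop("ddmax_range must be an increasing pair of positive ppm values", call. = FALSE)
    }
    if (protein_conc <= 0) stop("protein_conc must be > 0", call. = FALSE)
    if (length(ratios) < 2L || ratios[1] != 0 || is.unsorted(ratios) || any(ratios < 0)) {
      stop("ratios must start at 0 and be nondecreasing", call. = FALSE)
    }
    if (noise_h < 0 || noise_n < 0) stop("noise SDs must be >= 0", call. = FALSE)
    if (broaden_prob < 0 || broaden_prob > 1) {
      stop("broaden_prob must be in [0, 1]", call. = FALSE)
    }
    if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  })
  structure(cfg, class = "simulation_config")
}

# Deterministic stratified binder assignment: residue i is a binder iff the
# running count ceiling(i*f) increments at i. Gives exactly ceiling(n*f)
# binders and is independent of n for each fixed i.
.binder_mask <- function(n, f) {
  i <- seq_len(n)
  ceiling(i * f) > ceiling((i - 1) * f)
}

#' Simulate a fast-exchange titration series
#'
#' Binder residues move linearly from their apo position toward a bound
#' position `ddmax` away (in the weighted CSP metric) along a per-residue
#' random direction, travelling the bound fraction given by the
#' ligand-depletion model at each point; non-binders are stationary. All
#' positions receive independent Gaussian noise (including at the apo
#' point). Binders past half saturation may broaden beyond detection and
#' then stay invisible at later points.
#'
#' @param config A [simulation_config()].
#' @return A `titration_simulation` list: `series` (a [titration_series()]),
#'   `truth` (data frame: `residue_id`, `binder`, `kd`, `ddmax`, `angle`,
#'   `apo_h`, `apo_n`, `broadened_from` -- NA when never broadened) and
#'   `config`.
#' @export
simulate_titration <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  .run_with_own_rng({
    n <- config$n_residues
    npts <- length(config$ratios)
    L <- config$ratios * config$protein_conc
    P <- config$protein_conc
    w <- config$weight_n
    binder <- .binder_mask(n, config$binder_fraction)
    fb <- predict_csp(P, L, config$true_kd, ddmax = 1)

    apo_h <- apo_n <- angle <- ddmax <- numeric(n)
    broadened_from <- rep(NA_integer_, n)
    pos_h <- pos_n <- matrix(NA_real_, n, npts)
    lo <- log(config$ddmax_range[1]); hi <- log(config$ddmax_range[2])

    for (i in seq_len(n)) {
      set.seed(.residue_seed(config$seed, i))
      apo_h[i] <- stats::runif(1, 6.5, 10)
      apo_n[i] <- stats::runif(1, 105, 130)
      angle[i] <- stats::runif(1, 0, 2 * pi)
      ddmax[i] <- exp(stats::runif(1, lo, hi))
      nh <- stats::rnorm(npts) * config$noise_h
      nn <- stats::rnorm(npts) * config$noise_n
      bu <- stats::runif(npts)
      move <- if (binder[i]) fb * ddmax[i] else rep(0, npts)
      pos_h[i, ] <- apo_h[i] + move * cos(angle[i]) + nh
      pos_n[i, ] <- apo_n[i] + move * sin(angle[i]) / w + nn
      if (binder[i] && config$broaden_prob > 0) {
        gone <- which(fb > 0.5 & bu < config$broaden_prob & seq_len(npts) > 1L)
        if (length(gone)) broadened_from[i] <- gone[1L] - 1L  # 0-based point index
      }
    }
    ddmax[!binder] <- NA_real_

    peaklists <- lapply(seq_len(npts), function(p) {
      present <- is.na(broadened_from) | (p - 1L) < broadened_from
      peak_list(data.frame(
        residue_id = seq_len(n)[present],
        shift_h = pos_h[present, p],
        shift_n = pos_n[present, p],
        status = "observed",
        stringsAsFactors = FALSE
      ), point_index = p - 1L)
    })
    series <- titration_series(peaklists, protein_conc = P,
                               ratios = config$ratios, label = config$label,
                               weight_n = w)
    truth <- data.frame(
      residue_id = seq_len(n),
      binder = binder,
      kd = ifelse(binder, config$true_kd, NA_real_),
      ddmax = ddmax,
      angle = angle,
      apo_h = apo_h,
      apo_n = apo_n,
      broadened_from = broadened_from,
      stringsAsFactors = FALSE
    )
    structure(list(series = series, truth = truth, config = config),
              class = "titration_simulation")
  })
}

#' @export
print.titration_simulation <- function(x, ...) {
  cat(sprintf("<titration_simulation> %s: %d residues (%d binders), true Kd = %g mM, seed %d\n",
              x$config$label, nrow(x$truth), sum(x$truth$binder),
              x$config$true_kd, x$config$seed))
  print(x$series)
  invisible(x)
}

#' Scenario descriptor for paired simulations
#'
#' @param name `"wildtype"` (no change), `"mutant"` (Kd multiplied by
#'   `kd_scale`; binding-deficient mutants typically show ~8-fold weaker
#'   affinity) or `"ternary"` (Kd multiplied by `ternary_kd_factor` < 1,
#'   modelling enhancement by a pre-bound second ligand).
#' @param kd_scale Mutant Kd multiplier (> 0, default 8).
#' @param ternary_kd_factor Ternary Kd multiplier (> 0, default 0.78, the
#'   magnitude of enhancement seen when a second ligand is pre-bound).
#' @return A `titration_scenario` list.
#' @export
scenario <- function(name = c("wildtype", "mutant", "ternary"),
                     kd_scale = 8, ternary_kd_factor = 0.78) {
  name <- match.arg(name)
  if (kd_scale <= 0 || ternary_kd_factor <= 0) {
    stop("scenario scale factors must be > 0", call. = FALSE)
  }
  structure(list(name = name, kd_scale = kd_scale,
                 ternary_kd_factor = ternary_kd_factor),
            class = "titration_scenario")
}

#' Simulate a reference/condition pair of titrations
#'
#' The reference uses the config's `true_kd`; the condition uses the scenario
#' scaled Kd. Residues, trajectory directions, saturation CSPs and noise
#' streams are shared between the pair (same master seed), isolating the Kd
#' change.
#'
#' @param config A [simulation_config()].
#' @param scen A [scenario()].
#' @return A list with `reference` and `condition` (both
#'   `titration_simulation`) and `scenario`.
#' @export
simulate_scenario <- function(config, scen) {
  if (!inherits(config, "simulation_config")) {
    stop("config must be a simulation_config", call. = FALSE)
  }
  if (!inherits(scen, "titration_scenario")) {
    stop("scen must be created with scenario()", call. = FALSE)
  }
  factor <- switch(scen$name,
                   wildtype = 1,
                   mutant = scen$kd_scale,
                   ternary = scen$ternary_kd_factor)
  ref_cfg <- config
  ref_cfg$label <- paste0(config$label, "_reference")
  cond_cfg <- config
  cond_cfg$true_kd <- config$true_kd * factor
  cond_cfg$label <- paste0(config$label, "_", scen$name)
  reference <- simulate_titration(ref_cfg)
  condition <- simulate_titration(cond_cfg)
  if (scen$name == "ternary") {
    condition$series$precondition_ligand <- "pre-bound ligand"
  }
  list(reference = reference, condition = condition, scenario = scen)
}

#' Write a simulation (series + ground truth) to a directory
#'
#' Emits the CSV peak lists and YAML config of [write_series_config()] plus
#' a `ground_truth.tsv` with the per-residue truth record.
#'
#' @param sim A [simulate_titration()] result.
#' @param dir Output directory.
#' @return The config path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "titration_simulation"))
  path <- write_series_config(sim$series, dir)
  truth <- sim$truth
  for (col in c("kd", "ddmax", "angle", "apo_h", "apo_n")) {
    truth[[col]] <- .fmt_num(truth[[col]])
  }
  utils::write.table(truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
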