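# Single-site ligand-depletion isotherm: prediction, per-residue fitting,
# Kd aggregation, upper-limit reporting, and condition comparison.

#' Predicted CSP under the single-site ligand-depletion model
#'
#' At total protein concentration \[P\] and total ligand concentration \[L\],
#' the bound fraction of a single site with dissociation constant Kd is the
#' physical root of the mass-action quadratic, and the observed fast-exchange
#' CSP is that fraction times the saturation CSP:
#' \deqn{\Delta\delta = \Delta\delta_{max}\,
#'   \frac{([L]+[P]+K_d) - \sqrt{([L]+[P]+K_d)^2 - 4[P][L]}}{2[P]}}
#' Evaluated in the numerically stable conjugate form
#' \eqn{2[L] / (s + \sqrt{s^2 - 4[P][L]})} with \eqn{s = [L]+[P]+K_d}, which
#' avoids cancellation for weak binding.
#'
#' @param protein_conc \[P\], mM (> 0).
#' @param ligand_conc \[L\], mM (>= 0); vectorized.
#' @param kd Dissociation constant, mM (>= 0).
#' @param ddmax Saturation CSP, ppm (> 0); default 1 returns the bound
#'   fraction itself.
#' @return CSP value(s) in `[0, ddmax]`.
#' @export
predict_csp <- function(protein_conc, ligand_conc, kd, ddmax = 1) {
  if (!is.numeric(protein_conc) || length(protein_conc) != 1L ||
      !is.finite(protein_conc) || protein_conc <= 0) {
    stop("protein_conc must be a single positive number (mM)", call. = FALSE)
  }
  if (!is.numeric(ligand_conc) || any(!is.finite(ligand_conc)) || any(ligand_conc < 0)) {
    stop("ligand_conc must be non-negative and finite (mM)", call. = FALSE)
  }
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd < 0) {
    stop("kd must be a single non-negative number (mM)", call. = FALSE)
  }
  if (!is.numeric(ddmax) || length(ddmax) != 1L || !is.finite(ddmax) || ddmax <= 0) {
    stop("ddmax must be a single positive number (ppm)", call. = FALSE)
  }
  s <- ligand_conc + protein_conc + kd
  disc <- s^2 - 4 * protein_conc * ligand_conc
  disc[disc < 0] <- 0  # guard against rounding at the stoichiometric corner
  fb <- 2 * ligand_conc / (s + sqrt(disc))
  ddmax * fb
}

# Linear interpolation of the ligand concentration at half-maximal CSP,
# used as the Kd starting value; falls back to [P].
.half_saturation_guess <- function(ligand_conc, csp, protein_conc) {
  o <- order(ligand_conc)
  L <- ligand_conc[o]
  y <- csp[o]
  half <- max(y) / 2
  j <- which(y >= half)[1L]
  if (is.na(j) || j <= 1L) return(protein_conc)
  L0 <- L[j - 1L]; L1 <- L[j]; y0 <- y[j - 1L]; y1 <- y[j]
  if (!is.finite(y1 - y0) || y1 == y0) return(protein_conc)
  guess <- L0 + (half - y0) / (y1 - y0) * (L1 - L0)
  if (!is.finite(guess) || guess <= 0) protein_conc else guess
}

.fit_nls <- function(L, y, protein_conc, kd0, ddmax0) {
  df <- data.frame(L = L, y = y)
  P <- protein_conc
  tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ predict_csp(P, L, kd, ddmax),
      data = df,
      start = list(kd = kd0, ddmax = ddmax0),
      lower = c(kd = 0, ddmax = 1e-9),
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, maxfev = 10000, ptol = 1e-12, ftol = 1e-14)
    )
    est <- stats::coef(fit)
    list(kd = unname(est["kd"]), ddmax = unname(est["ddmax"]),
         rss = sum(stats::resid(fit)^2), converged = isTRUE(fit$convInfo$isConv))
  }, error = function(e) NULL)
}

#' Fit the ligand-depletion isotherm to one residue
#'
#' Nonlinear least squares of [predict_csp()] against the residue's CSP at
#' each titration point where it is observed. Initial values are 1.2x the
#' largest observed CSP for the saturation CSP and the interpolated
#' half-saturation ligand concentration for Kd; if that start fails to
#' converge, restarts at Kd in \{0.1, 1, 10\} x \[P\] are tried and the best
#' (lowest residual sum of squares) solution kept. Kd is bounded below by 0;
#' fits that settle on the bound are reported converged with Kd = 0 and are
#' handled downstream by the upper-limit rule.
#'
#' Residues whose largest CSP stays below `3 * noise_floor` are flagged
#' non-binders and not fit.
#'
#' @param trajectory Rows of a [track_residues()] result for one residue, or
#'   the full trajectories object together with `residue_id`.
#' @param series The [titration_series()] the trajectories came from.
#' @param residue_id Residue to fit when `trajectory` contains several.
#' @param noise_floor CSP noise floor, ppm (default 0.002).
#' @return A `residue_fit` list: `residue_id`, `kd` (mM), `ddmax` (ppm),
#'   `rss`, `converged`, `n_points`, `nonbinder`.
#' @export
fit_residue <- function(trajectory, series, residue_id = NULL, noise_floor = 0.002) {
  stopifnot(inherits(series, "titration_series"))
  if (!is.null(residue_id)) {
    trajectory <- trajectory[trajectory$residue_id == residue_id, , drop = FALSE]
  }
  rid <- unique(trajectory$residue_id)
  if (length(rid) != 1L) {
    stop("trajectory must contain exactly one residue (use residue_id=)", call. = FALSE)
  }
  Lall <- series_ligand_conc(series)
  use <- trajectory$status == "observed" & !is.na(trajectory$csp)
  L <- Lall[trajectory$point[use] + 1L]
  y <- trajectory$csp[use]
  if (length(y) < 4L) {
    stop("residue ", rid, ": at least 4 observed points are required for fitting",
         call. = FALSE)
  }
  if (max(y) < 3 * noise_floor || sum(y > 0) < 2L) {
    return(structure(list(residue_id = rid, kd = NA_real_, ddmax = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          n_points = length(y), nonbinder = TRUE),
                     class = "residue_fit"))
  }
  P <- series$protein_conc
  ddmax0 <- 1.2 * max(y)
  kd0 <- .half_saturation_guess(L, y, P)
  best <- .fit_nls(L, y, P, kd0, ddmax0)
  if (is.null(best) || !best$converged) {
    for (k0 in c(0.1, 1, 10) * P) {
      cand <- .fit_nls(L, y, P, k0, ddmax0)
      if (!is.null(cand) && cand$converged &&
          (is.null(best) || !best$converged || cand$rss < best$rss)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(structure(list(residue_id = rid, kd = NA_real_, ddmax = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          n_points = length(y), nonbinder = FALSE),
                     class = "residue_fit"))
  }
  structure(list(residue_id = rid, kd = best$kd, ddmax = best$ddmax,
                 rss = best$rss, converged = best$converged,
                 n_points = length(y), nonbinder = FALSE),
            class = "residue_fit")
}

#' @export
print.residue_fit <- function(x, ...) {
  if (x$nonbinder) {
    cat(sprintf("<residue_fit> residue %d: non-binder (all CSP at noise floor)\n",
                x$residue_id))
  } else {
    cat(sprintf("<residue_fit> residue %d: Kd = %.4g mM, ddmax = %.4g ppm (rss %.3g, %s, %d points)\n",
                x$residue_id, x$kd, x$ddmax, x$rss,
                if (x$converged) "converged" else "NOT converged", x$n_points))
  }
  invisible(x)
}

#' Fit the isotherm to a set of residues
#'
#' Convenience wrapper around [fit_residue()]. Residues with fewer than 4
#' observed points are skipped silently when `residue_ids` is `NULL`
#' (automatic selection); asking for such a residue explicitly raises the
#' per-residue error.
#'
#' @inheritParams fit_residue
#' @param trajectories A [track_residues()] result.
#' @param residue_ids Residues to fit; default: all with >= 4 observed points.
#' @return A data frame with one row per fit attempt: `residue_id`, `kd`,
#'   `ddmax`, `rss`, `converged`, `n_points`, `nonbinder`.
#' @export
fit_binding <- function(trajectories, series, residue_ids = NULL, noise_floor = 0.002) {
  stopifnot(inherits(trajectories, "residue_trajectories"))
  auto <- is.null(residue_ids)
  if (auto) {
    tab <- table(trajectories$residue_id[trajectories$status == "observed" &
                                           !is.na(trajectories$csp)])
    residue_ids <- as.integer(names(tab)[tab >= 4L])
  }
  rows <- lapply(residue_ids, function(rid) {
    f <- tryCatch(fit_residue(trajectories, series, residue_id = rid,
                              noise_floor = noise_floor),
                  error = function(e) if (auto) NULL else stop(e))
    if (is.null(f)) return(NULL)
    data.frame(residue_id = f$residue_id, kd = f$kd, ddmax = f$ddmax,
               rss = f$rss, converged = f$converged, n_points = f$n_points,
               nonbinder = f$nonbinder, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(residue_id = integer(0), kd = numeric(0), ddmax = numeric(0),
                      rss = numeric(0), converged = logical(0),
                      n_points = integer(0), nonbinder = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# "0.025" style formatting for mM values in display strings.
.fmt_kd <- function(x) formatC(signif(x, 2), format = "fg", width = 1)

#' Aggregate per-residue dissociation constants
#'
#' The reported Kd of a titration is the mean (with across-residue sample SD)
#' of the individual Kd values of residues that are both significantly
#' perturbed and successfully fit. Non-converged or non-binder fits among the
#' significant residues are listed in `excluded_ids`, not averaged.
#'
#' @param fits Fit table from [fit_binding()] (or a list of `residue_fit`s).
#' @param significant_ids Residues called significant (see
#'   [significance_threshold()]).
#' @param protein_conc \[P\] in mM, kept for the upper-limit rule.
#' @return An `aggregate_kd` list: `mean_kd`, `sd_kd` (NA when a single
#'   contributor), `n_residues`, `kd_values`, `residue_ids`, `excluded_ids`,
#'   `upper_limit` (NULL until [apply_upper_limit()]), `protein_conc`,
#'   `display` (e.g. `"0.025 ± 0.005 mM"`).
#' @export
aggregate_kd <- function(fits, significant_ids, protein_conc) {
  if (inherits(fits, "residue_fit")) fits <- list(fits)
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(residue_id = f$residue_id, kd = f$kd, ddmax = f$ddmax,
                 rss = f$rss, converged = f$converged, n_points = f$n_points,
                 nonbinder = f$nonbinder)))
  }
  if (!is.numeric(protein_conc) || protein_conc <= 0) {
    stop("protein_conc must be positive (mM)", call. = FALSE)
  }
  sig <- fits[fits$residue_id %in% significant_ids, , drop = FALSE]
  use <- sig$converged & !sig$nonbinder & is.finite(sig$kd)
  contrib <- sig[use, , drop = FALSE]
  if (nrow(contrib) == 0) {
    stop("no significant residue has a converged binding fit; nothing to aggregate",
         call. = FALSE)
  }
  m <- mean(contrib$kd)
  s <- if (nrow(contrib) >= 2L) stats::sd(contrib$kd) else NA_real_
  display <- if (is.na(s)) sprintf("%s mM", .fmt_kd(m)) else
    sprintf("%s ± %s mM", .fmt_kd(m), .fmt_kd(s))
  structure(
    list(mean_kd = m, sd_kd = s, n_residues = nrow(contrib),
         kd_values = contrib$kd, residue_ids = contrib$residue_id,
         excluded_ids = sig$residue_id[!use],
         upper_limit = NULL, protein_conc = protein_conc, display = display),
    class = "aggregate_kd"
  )
}

#' Upper-limit reporting for tight binders
#'
#' A fitted Kd below one tenth of the protein concentration is outside the
#' quantifiable range of a protein-observed titration, so the aggregate is
#' reported as an upper bound: if `mean_kd < protein_conc / 10` (strict), the
#' display becomes `"< [P]/10 mM"` and `upper_limit` is set; otherwise the
#' aggregate is returned unchanged.
#'
#' @param agg An [aggregate_kd()] result.
#' @param protein_conc \[P\] in mM; defaults to the one stored in `agg`.
#' @return The (possibly updated) `aggregate_kd`.
#' @export
apply_upper_limit <- function(agg, protein_conc = agg$protein_conc) {
  stopifnot(inherits(agg, "aggregate_kd"))
  if (!is.numeric(protein_conc) || protein_conc <= 0) {
    stop("protein_conc must be positive (mM)", call. = FALSE)
  }
  limit <- protein_conc / 10
  if (agg$mean_kd < limit) {
    agg$upper_limit <- limit
    agg$display <- sprintf("< %s mM", .fmt_kd(limit))
  }
  agg
}

#' @export
print.aggregate_kd <- function(x, ...) {
  cat(sprintf("<aggregate_kd> Kd = %s (n = %d residue(s))\n", x$display, x$n_residues))
  if (length(x$excluded_ids)) {
    cat("  significant but not averaged (no converged fit):",
        paste(x$excluded_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two per-residue Kd sets
#'
#' Fold-change (mean of set A over mean of set B) plus a two-sided Welch
#' two-sample t-test on the per-residue Kd values. The Welch test is a
#' pragmatic choice for across-residue Kd scatter and is labelled as such in
#' the output.
#'
#' @param kd_a,kd_b Numeric vectors of per-residue Kd values (mM), nonempty;
#'   the p-value needs at least 2 values per set.
#' @return A `kd_comparison` list: `fold_change`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`, `statistic`, `df`, `p_value` (NA when either set has a single
#'   value), `test` = `"welch_t"`.
#' @export
compare_kd_sets <- function(kd_a, kd_b) {
  kd_a <- as.numeric(kd_a); kd_b <- as.numeric(kd_b)
  if (length(kd_a) == 0 || length(kd_b) == 0 || anyNA(kd_a) || anyNA(kd_b)) {
    stop("both Kd sets must be nonempty and free of NAs", call. = FALSE)
  }
  ma <- mean(kd_a); mb <- mean(kd_b)
  stat <- df <- p <- NA_real_
  if (length(kd_a) >= 2L && length(kd_b) >= 2L) {
    va <- stats::var(kd_a); vb <- stats::var(kd_b)
    if (va == 0 && vb == 0) {
      # degenerate: identical-variance-free sets; equal means are indistinguishable
      stat <- if (ma == mb) 0 else Inf
      p <- if (ma == mb) 1 else 0
    } else {
      tt <- stats::t.test(kd_a, kd_b, var.equal = FALSE)
      stat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
  }
  structure(
    list(fold_change = ma / mb, mean_a = ma, mean_b = mb,
         n_a = length(kd_a), n_b = length(kd_b),
         statistic = stat, df = df, p_value = p, test = "welch_t"),
    class = "kd_comparison"
  )
}

#' @export
print.kd_comparison <- function(x, ...) {
  cat(sprintf("<kd_comparison> fold-change (A/B) = %.3g  [mean A %.4g, mean B %.4g mM]\n",
              x$fold_change, x$mean_a, x$mean_b))
  if (!is.na(x$p_value)) {
    cat(sprintf("  Welch t = %.3g, df = %.3g, two-sided p = %.3g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}
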