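# Full analysis pipeline and condition comparison.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the CSP analysis pipeline on one titration series
#'
#' Executes track -> CSP profile -> significance -> per-residue fit ->
#' aggregate -> upper limit, optionally writing the per-residue table, a
#' one-row summary and a structure-attribute file. Only significant residues
#' are fit (they are the ones that enter the reported Kd). Errors carry the
#' name of the failing stage. The run is deterministic for fixed inputs.
#'
#' @param series A [titration_series()], a [simulate_titration()] result, or
#'   a path to a YAML series config.
#' @param reference_point 0-based point index for the CSP profile; default:
#'   the last point.
#' @param trim_fraction,k_sd Significance rule parameters (defaults 0.10, 2).
#' @param max_step,merge_tol Tracking thresholds in weighted ppm (defaults
#'   0.05, 0.01).
#' @param noise_floor CSP noise floor for the non-binder flag, ppm.
#' @param out_dir Optional output directory; when given, writes
#'   `residue_table.tsv`, `summary.tsv` and `attributes.txt`.
#' @param verbose Log stage summaries to stderr (default TRUE).
#' @return A `csp_pipeline` bundle: `label`, `series`, `trajectories`,
#'   `profile` (classified), `significance`, `fits`, `aggregate`, `params`,
#'   `files`.
#' @export
run_pipeline <- function(series,
                         reference_point = NULL,
                         trim_fraction = 0.10,
                         k_sd = 2,
                         max_step = 0.05,
                         merge_tol = 0.01,
                         noise_floor = 0.002,
                         out_dir = NULL,
                         verbose = TRUE) {
  if (inherits(series, "titration_simulation")) series <- series$series
  if (is.character(series)) series <- .stage("read", read_series_config(series))
  stopifnot(inherits(series, "titration_series"))
  say <- function(...) if (verbose) message(sprintf(...))

  traj <- .stage("track", track_residues(series, max_step = max_step,
                                         merge_tol = merge_tol))
  say("track: %d residues over %d points (%s)",
      length(unique(traj$residue_id)), attr(traj, "n_points"), series$label)

  profile <- .stage("csp_profile", csp_profile(traj, reference_point))
  say("csp_profile: reference point %d, %d residues with defined CSP",
      attr(profile, "reference_point"), sum(!is.na(profile$csp)))

  sig <- .stage("significance",
                significance_threshold(profile, trim_fraction = trim_fraction,
                                       k_sd = k_sd))
  profile <- .stage("significance", classify(profile, sig))
  say("significance: threshold %.4f ppm, %d significant residue(s)",
      sig$threshold, length(sig$significant_ids))

  fits <- .stage("fit", fit_binding(traj, series,
                                    residue_ids = sig$significant_ids,
                                    noise_floor = noise_floor))
  agg <- .stage("aggregate",
                aggregate_kd(fits, sig$significant_ids, series$protein_conc))
  agg <- .stage("upper_limit", apply_upper_limit(agg))
  say("aggregate: Kd = %s from residues %s", agg$display,
      paste(agg$residue_ids, collapse = ", "))

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    f_res <- file.path(out_dir, "residue_table.tsv")
    f_sum <- file.path(out_dir, "summary.tsv")
    f_att <- file.path(out_dir, "attributes.txt")
    .stage("write", write_residue_table(profile, fits, f_res, trajectories = traj))
    .stage("write", .write_summary(series, profile, sig, agg, f_sum))
    .stage("write", export_structure_attributes(profile, f_att))
    files <- c(residue_table = f_res, summary = f_sum, attributes = f_att)
  }

  structure(
    list(label = series$label, series = series, trajectories = traj,
         profile = profile, significance = sig, fits = fits, aggregate = agg,
         params = list(reference_point = attr(profile, "reference_point"),
                       trim_fraction = trim_fraction, k_sd = k_sd,
                       weight_n = series$weight_n, max_step = max_step,
                       merge_tol = merge_tol, noise_floor = noise_floor),
         files = files),
    class = "csp_pipeline"
  )
}

.write_summary <- function(series, profile, sig, agg, path) {
  row <- data.frame(
    label = series$label,
    protein_conc_mM = .fmt_num(series$protein_conc),
    reference_point = attr(profile, "reference_point"),
    n_residues = nrow(profile),
    n_defined = sum(!is.na(profile$csp)),
    threshold_ppm = .fmt_num(sig$threshold),
    n_significant = length(sig$significant_ids),
    n_contributors = agg$n_residues,
    mean_kd_mM = .fmt_num(agg$mean_kd),
    sd_kd_mM = .fmt_num(agg$sd_kd),
    upper_limit_mM = .fmt_num(if (is.null(agg$upper_limit)) NA_real_ else agg$upper_limit),
    kd_display = agg$display,
    stringsAsFactors = FALSE
  )
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.csp_pipeline <- function(x, ...) {
  cat(sprintf("<csp_pipeline> %s\n", x$label))
  cat(sprintf("  threshold %.4f ppm; significant: %s\n",
              x$significance$threshold,
              paste(x$significance$significant_ids, collapse = ", ")))
  cat(sprintf("  Kd = %s (n = %d)\n", x$aggregate$display, x$aggregate$n_residues))
  invisible(x)
}

#' Compare two pipeline runs
#'
#' Fold-change of the aggregate Kd (A over B) with a Welch test on the
#' per-residue Kd sets. If either aggregate was upper-limited, the
#' fold-change is reported as a bound rather than a point value, since one
#' of the means is itself only a bound.
#'
#' @param bundle_a,bundle_b [run_pipeline()] bundles.
#' @param path Optional TSV path for a side-by-side summary.
#' @return A `run_comparison` list: `comparison` (a [compare_kd_sets()]
#'   result), `fold_display`, `label_a`, `label_b`, `display_a`, `display_b`.
#' @export
compare_runs <- function(bundle_a, bundle_b, path = NULL) {
  stopifnot(inherits(bundle_a, "csp_pipeline"), inherits(bundle_b, "csp_pipeline"))
  a <- bundle_a$aggregate; b <- bundle_b$aggregate
  if (is.null(a) || is.null(b)) stop("both bundles need aggregate Kd values", call. = FALSE)
  cmp <- compare_kd_sets(a$kd_values, b$kd_values)
  lim_a <- !is.null(a$upper_limit); lim_b <- !is.null(b$upper_limit)
  fold_display <- if (lim_a && lim_b) {
    "n/a (both Kd values are upper limits)"
  } else if (lim_a) {
    sprintf("< %s", .fmt_kd(a$upper_limit / b$mean_kd))
  } else if (lim_b) {
    sprintf("> %s", .fmt_kd(a$mean_kd / b$upper_limit))
  } else {
    .fmt_kd(cmp$fold_change)
  }
  out <- structure(
    list(comparison = cmp, fold_display = fold_display,
         label_a = bundle_a$label, label_b = bundle_b$label,
         display_a = a$display, display_b = b$display),
    class = "run_comparison"
  )
  if (!is.null(path)) {
    tab <- data.frame(
      label = c(bundle_a$label, bundle_b$label),
      kd = c(a$display, b$display),
      n_residues = c(a$n_residues, b$n_residues),
      fold_change_a_over_b = c(fold_display, ""),
      welch_p = c(.fmt_num(cmp$p_value), ""),
      stringsAsFactors = FALSE
    )
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf("<run_comparison> %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  Kd: %s vs %s; fold-change (A/B): %s\n",
              x$display_a, x$display_b, x$fold_display))
  if (!is.na(x$comparison$p_value)) {
    cat(sprintf("  Welch two-sided p = %.3g\n", x$comparison$p_value))
  }
  invisible(x)
}

#' Export per-residue attributes for molecular-graphics mapping
#'
#' Writes one whitespace-delimited line per residue: `residue_id`, CSP at
#' the reference point (or `NA`), and a 0/1 significance flag -- a minimal
#' format that molecular-graphics attribute loaders can ingest to colour a
#' structure by perturbation.
#'
#' @param profile A classified [csp_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_structure_attributes <- function(profile, path) {
  stopifnot(inherits(profile, "csp_profile"))
  if (all(is.na(profile$significant))) {
    stop("profile has no significance flags; run classify() first", call. = FALSE)
  }
  csp <- ifelse(is.na(profile$csp), "NA", .fmt_num(profile$csp))
  flag <- ifelse(is.na(profile$significant), 0L, as.integer(profile$significant))
  writeLines(sprintf("%d\t%s\t%d", profile$residue_id, csp, flag), path)
  invisible(path)
}
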