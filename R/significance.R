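# Trimmed-threshold classification of significantly perturbed residues.

#' Significance threshold for a CSP profile
#'
#' Implements the trimmed mean-plus-k-SD rule: residues with undefined CSP
#' (unassigned, overlapped, broadened) are excluded entirely; the
#' `ceiling(trim_fraction * N)` residues with the largest CSP are removed
#' from the statistic (they are the expected binders and would otherwise
#' inflate it); the threshold is mean + `k_sd` * SD of the remainder, with
#' the SD taken over the remainder as a population (divisor n). Every residue
#' with a defined CSP -- including the trimmed ones -- strictly exceeding the
#' threshold is called significant.
#'
#' Ties at the trim boundary are broken by residue number, the lower number
#' being retained in the statistic.
#'
#' @param profile A [csp_profile()].
#' @param trim_fraction Fraction of largest-CSP residues removed from the
#'   statistic (default 0.10).
#' @param k_sd SD multiplier (default 2).
#' @return A `csp_significance` list: `threshold` (ppm), `trimmed_ids`,
#'   `significant_ids`, `n_used`, `mean_used`, `sd_used`, `trim_fraction`,
#'   `k_sd`.
#' @export
significance_threshold <- function(profile, trim_fraction = 0.10, k_sd = 2) {
  stopifnot(inherits(profile, "csp_profile"))
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 1) {
    stop("trim_fraction must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(k_sd) || k_sd < 0) stop("k_sd must be >= 0", call. = FALSE)
  ok <- !is.na(profile$csp)
  ids <- profile$residue_id[ok]
  x <- profile$csp[ok]
  if (length(x) < 3L) {
    stop("significance classification requires at least 3 residues with a defined CSP",
         call. = FALSE)
  }
  n_trim <- as.integer(ceiling(trim_fraction * length(x)))
  ord <- order(x, ids)  # ascending; among tied CSPs the larger id is trimmed first
  trimmed <- if (n_trim > 0L) ord[seq.int(length(x) - n_trim + 1L, length(x))] else integer(0)
  kept <- if (n_trim > 0L) ord[seq_len(length(x) - n_trim)] else ord
  if (length(kept) < 2L) {
    stop("fewer than 2 residues remain after trimming; SD undefined", call. = FALSE)
  }
  m <- mean(x[kept])
  s <- sqrt(mean((x[kept] - m)^2))
  threshold <- m + k_sd * s
  structure(
    list(
      threshold = threshold,
      trimmed_ids = sort(ids[trimmed]),
      significant_ids = sort(ids[x > threshold]),
      n_used = length(kept),
      mean_used = m,
      sd_used = s,
      trim_fraction = trim_fraction,
      k_sd = k_sd
    ),
    class = "csp_significance"
  )
}

#' @export
print.csp_significance <- function(x, ...) {
  cat(sprintf("<csp_significance> threshold = %.4f ppm (mean %.4f + %g SD %.4f; n = %d)\n",
              x$threshold, x$mean_used, x$k_sd, x$sd_used, x$n_used))
  cat(sprintf("  trimmed: %d residue(s); significant: %d residue(s)\n",
              length(x$trimmed_ids), length(x$significant_ids)))
  if (length(x$significant_ids)) {
    cat("  significant:", paste(x$significant_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annotate a CSP profile with significance calls
#'
#' @param profile The [csp_profile()] the result was computed from.
#' @param result A [significance_threshold()] result for that profile.
#' @return The profile with its `significant` column filled (NA where the
#'   CSP is undefined) and a `threshold` attribute (the profile plot's "grey
#'   line").
#' @export
classify <- function(profile, result) {
  stopifnot(inherits(profile, "csp_profile"), inherits(result, "csp_significance"))
  defined <- profile$residue_id[!is.na(profile$csp)]
  known <- c(defined, result$trimmed_ids, result$significant_ids)
  if (!all(result$significant_ids %in% defined) ||
      !all(result$trimmed_ids %in% defined)) {
    stop("significance result does not match this profile's residue set", call. = FALSE)
  }
  profile$significant <- ifelse(is.na(profile$csp), NA,
                                profile$residue_id %in% result$significant_ids)
  attr(profile, "threshold") <- result$threshold
  profile
}
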