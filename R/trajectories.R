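# Residue tracking across titration points and CSP computation.

#' Weighted chemical shift perturbation
#'
#' Combines amide 1H and 15N shift differences into the normalized CSP
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (w_N\,\Delta\delta_N)^2}}
#' with the conventional nitrogen weight \eqn{w_N = 0.154} accounting for the
#' narrower 1H dispersion. Vectorized; inputs recycle as usual.
#'
#' @param delta_h 1H shift difference(s), ppm.
#' @param delta_n 15N shift difference(s), ppm.
#' @param weight_n Dimensionless nitrogen weight (> 0, default 0.154).
#' @return Nonnegative CSP value(s), ppm.
#' @examples
#' compute_csp(0.10, 0)          # 0.10
#' compute_csp(0, 1.0)           # 0.154
#' @export
compute_csp <- function(delta_h, delta_n, weight_n = 0.154) {
  if (!is.numeric(delta_h) || !is.numeric(delta_n)) {
    stop("delta_h and delta_n must be numeric", call. = FALSE)
  }
  if (any(!is.finite(delta_h)) || any(!is.finite(delta_n))) {
    stop("chemical shift differences must be finite", call. = FALSE)
  }
  if (!is.numeric(weight_n) || length(weight_n) != 1L ||
      !is.finite(weight_n) || weight_n <= 0) {
    stop("weight_n must be a single positive number", call. = FALSE)
  }
  sqrt(delta_h^2 + (weight_n * delta_n)^2)
}

# Weighted distance between peak positions, using the same 15N weight as the
# CSP metric so tracking and quantification share one geometry.
.weighted_dist <- function(h1, n1, h2, n2, weight_n) {
  sqrt((h1 - h2)^2 + (weight_n * (n1 - n2))^2)
}

#' Track residue peaks across a titration series
#'
#' Builds one trajectory per residue from the apo point outward. When every
#' peak list carries residue assignments, tracking is by `residue_id`. Points
#' whose peaks lack assignments are tracked by nearest neighbour in the
#' weighted (1H, 15N) plane, seeded from each residue's position at the
#' previous point and rejecting jumps larger than `max_step`.
#'
#' Status bookkeeping mirrors the starred categories of per-residue CSP
#' profiles: residues missing from a point are `broadened` from that point
#' onward (`***`); two trajectories whose peaks approach within `merge_tol`
#' are both `overlapped` from that point onward (`**`); residues with no apo
#' assignment are `unassigned_apo` throughout (`*`). CSP values are defined
#' only where a residue is `observed`, and are 0 at the apo point.
#'
#' @param series A [titration_series()].
#' @param max_step Maximum weighted per-step displacement (ppm) accepted by
#'   nearest-neighbour tracking; default 0.05.
#' @param merge_tol Weighted distance (ppm) below which two peaks are deemed
#'   unresolvable; default 0.01.
#' @return A `residue_trajectories` data frame in long format with columns
#'   `residue_id`, `point` (0-based), `shift_h`, `shift_n`, `status`,
#'   `delta_h`, `delta_n`, `csp`, plus attributes `weight_n`, `ligand_conc`,
#'   `protein_conc`, `label`, `n_points`.
#' @export
track_residues <- function(series, max_step = 0.05, merge_tol = 0.01) {
  stopifnot(inherits(series, "titration_series"))
  w <- series$weight_n
  npts <- length(series$points)
  apo <- series$points[[1L]]$peaks
  if (nrow(apo) == 0) stop("apo peak list is empty", call. = FALSE)

  all_ids <- sort(unique(unlist(lapply(series$points, function(p) {
    id <- p$peaks$residue_id
    id[!is.na(id)]
  }))))
  if (length(all_ids) == 0) {
    stop("no assigned residues in any peak list; apo assignments are required",
         call. = FALSE)
  }
  n <- length(all_ids)
  pos_h <- pos_n <- matrix(NA_real_, n, npts)
  status <- matrix(NA_character_, n, npts)

  # Apo point must be assigned; it anchors every trajectory.
  i_apo <- match(apo$residue_id, all_ids)
  if (anyNA(i_apo)) stop("apo peak list has unassigned peaks", call. = FALSE)
  pos_h[i_apo, 1L] <- apo$shift_h
  pos_n[i_apo, 1L] <- apo$shift_n
  status[i_apo, 1L] <- apo$status

  for (p in seq_len(npts)[-1L]) {
    pk <- series$points[[p]]$peaks
    if (nrow(pk) == 0) next
    keyed <- !anyNA(pk$residue_id)
    if (keyed) {
      i <- match(pk$residue_id, all_ids)
      pos_h[i, p] <- pk$shift_h
      pos_n[i, p] <- pk$shift_n
      status[i, p] <- pk$status
    } else {
      # Nearest-neighbour assignment seeded from the last known position of
      # each live trajectory; greedy on global minimum distance.
      seed_h <- apply(pos_h[, seq_len(p - 1L), drop = FALSE], 1L, function(v) {
        v <- v[!is.na(v)]; if (length(v)) v[length(v)] else NA_real_
      })
      seed_n <- apply(pos_n[, seq_len(p - 1L), drop = FALSE], 1L, function(v) {
        v <- v[!is.na(v)]; if (length(v)) v[length(v)] else NA_real_
      })
      live <- which(!is.na(seed_h))
      d <- outer(seq_along(live), seq_len(nrow(pk)), function(a, b) {
        .weighted_dist(seed_h[live[a]], seed_n[live[a]], pk$shift_h[b], pk$shift_n[b], w)
      })
      while (length(d) > 0 && min(d, na.rm = TRUE) <= max_step) {
        hit <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)[1L, ]
        ri <- live[hit[1L]]
        pos_h[ri, p] <- pk$shift_h[hit[2L]]
        pos_n[ri, p] <- pk$shift_n[hit[2L]]
        status[ri, p] <- pk$status[hit[2L]]
        d[hit[1L], ] <- Inf
        d[, hit[2L]] <- Inf
        if (all(!is.finite(d))) break
      }
    }
  }

  # Residues with no apo assignment are unusable throughout.
  no_apo <- is.na(status[, 1L])
  status[no_apo, ] <- "unassigned_apo"

  # Absence at a point means the peak broadened beyond detection; sticky.
  for (i in which(!no_apo)) {
    gone <- which(is.na(status[i, ]) | status[i, ] == "broadened")
    if (length(gone)) status[i, gone[1L]:npts] <- "broadened"
  }

  # Overlap: symmetric and sticky. Detected on peaks still 'observed'.
  for (p in if (merge_tol > 0) seq_len(npts) else integer(0)) {
    obs <- which(status[, p] == "observed" & is.finite(pos_h[, p]))
    if (length(obs) < 2L) next
    dh <- outer(pos_h[obs, p], pos_h[obs, p], "-")
    dn <- outer(pos_n[obs, p], pos_n[obs, p], "-")
    d <- sqrt(dh^2 + (w * dn)^2)
    diag(d) <- Inf
    clash <- obs[apply(d < merge_tol, 1L, any)]
    for (i in clash) {
      later <- p:npts
      status[i, later][status[i, later] == "observed"] <- "overlapped"
    }
  }
  # File-supplied overlapped flags are sticky too.
  for (i in seq_len(n)) {
    ov <- which(status[i, ] == "overlapped")
    if (length(ov)) {
      later <- ov[1L]:npts
      status[i, later][status[i, later] == "observed"] <- "overlapped"
    }
  }

  delta_h <- pos_h - pos_h[, 1L]
  delta_n <- pos_n - pos_n[, 1L]
  csp <- sqrt(delta_h^2 + (w * delta_n)^2)
  defined <- status == "observed" & is.finite(csp)
  csp[!defined] <- NA_real_
  delta_h[!defined] <- NA_real_
  delta_n[!defined] <- NA_real_

  out <- data.frame(
    residue_id = rep(all_ids, npts),
    point = rep(seq_len(npts) - 1L, each = n),
    shift_h = as.vector(pos_h),
    shift_n = as.vector(pos_n),
    status = as.vector(status),
    delta_h = as.vector(delta_h),
    delta_n = as.vector(delta_n),
    csp = as.vector(csp),
    stringsAsFactors = FALSE
  )
  attr(out, "weight_n") <- w
  attr(out, "ligand_conc") <- series_ligand_conc(series)
  attr(out, "protein_conc") <- series$protein_conc
  attr(out, "label") <- series$label
  attr(out, "n_points") <- npts
  class(out) <- c("residue_trajectories", "data.frame")
  out
}

#' Per-residue CSP profile at a reference titration point
#'
#' Extracts the CSP of every residue at one (nonzero) titration point,
#' carrying the residue status where no CSP is defined. By default the final
#' point is used, matching the convention of reporting profiles at the last
#' ratio of a titration.
#'
#' @param trajectories Result of [track_residues()].
#' @param reference_point 0-based point index (> 0); default: the last point.
#' @return A `csp_profile` data frame with columns `residue_id`, `csp`,
#'   `status`, `significant` (NA until [classify()]), and attributes
#'   `reference_point`, `weight_n`, `ligand_conc`, `protein_conc`, `label`.
#' @export
csp_profile <- function(trajectories, reference_point = NULL) {
  stopifnot(inherits(trajectories, "residue_trajectories"))
  npts <- attr(trajectories, "n_points")
  if (is.null(reference_point)) reference_point <- npts - 1L
  reference_point <- as.integer(reference_point)
  if (is.na(reference_point) || reference_point < 1L || reference_point > npts - 1L) {
    stop("reference_point must be a point index in 1..", npts - 1L, call. = FALSE)
  }
  ref <- trajectories[trajectories$point == reference_point, , drop = FALSE]
  out <- data.frame(
    residue_id = ref$residue_id,
    csp = ref$csp,
    status = ref$status,
    significant = NA,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$residue_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference_point") <- reference_point
  attr(out, "weight_n") <- attr(trajectories, "weight_n")
  attr(out, "ligand_conc") <- attr(trajectories, "ligand_conc")
  attr(out, "protein_conc") <- attr(trajectories, "protein_conc")
  attr(out, "label") <- attr(trajectories, "label")
  class(out) <- c("csp_profile", "data.frame")
  out
}
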