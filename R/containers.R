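# Core data containers: peak lists and titration series.
# Concentrations are mM throughout; shifts are ppm; point 0 is the apo spectrum.

#' Peak status codes
#'
#' Residue/peak status categories used across the package: `"observed"` (a
#' tracked, quantifiable peak), `"unassigned_apo"` (no apo assignment, `*`),
#' `"overlapped"` (bound-state peak not trackable due to overlap, `**`) and
#' `"broadened"` (peak broadened beyond detection, `***`).
#'
#' @format A character vector of the four status tokens.
#' @export
peak_statuses <- c("observed", "unassigned_apo", "overlapped", "broadened")

# Glyph aliases accepted on read, mirroring the starred categories used in
# per-residue CSP profile figures.
.status_glyphs <- c("*" = "unassigned_apo", "**" = "overlapped", "***" = "broadened")

.normalize_status <- function(status) {
  status <- as.character(status)
  status[is.na(status) | status == ""] <- "observed"
  glyph <- status %in% names(.status_glyphs)
  status[glyph] <- .status_glyphs[status[glyph]]
  bad <- !(status %in% peak_statuses)
  if (any(bad)) {
    stop("unknown peak status token(s): ", paste(unique(status[bad]), collapse = ", "),
         call. = FALSE)
  }
  status
}

#' Construct a peak list
#'
#' A peak list is a data frame with one row per assigned backbone amide peak
#' of a single 2D spectrum, carrying the `point_index` of the titration point
#' it belongs to (0 = apo).
#'
#' @param peaks Data frame with columns `residue_id` (positive integer
#'   sequence number), `shift_h` (ppm), `shift_n` (ppm), and optionally
#'   `residue_name` and `status` (see [peak_statuses]; the glyphs `*`, `**`,
#'   `***` are accepted as aliases).
#' @param point_index Integer >= 0; 0 denotes the apo spectrum.
#' @return A `peak_list` data frame with columns `residue_id`,
#'   `residue_name`, `shift_h`, `shift_n`, `status`, ordered by residue.
#' @export
peak_list <- function(peaks, point_index = 0L) {
  stopifnot(is.data.frame(peaks))
  point_index <- as.integer(point_index)
  if (is.na(point_index) || point_index < 0L) {
    stop("point_index must be a non-negative integer", call. = FALSE)
  }
  required <- c("residue_id", "shift_h", "shift_n")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0) {
    stop("peak list is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  residue_id <- suppressWarnings(as.integer(peaks$residue_id))
  if (any(!is.na(residue_id) & residue_id < 1L)) {
    stop("residue_id must be positive integers (NA allowed for unassigned peaks)",
         call. = FALSE)
  }
  known <- residue_id[!is.na(residue_id)]
  if (anyDuplicated(known)) {
    stop("duplicate residue_id in peak list: ",
         paste(unique(known[duplicated(known)]), collapse = ", "),
         call. = FALSE)
  }
  status <- if ("status" %in% names(peaks)) .normalize_status(peaks$status) else
    rep("observed", nrow(peaks))
  shift_h <- as.numeric(peaks$shift_h)
  shift_n <- as.numeric(peaks$shift_n)
  obs <- status == "observed"
  if (any(!is.finite(shift_h[obs])) || any(!is.finite(shift_n[obs]))) {
    stop("observed peaks must have finite shift_h and shift_n", call. = FALSE)
  }
  residue_name <- if ("residue_name" %in% names(peaks))
    as.character(peaks$residue_name) else rep(NA_character_, nrow(peaks))
  residue_name[!is.na(residue_name) & residue_name == ""] <- NA_character_
  out <- data.frame(
    residue_id = residue_id,
    residue_name = residue_name,
    shift_h = shift_h,
    shift_n = shift_n,
    status = status,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$residue_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "point_index") <- point_index
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Construct a titration series
#'
#' An ordered set of titration points sharing a protein concentration, each
#' pairing a ligand:protein molar ratio with the peak list observed at that
#' point. The first point must be the apo spectrum (ratio 0) and ratios must
#' be nondecreasing. At least 4 points are required for isotherm fitting
#' downstream (typical experiments use 7-9).
#'
#' @param peaklists List of peak lists (see [peak_list()]); plain data frames
#'   are accepted and validated.
#' @param protein_conc Protein concentration \[P\] in mM (> 0), shared across
#'   points.
#' @param ratios Numeric vector of ligand:protein molar ratios, one per peak
#'   list, starting at 0 and nondecreasing.
#' @param label Series label, e.g. `"BD2:dsRNAI"`.
#' @param weight_n Dimensionless nitrogen weight used in the CSP metric
#'   (default 0.154).
#' @param precondition_ligand Optional name of a ligand held saturating
#'   throughout (ternary-condition experiments).
#' @return A `titration_series` object: list with `label`, `protein_conc`,
#'   `weight_n`, `precondition_ligand` and `points`, each point a list with
#'   `point_index`, `molar_ratio`, `ligand_conc` (mM), `protein_conc` and
#'   `peaks`.
#' @export
titration_series <- function(peaklists, protein_conc, ratios, label = "series",
                             weight_n = 0.154, precondition_ligand = NULL) {
  if (!is.numeric(protein_conc) || length(protein_conc) != 1L ||
      !is.finite(protein_conc) || protein_conc <= 0) {
    stop("protein_conc must be a single positive number (mM)", call. = FALSE)
  }
  if (!is.numeric(weight_n) || length(weight_n) != 1L || weight_n <= 0) {
    stop("weight_n must be a single positive number", call. = FALSE)
  }
  if (!is.list(peaklists) || length(peaklists) != length(ratios)) {
    stop("peaklists and ratios must have the same length", call. = FALSE)
  }
  ratios <- as.numeric(ratios)
  if (length(ratios) < 1L || anyNA(ratios) || any(ratios < 0)) {
    stop("ratios must be non-negative numbers", call. = FALSE)
  }
  if (ratios[1L] != 0) {
    stop("first titration point must be the apo spectrum (ratio 0)", call. = FALSE)
  }
  if (is.unsorted(ratios)) {
    stop("molar ratios must be nondecreasing", call. = FALSE)
  }
  points <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    pl <- peaklists[[i]]
    if (!inherits(pl, "peak_list")) pl <- peak_list(pl, point_index = i - 1L)
    attr(pl, "point_index") <- i - 1L
    points[[i]] <- list(
      point_index = i - 1L,
      molar_ratio = ratios[i],
      ligand_conc = ratios[i] * protein_conc,
      protein_conc = protein_conc,
      peaks = pl
    )
  }
  structure(
    list(
      label = as.character(label),
      protein_conc = protein_conc,
      weight_n = weight_n,
      precondition_ligand = precondition_ligand,
      points = points
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  ratios <- vapply(x$points, `[[`, numeric(1), "molar_ratio")
  cat(sprintf("<titration_series> %s\n", x$label))
  cat(sprintf("  [P] = %g mM; %d points; ratios: %s\n",
              x$protein_conc, length(x$points), paste(ratios, collapse = ", ")))
  if (!is.null(x$precondition_ligand)) {
    cat(sprintf("  pre-bound ligand: %s\n", x$precondition_ligand))
  }
  n_apo <- nrow(x$points[[1L]]$peaks)
  cat(sprintf("  apo peaks: %d; weight_n = %g\n", n_apo, x$weight_n))
  invisible(x)
}

# Ligand concentrations (mM) of every point, in order.
series_ligand_conc <- function(series) {
  vapply(series$points, `[[`, numeric(1), "ligand_conc")
}
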