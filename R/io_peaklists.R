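# Peak-list and titration-series file I/O.
#
# Two peak-list dialects are supported: a headed CSV (columns residue_id,
# shift_h, shift_n, optional residue_name, status) and Sparky-style .list
# files (assignment w1 w2, with w1 = 15N and w2 = 1H). A titration series is
# described by a small YAML config naming the protein concentration, the
# molar-ratio schedule and one peak-list file per point.

# Format a double so that reading it back reproduces the value exactly
# (17 significant digits round-trip IEEE doubles).
.fmt_num <- function(x) {
  out <- character(length(x))
  ok <- !is.na(x)
  out[ok] <- formatC(x[ok], digits = 17, format = "g", width = 1)
  out[!ok] <- ""
  out
}

#' Read a peak list file
#'
#' @param path Path to the file.
#' @param format `"csv"` (headed, columns `residue_id`, `shift_h`, `shift_n`,
#'   optional `residue_name` and `status`) or `"sparky"` (whitespace-delimited
#'   `assignment w1 w2` rows such as `G275N-H 119.20 8.05`, where `w1` is the
#'   15N shift and `w2` the 1H shift).
#' @param point_index Titration point the list belongs to (0 = apo).
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, format = c("csv", "sparky"), point_index = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("peak list file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    required <- c("residue_id", "shift_h", "shift_n")
    missing_cols <- setdiff(required, names(df))
    if (length(missing_cols) > 0) {
      stop("peak list CSV ", path, " is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    peak_list(df, point_index = point_index)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    lines <- lines[!grepl("^Assignment", lines, ignore.case = TRUE)]
    if (length(lines) == 0) {
      return(peak_list(data.frame(residue_id = integer(0), shift_h = numeric(0),
                                  shift_n = numeric(0)), point_index = point_index))
    }
    fields <- strsplit(lines, "[[:space:]]+")
    n_fields <- lengths(fields)
    if (any(n_fields < 3L)) {
      stop("sparky list ", path, ": expected 'assignment w1 w2' on every line",
           call. = FALSE)
    }
    assignment <- vapply(fields, `[[`, character(1), 1L)
    m <- regmatches(assignment, regexec("^([A-Za-z]{1,3})?([0-9]+)N-?H$", assignment))
    bad <- vapply(m, length, integer(1)) == 0L
    if (any(bad)) {
      stop("sparky list ", path, ": unparseable assignment(s): ",
           paste(utils::head(assignment[bad], 3L), collapse = ", "), call. = FALSE)
    }
    residue_name <- vapply(m, `[[`, character(1), 2L)
    residue_name[residue_name == ""] <- NA_character_
    residue_id <- as.integer(vapply(m, `[[`, character(1), 3L))
    w1 <- as.numeric(vapply(fields, `[[`, character(1), 2L))  # 15N
    w2 <- as.numeric(vapply(fields, `[[`, character(1), 3L))  # 1H
    peak_list(data.frame(residue_id = residue_id, residue_name = residue_name,
                         shift_h = w2, shift_n = w1, stringsAsFactors = FALSE),
              point_index = point_index)
  }
}

#' Write a peak list file
#'
#' Numeric shifts are written with full precision so that
#' `read_peaklist(write_peaklist(x))` reproduces `x` exactly.
#'
#' @param peaks A [peak_list()].
#' @param path Output path.
#' @param format `"csv"` or `"sparky"` (sparky drops status and non-observed
#'   peaks, as the dialect has no status field).
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path, format = c("csv", "sparky")) {
  format <- match.arg(format)
  stopifnot(inherits(peaks, "peak_list"))
  if (format == "csv") {
    df <- data.frame(
      residue_id = ifelse(is.na(peaks$residue_id), "", as.character(peaks$residue_id)),
      residue_name = ifelse(is.na(peaks$residue_name), "", peaks$residue_name),
      shift_h = .fmt_num(peaks$shift_h),
      shift_n = .fmt_num(peaks$shift_n),
      status = peaks$status,
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    obs <- peaks[peaks$status == "observed" & !is.na(peaks$residue_id), , drop = FALSE]
    name <- ifelse(is.na(obs$residue_name), "", obs$residue_name)
    lines <- c("Assignment w1 w2",
               sprintf("%s%dN-H %s %s", name, obs$residue_id,
                       .fmt_num(obs$shift_n), .fmt_num(obs$shift_h)))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a titration-series configuration
#'
#' The config is a YAML file with fields `label`, `protein_conc` (mM),
#' optional `weight_n`, optional `precondition_ligand`, optional `format`
#' (`csv` or `sparky`, default `csv`) and `points`: a list of
#' `{ratio, peaklist}` entries ordered by nondecreasing ratio, the first with
#' ratio 0 (apo). Peak-list paths are resolved relative to the config file.
#' Ligand concentrations are derived as `ratio * protein_conc`.
#'
#' @param path Path to the YAML config.
#' @return A [titration_series()].
#' @export
read_series_config <- function(path) {
  if (!file.exists(path)) stop("series config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (field in c("protein_conc", "points")) {
    if (is.null(cfg[[field]])) {
      stop("series config is missing mandatory field: ", field, call. = FALSE)
    }
  }
  fmt <- if (is.null(cfg$format)) "csv" else cfg$format
  base <- dirname(normalizePath(path))
  ratios <- vapply(cfg$points, function(p) as.numeric(p$ratio), numeric(1))
  if (anyNA(ratios)) stop("every point needs a numeric ratio", call. = FALSE)
  peaklists <- lapply(seq_along(cfg$points), function(i) {
    rel <- cfg$points[[i]]$peaklist
    if (is.null(rel)) stop("point ", i - 1L, " has no peaklist path", call. = FALSE)
    p <- if (file.exists(rel)) rel else file.path(base, rel)
    read_peaklist(p, format = fmt, point_index = i - 1L)
  })
  titration_series(
    peaklists = peaklists,
    protein_conc = as.numeric(cfg$protein_conc),
    ratios = ratios,
    label = if (is.null(cfg$label)) "series" else cfg$label,
    weight_n = if (is.null(cfg$weight_n)) 0.154 else as.numeric(cfg$weight_n),
    precondition_ligand = cfg$precondition_ligand
  )
}

#' Write a titration series to a directory
#'
#' Writes one CSV peak list per point (`point_0.csv`, `point_1.csv`, ...) and
#' a YAML config `series.yaml` referring to them, in the formats
#' [read_series_config()] consumes. Numbers are written at full precision so
#' the round trip is exact.
#'
#' @param series A [titration_series()].
#' @param dir Output directory (created if needed).
#' @param name Config file name (default `"series.yaml"`).
#' @return The config path, invisibly.
#' @export
write_series_config <- function(series, dir, name = "series.yaml") {
  stopifnot(inherits(series, "titration_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("point_%d.csv", seq_along(series$points) - 1L)
  for (i in seq_along(series$points)) {
    write_peaklist(series$points[[i]]$peaks, file.path(dir, files[i]), "csv")
  }
  cfg <- list(
    label = series$label,
    protein_conc = .fmt_num(series$protein_conc),
    weight_n = .fmt_num(series$weight_n),
    format = "csv",
    points = lapply(seq_along(series$points), function(i) {
      list(ratio = .fmt_num(series$points[[i]]$molar_ratio), peaklist = files[i])
    })
  )
  if (!is.null(series$precondition_ligand)) {
    cfg$precondition_ligand <- series$precondition_ligand
  }
  path <- file.path(dir, name)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write the per-residue results table
#'
#' One TSV row per residue of the profile: CSP at every titration point (when
#' trajectories are supplied), CSP at the reference point, status,
#' significance flag, and the fitted Kd and saturation CSP where a fit
#' exists. Residues without a fit (e.g. broadened or non-significant) keep
#' empty fit columns. Output is deterministic: rewriting unchanged inputs is
#' byte-identical.
#'
#' @param profile A [csp_profile()], ideally after [classify()].
#' @param fits Fit table from [fit_binding()] (may be empty or `NULL`).
#' @param path Output TSV path.
#' @param trajectories Optional [track_residues()] result; adds per-point
#'   CSP columns `csp_p<k>`.
#' @return `path`, invisibly.
#' @export
write_residue_table <- function(profile, fits, path, trajectories = NULL) {
  stopifnot(inherits(profile, "csp_profile"))
  out <- data.frame(residue_id = profile$residue_id, stringsAsFactors = FALSE)
  if (!is.null(trajectories)) {
    for (p in sort(unique(trajectories$point))) {
      v <- trajectories$csp[match(
        paste(profile$residue_id, p),
        paste(trajectories$residue_id, trajectories$point))]
      out[[sprintf("csp_p%d", p)]] <- .fmt_num(v)
    }
  }
  out$csp <- .fmt_num(profile$csp)
  out$status <- profile$status
  sig <- if ("significant" %in% names(profile)) profile$significant else
    rep(NA, nrow(profile))
  out$significant <- ifelse(is.na(sig), "", ifelse(sig, "yes", "no"))
  kd <- ddmax <- rep(NA_real_, nrow(profile))
  if (!is.null(fits) && nrow(fits) > 0) {
    i <- match(profile$residue_id, fits$residue_id)
    has <- !is.na(i) & fits$converged[pmax(i, 1L)] & !fits$nonbinder[pmax(i, 1L)]
    has[is.na(has)] <- FALSE
    kd[has] <- fits$kd[i[has]]
    ddmax[has] <- fits$ddmax[i[has]]
  }
  out$kd <- .fmt_num(kd)
  out$ddmax <- .fmt_num(ddmax)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
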