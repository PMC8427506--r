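#' Write a recording to the neutral sweep-table format
#'
#' The sweep_csv format is a long-format CSV (`cell_id, protocol,
#' sweep_index, t_s, y, i_cmd`) accompanied by a JSON sidecar
#' (`<stem>.json`) holding the sampling rate, recording mode and units per
#' protocol plus the cell-level metadata.  The format is plain text, so
#' fixtures and round-trips stay dependency-free.
#'
#' @param rec A [cell_recording()].
#' @param path Output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(rec, path) {
  rows <- list()
  side <- list(cell_id = rec$cell_id, genotype = rec$genotype,
               series_resistance_mohm = rec$series_resistance_mohm,
               protocols = list())
  for (pn in names(rec$sweeps)) {
    sws <- rec$sweeps[[pn]]
    side$protocols[[pn]] <- list(fs = sws[[1]]$fs, mode = sws[[1]]$mode,
                                 units = list(t = "s",
                                              y = if (sws[[1]]$mode == "current_clamp") "mV" else "pA",
                                              i_cmd = if (sws[[1]]$mode == "current_clamp") "pA" else "mV"))
    if (!is.null(rec$protocols[[pn]]))
      side$protocols[[pn]]$step <- unclass(rec$protocols[[pn]])
    for (k in seq_along(sws)) {
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = rec$cell_id, protocol = pn, sweep_index = k,
                   t_s = sws[[k]]$t, y = sws[[k]]$y, i_cmd = sws[[k]]$i_cmd)
    }
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  jsonlite::write_json(side, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a recording from the sweep-table format
#'
#' Units are normalized at ingestion: a sidecar declaring the signal in
#' volts (`"V"`) or amperes-scale units is converted to mV/pA; time must be
#' seconds.  A missing sampling rate or ragged sweeps are errors.
#'
#' @param path CSV path written by [write_sweeps()] (sidecar alongside).
#' @param format Input format; only `"sweep_csv"` is supported.
#' @return A [cell_recording()].
#' @export
read_sweeps <- function(path, format = c("sweep_csv", "abf", "nwb")) {
  format <- match.arg(format)
  if (format != "sweep_csv")
    stop(sprintf("format '%s' is not supported by this build", format))
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "protocol", "sweep_index", "t_s", "y", "i_cmd")
  if (!all(need %in% names(df)))
    stop("sweep_csv must have columns: ", paste(need, collapse = ", "))
  sweeps <- list()
  protocols <- list()
  for (pn in unique(df$protocol)) {
    meta <- side$protocols[[pn]]
    if (is.null(meta) || is.null(meta$fs))
      stop(sprintf("sidecar lacks fs for protocol '%s'", pn))
    scale_y <- .unit_scale(meta$units$y, meta$mode)
    sub <- df[df$protocol == pn, ]
    ks <- sort(unique(sub$sweep_index))
    lens <- tapply(sub$t_s, sub$sweep_index, length)
    if (length(unique(lens)) != 1)
      stop(sprintf("ragged sweeps in protocol '%s'", pn))
    sweeps[[pn]] <- lapply(ks, function(k) {
      sk <- sub[sub$sweep_index == k, ]
      new_sweep(sk$t_s, sk$y * scale_y, sk$i_cmd, meta$fs, meta$mode)
    })
    if (!is.null(meta$step))
      protocols[[pn]] <- step_protocol(meta$step$baseline_ms,
                                       meta$step$step_dur_ms,
                                       meta$step$amplitudes_pA,
                                       tail_ms = meta$step$tail_ms,
                                       step_start_ms = meta$step$step_start_ms)
  }
  cell_recording(side$cell_id, side$genotype, sweeps = sweeps,
                 protocols = protocols,
                 series_resistance_mohm = side$series_resistance_mohm)
}

# Conversion factor to the package-internal unit (mV or pA).
.unit_scale <- function(unit, mode) {
  internal <- if (identical(mode, "current_clamp")) "mV" else "pA"
  if (is.null(unit) || identical(unit, internal)) return(1)
  conv <- c(V = 1000, mV = 1, A = 1e12, nA = 1000, pA = 1)
  if (!unit %in% names(conv)) stop("unknown unit: ", unit)
  conv[[unit]] / conv[[internal]]
}

#' Cell-level quality-control rule
#'
#' Cells with a series resistance above 30 MOhm or a resting membrane
#' potential above (more depolarized than) -60 mV are excluded.  Both
#' comparisons are strict.
#'
#' @param max_series_resistance_mohm,max_rmp_mv Exclusion bounds.
#' @return An object of class `qc_rule`.
#' @export
qc_rule <- function(max_series_resistance_mohm = .const$qc_max_rs_mohm,
                    max_rmp_mv = .const$qc_max_rmp_mv) {
  structure(list(max_series_resistance_mohm = max_series_resistance_mohm,
                 max_rmp_mv = max_rmp_mv), class = "qc_rule")
}

#' Apply the cell-level QC rule
#'
#' Sets `qc_pass` to `FALSE` exactly when the series resistance exceeds the
#' bound or the RMP (computed from the zero-current sweep by [rmp()]) is
#' more depolarized than the bound, with the reason (`"Rs"`, `"RMP"` or
#' `"Rs+RMP"`) recorded.  Excluded cells must never enter group statistics.
#' Idempotent.
#'
#' @param rec A [cell_recording()].
#' @param rule A [qc_rule()].
#' @return The recording with `qc_pass`/`qc_reason` filled in.
#' @export
apply_qc <- function(rec, rule = qc_rule()) {
  stopifnot(inherits(rec, "cell_recording"), inherits(rule, "qc_rule"))
  reasons <- character(0)
  if (is.finite(rec$series_resistance_mohm) &&
      rec$series_resistance_mohm > rule$max_series_resistance_mohm)
    reasons <- c(reasons, "Rs")
  if (rmp(rec) > rule$max_rmp_mv)
    reasons <- c(reasons, "RMP")
  rec$qc_pass <- length(reasons) == 0
  rec$qc_reason <- if (length(reasons)) paste(reasons, collapse = "+") else NA_character_
  rec
}

#' Apply QC to a whole cohort
#'
#' @param cohort List of [cell_recording()] objects.
#' @param rule A [qc_rule()].
#' @return The cohort with QC state filled in; a summary data frame of
#'   exclusions is attached as attribute `"qc_report"`.
#' @export
apply_qc_cohort <- function(cohort, rule = qc_rule()) {
  out <- lapply(cohort, apply_qc, rule = rule)
  rep <- data.frame(cell_id = vapply(out, `[[`, "", "cell_id"),
                    genotype = vapply(out, `[[`, "", "genotype"),
                    qc_pass = vapply(out, `[[`, TRUE, "qc_pass"),
                    reason = vapply(out, `[[`, "", "qc_reason"))
  attr(out, "qc_report") <- rep
  out
}
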