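#' Resting membrane potential
#'
#' Mean of the first 100 ms of the zero-current sweep of the 1-s step
#' series.
#'
#' @param rec A [cell_recording()] with a `steps_1s` protocol.
#' @return RMP (mV).
#' @export
rmp <- function(rec) {
  k <- .sweep_at(rec, "steps_1s", 0)
  if (is.na(k)) stop("no zero-current sweep in the step protocol")
  sw <- .get_sweeps(rec, "steps_1s")[[k]]
  n <- round(0.1 * sw$fs)
  if (length(sw$y) < n) stop("zero-current sweep shorter than 100 ms")
  mean(sw$y[seq_len(n)])
}

#' f-I curve: firing frequency per depolarizing step
#'
#' Spike count within the 1-s step window at each depolarizing level
#' (50-300 pA), expressed in Hz.  All APs count, burst or single.
#'
#' @param rec A [cell_recording()] with a `steps_1s` protocol.
#' @param steps_pa Step amplitudes to report (default 50-300 pA).
#' @return Named numeric vector, one entry per available step (Hz);
#'   requested steps missing from the protocol are dropped with a warning.
#' @export
fi_curve <- function(rec, steps_pa = seq(50, 300, by = 50)) {
  sweeps <- .get_sweeps(rec, "steps_1s")
  proto <- rec$protocols$steps_1s
  win <- c(proto$step_start_ms, proto$step_start_ms + proto$step_dur_ms) / 1000
  dur_s <- proto$step_dur_ms / 1000
  out <- numeric(0)
  for (a in steps_pa) {
    k <- .sweep_at(rec, "steps_1s", a)
    if (is.na(k)) {
      warning(sprintf("cell %s: %g pA step missing from protocol", rec$cell_id, a))
      next
    }
    st <- detect_spikes(sweeps[[k]])
    n <- sum(st$peak_times_s >= win[1] & st$peak_times_s <= win[2])
    out[as.character(a)] <- n / dur_s
  }
  out
}

#' Input resistance from hyperpolarizing steps
#'
#' The steady-state deflection of each non-spiking hyperpolarizing step
#' (mean over the last 200 ms of the step minus the mean over the 100 ms
#' pre-step baseline) is regressed on the injected current with a
#' least-squares line through the origin; the slope is the input
#' resistance.  `mode = "single"` instead uses the -100 pA trace alone
#' (deflection over current).
#'
#' @param rec A [cell_recording()] with a `steps_1s` protocol.
#' @param mode `"multi"` (fit over -150, -100, -50 pA) or `"single"`.
#' @return Input resistance (MOhm), with attribute `"mode"`.
#' @export
input_resistance <- function(rec, mode = c("multi", "single")) {
  mode <- match.arg(mode)
  sweeps <- .get_sweeps(rec, "steps_1s")
  proto <- rec$protocols$steps_1s
  amps <- if (mode == "single") -100 else c(-150, -100, -50)
  use_amp <- numeric(0)
  dv <- numeric(0)
  for (a in amps) {
    k <- .sweep_at(rec, "steps_1s", a)
    if (is.na(k)) next
    sw <- sweeps[[k]]
    if (length(detect_spikes(sw)$peak_index)) next
    fs <- sw$fs
    i_base <- round((proto$step_start_ms - 100) / 1000 * fs):round(proto$step_start_ms / 1000 * fs)
    step_end <- proto$step_start_ms + proto$step_dur_ms
    i_ss <- round((step_end - 200) / 1000 * fs):round(step_end / 1000 * fs)
    dv <- c(dv, mean(sw$y[i_ss]) - mean(sw$y[i_base]))
    use_amp <- c(use_amp, a)
  }
  if (!length(use_amp))
    stop("no usable hyperpolarizing sweep (depolarizing-only protocol?)")
  r_gohm <- sum(dv * use_amp) / sum(use_amp^2)   # mV/pA = GOhm
  structure(r_gohm * 1000, mode = mode, steps_pa = use_amp)
}

#' Medium afterhyperpolarization after a 50 Hz pulse train
#'
#' The mAHP is the difference between the trough of the membrane potential
#' after the last evoked spike (the first negative voltage peak, located as
#' the minimum over the post-train window) and the baseline RMP averaged
#' over the 100 ms before the first current pulse.  Negative values mean
#' hyperpolarization below baseline.
#'
#' @param rec A [cell_recording()] with a `mahp_train` protocol.
#' @return mAHP (mV, trough minus baseline).
#' @export
mahp <- function(rec) {
  sw <- .get_sweeps(rec, "mahp_train")[[1]]
  fs <- sw$fs
  on <- which(sw$i_cmd != 0)
  if (!length(on)) stop("mAHP sweep has no stimulus pulses")
  first_pulse <- on[1]
  i_base <- max(1L, first_pulse - round(0.1 * fs)):(first_pulse - 1L)
  baseline <- mean(sw$y[i_base])
  st <- detect_spikes(sw)
  if (!length(st$peak_index)) stop("no spikes evoked by the mAHP train")
  # search from just after the last spike's pasted waveform to sweep end
  start <- st$peak_index[length(st$peak_index)] + round(0.002 * fs)
  seg <- sw$y[start:length(sw$y)]
  imin <- which.min(seg)
  if (imin >= length(seg))
    stop("no voltage trough after the last spike (monotonic return)")
  sw$y[start + imin - 1L] - baseline
}

#' Interspike-interval ratio at 300 pA
#'
#' Ratio of the shortest to the mean inter-spike interval of the APs
#' elicited by the 300 pA step.  Cells firing fewer than 3 APs at 300 pA
#' make the ratio unfeasible and return `NA` (excluded from summaries).
#'
#' @param rec A [cell_recording()] with a `steps_1s` protocol.
#' @return ISI ratio in (0, 1], or `NA`.
#' @export
isi_ratio <- function(rec) {
  k <- .sweep_at(rec, "steps_1s", 300)
  if (is.na(k)) stop("no 300 pA sweep in the step protocol")
  proto <- rec$protocols$steps_1s
  win <- c(proto$step_start_ms, proto$step_start_ms + proto$step_dur_ms) / 1000
  st <- detect_spikes(.get_sweeps(rec, "steps_1s")[[k]])
  tt <- st$peak_times_s[st$peak_times_s >= win[1] & st$peak_times_s <= win[2]]
  if (length(tt) < 3) return(NA_real_)
  isi <- diff(tt)
  min(isi) / mean(isi)
}

#' Extract the full feature set of one cell
#'
#' Aggregates classification and every intrinsic membrane property into a
#' single row: class label, f-I curve (one column per step), maximum firing
#' rate at 150 pA, input resistance, RMP, mAHP, rheobase, AP threshold /
#' amplitude / half-width (from the brief-pulse reference AP) and ISI
#' ratio.  Undefined sub-measures are carried as `NA`.
#'
#' @param rec A QC-passed [cell_recording()] with `steps_1s`, `brief_10ms`
#'   and `mahp_train` protocols.
#' @return A one-row data frame.
#' @export
extract_features <- function(rec) {
  if (isFALSE(rec$qc_pass))
    stop(sprintf("cell %s failed QC (%s); excluded from analysis",
                 rec$cell_id, rec$qc_reason))
  cl <- classify_cell(rec)
  fi <- fi_curve(rec)
  wf <- tryCatch(select_ap_for_waveform(rec)$waveform, error = function(e) NULL)
  mh <- tryCatch(mahp(rec), error = function(e) NA_real_)
  out <- data.frame(cell_id = rec$cell_id, genotype = rec$genotype,
                    class = cl$label, qc_pass = isTRUE(rec$qc_pass) | is.na(rec$qc_pass),
                    rmp_mv = rmp(rec),
                    input_resistance_mohm = as.numeric(input_resistance(rec)),
                    mahp_mv = mh,
                    rheobase_pa = rheobase(rec),
                    threshold_mv = if (is.null(wf)) NA_real_ else wf$threshold_mv,
                    amplitude_mv = if (is.null(wf)) NA_real_ else wf$amplitude_mv,
                    half_width_ms = if (is.null(wf)) NA_real_ else wf$half_width_ms,
                    isi_ratio = isi_ratio(rec),
                    max_rate_150pa_hz = unname(fi["150"]),
                    stringsAsFactors = FALSE)
  for (nm in names(fi)) out[[paste0("fi_", nm, "pa_hz")]] <- unname(fi[nm])
  out
}

#' Feature table for a cohort
#'
#' Applies [extract_features()] to every QC-passed cell and binds the rows.
#' QC-failed cells are skipped (never entering group statistics).
#'
#' @param cohort List of [cell_recording()] objects.
#' @return A data frame, one row per included cell.
#' @export
extract_features_cohort <- function(cohort) {
  rows <- lapply(cohort, function(rec) {
    if (isFALSE(rec$qc_pass)) return(NULL)
    extract_features(rec)
  })
  do.call(rbind, rows)
}
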