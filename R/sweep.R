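#' Construct a single stimulus sweep
#'
#' A sweep is one stimulus epoch: a uniform time base, the recorded signal
#' (membrane potential in mV under current clamp, membrane current in pA
#' under voltage clamp) and the command waveform applied by the amplifier.
#'
#' @param t Time vector in seconds, uniformly spaced.
#' @param y Signal vector (mV or pA), same length as `t`.
#' @param i_cmd Command waveform (pA under current clamp, mV under voltage
#'   clamp), same length as `t`.
#' @param fs Sampling rate in Hz.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @return An object of class `sweep` (a list with the fields above).
#' @export
new_sweep <- function(t, y, i_cmd, fs, mode = c("current_clamp", "voltage_clamp")) {
  mode <- match.arg(mode)
  if (length(t) != length(y) || length(t) != length(i_cmd))
    stop("t, y and i_cmd must have equal length")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  if (length(t) > 2) {
    dt <- diff(t)
    if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("time base must be uniform to within 1 ppm")
  }
  structure(list(t = as.numeric(t), y = as.numeric(y),
                 i_cmd = as.numeric(i_cmd), fs = fs, mode = mode),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s, %d samples @ %g kHz (%.3f s)\n",
              x$mode, length(x$t), x$fs / 1000, length(x$t) / x$fs))
  invisible(x)
}

#' Define a square-step stimulus protocol
#'
#' @param baseline_ms Pre-step baseline duration (ms).
#' @param step_dur_ms Step duration (ms).
#' @param amplitudes_pA Ordered vector of step amplitudes (pA).
#' @param tail_ms Post-step tail duration (ms).
#' @param step_start_ms Step onset time (ms); defaults to `baseline_ms`.
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(baseline_ms, step_dur_ms, amplitudes_pA,
                          tail_ms = 300, step_start_ms = baseline_ms) {
  stopifnot(step_dur_ms > 0, baseline_ms >= 0, tail_ms >= 0,
            all(is.finite(amplitudes_pA)))
  structure(list(baseline_ms = baseline_ms, step_start_ms = step_start_ms,
                 step_dur_ms = step_dur_ms, tail_ms = tail_ms,
                 amplitudes_pA = as.numeric(amplitudes_pA)),
            class = "step_protocol")
}

#' Standard protocols
#'
#' `default_step_protocol()` is the 1-s membrane-excitability series
#' (-150 to +300 pA in 50 pA increments, zero-current sweep included);
#' `brief_step_protocol()` is the 10-ms pulse series in 10 pA increments
#' used for rheobase and AP-waveform measurements.
#'
#' @param max_pa Largest brief-pulse amplitude to test (pA).
#' @return A [step_protocol()].
#' @export
default_step_protocol <- function() {
  step_protocol(baseline_ms = 200, step_dur_ms = 1000,
                amplitudes_pA = seq(-150, 300, by = 50), tail_ms = 300)
}

#' @rdname default_step_protocol
#' @export
brief_step_protocol <- function(max_pa = 500) {
  step_protocol(baseline_ms = 20, step_dur_ms = 10,
                amplitudes_pA = seq(10, max_pa, by = 10), tail_ms = 30)
}

#' Assemble a cell recording
#'
#' Holds all sweeps and protocols for one cell, together with the genotype
#' label, the series resistance and the quality-control state.  Sweep sets
#' are named by protocol: `steps_1s`, `brief_10ms`, `mahp_train`,
#' `sepsc_gapfree`.
#'
#' @param cell_id Character id.
#' @param genotype `"WT"` or `"AS"`.
#' @param sweeps Named list; each element a list of [new_sweep()] objects.
#' @param protocols Named list of [step_protocol()] objects (where defined).
#' @param series_resistance_mohm Pipette series resistance (MOhm).
#' @param meta Free-form metadata list (e.g. simulation ground truth).
#' @return An object of class `cell_recording`.
#' @export
cell_recording <- function(cell_id, genotype = c("WT", "AS"), sweeps = list(),
                           protocols = list(), series_resistance_mohm = NA_real_,
                           meta = list()) {
  genotype <- match.arg(genotype)
  known <- c("steps_1s", "brief_10ms", "mahp_train", "sepsc_gapfree")
  if (length(sweeps) && !all(names(sweeps) %in% known))
    stop("unknown protocol name(s): ",
         paste(setdiff(names(sweeps), known), collapse = ", "))
  structure(list(cell_id = as.character(cell_id), genotype = genotype,
                 sweeps = sweeps, protocols = protocols,
                 series_resistance_mohm = series_resistance_mohm,
                 qc_pass = NA, qc_reason = NA_character_, meta = meta),
            class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("<cell_recording> %s (%s): %s; Rs = %s MOhm; QC: %s\n",
              x$cell_id, x$genotype,
              if (length(x$sweeps))
                paste(sprintf("%s[%d]", names(x$sweeps),
                              vapply(x$sweeps, length, 1L)), collapse = ", ")
              else "no sweeps",
              format(x$series_resistance_mohm),
              if (is.na(x$qc_pass)) "not run"
              else if (x$qc_pass) "pass" else paste0("FAIL (", x$qc_reason, ")")))
  invisible(x)
}

# Internal: fetch the sweep list for a protocol or fail with context.
.get_sweeps <- function(rec, protocol) {
  sw <- rec$sweeps[[protocol]]
  if (is.null(sw))
    stop(sprintf("cell %s: protocol '%s' not present", rec$cell_id, protocol))
  sw
}

# Internal: index of the sweep with a given step amplitude (pA).
.sweep_at <- function(rec, protocol, amp_pa) {
  amps <- rec$protocols[[protocol]]$amplitudes_pA
  i <- which(abs(amps - amp_pa) < 1e-9)
  if (!length(i)) return(NA_integer_)
  i[1]
}
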