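#' Firing-class presets for the adaptive exponential integrate-and-fire model
#'
#' A preset bundles the model constants that put the adaptive exponential
#' integrate-and-fire (AdEx) membrane into one of the three subicular firing
#' phenotypes:
#'
#' * **RF** (regular firing): sub-threshold reset and strong, slow
#'   adaptation; the cell fires trains of single APs (all ISIs > 10 ms).
#' * **WB** (weak bursting): reset above the spike-initiation threshold but
#'   with a large spike-triggered adaptation increment.  At stimulus onset
#'   the adaptation current is still low, so the first reset re-ignites the
#'   spike (an initial burst); from then on the adaptation current stays too
#'   high for another re-ignition and the cell fires tonic single APs.
#' * **SB** (strong bursting): reset well above the spike-initiation
#'   threshold with a smaller adaptation increment; every escape from
#'   quiescence re-ignites into a 2-4 spike burst, and bursts recur as the
#'   adaptation current decays between them.
#'
#' Model constants are in physical units: capacitance `C_pf` (pF), leak
#' conductance `g_l_ns` (nS), leak reversal `e_l_mv` (mV, this is the
#' resting potential at zero current), slope factor `delta_t_mv` (mV),
#' spike-initiation threshold `v_t_mv` (mV), subthreshold adaptation
#' coupling `a_ns` (nS), adaptation time constant `tau_w_ms` (ms), reset
#' `v_r_mv` (mV), spike-triggered adaptation increment `b_pa` (pA).
#'
#' Because the integrate-and-fire reset truncates the action potential, a
#' stereotyped spike waveform (half-cosine rise to `spike_peak_mv` over
#' `spike_rise_ms`, half-cosine fall to the reset over `spike_fall_ms`) is
#' pasted at each spike time so waveform parameters (threshold, amplitude,
#' half-width) are measurable.
#'
#' @param label Firing class, one of `"RF"`, `"WB"`, `"SB"`.
#' @param noise_sd Standard deviation of the Ornstein-Uhlenbeck current
#'   noise (pA); correlation time is `noise_tau_ms`.
#' @param seed Default RNG seed used when simulating this preset.
#' @param ... Named overrides of any preset field (e.g. `e_l_mv = -68`).
#' @return An object of class `neuron_preset`.
#' @examples
#' p <- neuron_preset("SB")
#' rec <- simulate_neuron(p, default_step_protocol())
#' classify_cell(rec)$label
#' @export
neuron_preset <- function(label = c("RF", "WB", "SB"), noise_sd = 5,
                          seed = 1L, ...) {
  label <- match.arg(label)
  base <- switch(label,
    RF = list(C_pf = 180, g_l_ns = 6, e_l_mv = -65, delta_t_mv = 1.5,
              v_t_mv = -52, a_ns = 2, tau_w_ms = 300, v_r_mv = -60,
              b_pa = 60),
    WB = list(C_pf = 100, g_l_ns = 7, e_l_mv = -65, delta_t_mv = 1.5,
              v_t_mv = -51, a_ns = 2, tau_w_ms = 250, v_r_mv = -48.2,
              b_pa = 64),
    SB = list(C_pf = 110, g_l_ns = 6, e_l_mv = -65, delta_t_mv = 2,
              v_t_mv = -53, a_ns = 3, tau_w_ms = 150, v_r_mv = -47.8,
              b_pa = 90))
  p <- c(base,
         list(label = label, noise_sd = noise_sd, noise_tau_ms = 5,
              seed = as.integer(seed),
              v_cut_mv = -30, t_ref_ms = 2.5,
              spike_peak_mv = 30, spike_rise_ms = 0.6, spike_fall_ms = 1.4,
              dt_ms = 0.025))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown preset field(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  num <- p[setdiff(names(p), "label")]
  if (!all(vapply(num, function(z) is.numeric(z) && all(is.finite(z)), TRUE)))
    stop("all model parameters must be finite numbers")
  structure(p, class = "neuron_preset")
}

#' @export
print.neuron_preset <- function(x, ...) {
  cat(sprintf(paste0("<neuron_preset> %s: C=%g pF, gL=%g nS, EL=%g mV, ",
                     "VT=%g mV, Vr=%g mV, a=%g nS, tau_w=%g ms, b=%g pA, ",
                     "noise_sd=%g pA\n"),
              x$label, x$C_pf, x$g_l_ns, x$e_l_mv, x$v_t_mv, x$v_r_mv,
              x$a_ns, x$tau_w_ms, x$b_pa, x$noise_sd))
  invisible(x)
}

# Analytic subthreshold total conductance: leak plus steady-state
# adaptation coupling.  The steady-state deflection to a small current step
# is dV = I / g_total.
.g_total_ns <- function(preset) preset$g_l_ns + preset$a_ns
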