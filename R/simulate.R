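#' Simulate the current-clamp response of a model neuron
#'
#' Integrates the adaptive exponential integrate-and-fire membrane over
#' every step of a stimulus protocol and returns one current-clamp sweep per
#' step.  At each registered spike a stereotyped spike waveform is pasted
#' over the trace (the integrate-and-fire reset truncates the AP), so
#' downstream waveform measurements see a realistic spike shape.  Traces are
#' deterministic given the seed.
#'
#' @param preset A [neuron_preset()].
#' @param protocol A [step_protocol()]; the 1-s series by default.
#' @param fs Sampling rate (Hz); must be at least 10 kHz and is tied to the
#'   integration step (`1/fs` must not exceed 0.05 ms).
#' @param seed RNG seed; defaults to the preset's seed.
#' @param protocol_name Name under which the sweeps are stored in the
#'   returned recording.
#' @param cell_id,genotype Passed to [cell_recording()].
#' @param series_resistance_mohm Series resistance recorded for QC.
#' @return A [cell_recording()] carrying one sweep per protocol step;
#'   ground-truth spike times are kept in `meta$spike_times`.
#' @export
simulate_neuron <- function(preset, protocol = default_step_protocol(),
                            fs = 40000, seed = preset$seed,
                            protocol_name = "steps_1s",
                            cell_id = "sim", genotype = "WT",
                            series_resistance_mohm = 15) {
  stopifnot(inherits(preset, "neuron_preset"), inherits(protocol, "step_protocol"))
  if (fs < 10000) stop("sampling rate must be >= 10 kHz")
  dt <- 1000 / fs                          # ms per sample
  if (dt > 0.05) stop("integration step must be <= 0.05 ms")
  set.seed(seed)
  sweeps <- vector("list", length(protocol$amplitudes_pA))
  truth <- vector("list", length(sweeps))
  for (k in seq_along(protocol$amplitudes_pA)) {
    i_cmd <- .step_icmd(protocol, protocol$amplitudes_pA[k], fs)
    sw <- .simulate_sweep(preset, i_cmd, fs)
    sweeps[[k]] <- sw$sweep
    truth[[k]] <- sw$spike_times_s
  }
  rec <- cell_recording(cell_id, genotype,
                        sweeps = stats::setNames(list(sweeps), protocol_name),
                        protocols = stats::setNames(list(protocol), protocol_name),
                        series_resistance_mohm = series_resistance_mohm,
                        meta = list(preset = preset, seed = seed,
                                    spike_times = stats::setNames(list(truth), protocol_name)))
  rec
}

# Square-step command waveform in pA, one value per sample.
.step_icmd <- function(protocol, amp_pa, fs) {
  dt <- 1000 / fs
  n_total <- round((protocol$step_start_ms + protocol$step_dur_ms +
                    protocol$tail_ms) / dt)
  i_cmd <- numeric(n_total)
  i0 <- round(protocol$step_start_ms / dt) + 1
  i1 <- round((protocol$step_start_ms + protocol$step_dur_ms) / dt)
  i_cmd[i0:i1] <- amp_pa
  i_cmd
}

# Integrate one sweep and paste the stereotyped spike waveform.
.simulate_sweep <- function(preset, i_cmd, fs) {
  dt <- 1000 / fs
  out <- .adex_integrate(i_cmd, dt,
                         preset$C_pf, preset$g_l_ns, preset$e_l_mv,
                         preset$delta_t_mv, preset$v_t_mv, preset$a_ns,
                         preset$tau_w_ms, preset$v_r_mv, preset$b_pa,
                         preset$v_cut_mv, preset$t_ref_ms,
                         preset$noise_sd, preset$noise_tau_ms)
  v <- out$v
  spk <- out$spike_index
  if (length(spk)) v <- .paste_spikes(v, spk, preset, dt)
  t <- (seq_along(v) - 1) / fs
  list(sweep = new_sweep(t, v, i_cmd, fs, "current_clamp"),
       spike_times_s = (spk - 1 + round(preset$spike_rise_ms / dt)) / fs)
}

# Replace the truncated upstroke/reset around each spike sample with a
# stereotyped waveform: half-cosine rise from the pre-spike voltage to the
# peak over spike_rise_ms, half-cosine fall to the reset over spike_fall_ms.
# The fall lands exactly on the reset potential, so the trace stays
# continuous into the post-spike trajectory.  The pasted peak sits
# spike_rise_ms after the integrator's crossing sample; ground-truth spike
# times report the peak.
.paste_spikes <- function(v, spike_index, preset, dt) {
  nr <- round(preset$spike_rise_ms / dt)
  nf <- round(preset$spike_fall_ms / dt)
  peak <- preset$spike_peak_mv
  last_end <- 0L
  for (s in spike_index) {
    j0 <- max(s - 1L, last_end + 1L, 1L)      # rise start (pre-spike sample)
    jp <- s + nr                              # peak sample
    j1 <- min(jp + nf, length(v))             # fall end
    if (jp >= length(v)) break
    v0 <- v[j0]
    rise_n <- jp - j0
    if (rise_n > 0) {
      ph <- seq_len(rise_n) / rise_n
      v[j0 + seq_len(rise_n)] <- v0 + (peak - v0) * (1 - cos(pi * ph)) / 2
    }
    fall_n <- j1 - jp
    if (fall_n > 0) {
      ph <- seq_len(fall_n) / nf
      v[jp + seq_len(fall_n)] <-
        preset$v_r_mv + (peak - preset$v_r_mv) * (1 + cos(pi * pmin(ph, 1))) / 2
    }
    last_end <- j1
  }
  v
}

#' Simulate the medium-afterhyperpolarization pulse-train protocol
#'
#' Drives the cell with a 50 Hz train of brief 3,000 pA pulses for 3 s
#' (150 pulses of `pulse_ms` each), preceded by a quiet baseline and
#' followed by a long tail in which the afterhyperpolarization develops.
#'
#' @inheritParams simulate_neuron
#' @param pulse_pa Pulse amplitude (pA).
#' @param pulse_hz Pulse rate (Hz).
#' @param train_s Train duration (s).
#' @param pulse_ms Single pulse width (ms).
#' @param baseline_ms,tail_ms Pre-train and post-train durations (ms).
#' @return A list: `sweep` (the current-clamp sweep) and `train_end_s`.
#' @export
simulate_mahp_train <- function(preset, fs = 40000, seed = preset$seed,
                                pulse_pa = 3000, pulse_hz = 50, train_s = 3,
                                pulse_ms = 2, baseline_ms = 200,
                                tail_ms = 1000) {
  dt <- 1000 / fs
  set.seed(seed)
  n_total <- round((baseline_ms + train_s * 1000 + tail_ms) / dt)
  i_cmd <- numeric(n_total)
  period_ms <- 1000 / pulse_hz
  n_pulse <- round(train_s * pulse_hz)
  for (k in seq_len(n_pulse) - 1L) {
    i0 <- round((baseline_ms + k * period_ms) / dt) + 1L
    i1 <- i0 + round(pulse_ms / dt) - 1L
    i_cmd[i0:i1] <- pulse_pa
  }
  sw <- .simulate_sweep(preset, i_cmd, fs)
  list(sweep = sw$sweep, spike_times_s = sw$spike_times_s,
       train_end_s = (baseline_ms + train_s * 1000) / 1000,
       baseline_start_s = (baseline_ms - 100) / 1000)
}

#' Simulate a complete cell: all three current-clamp protocols
#'
#' Convenience wrapper producing the 1-s step series, the 10-ms brief-pulse
#' series and the mAHP pulse train for one preset, assembled into a single
#' recording ready for [extract_features()].
#'
#' @inheritParams simulate_neuron
#' @return A [cell_recording()].
#' @export
simulate_cell <- function(preset, fs = 40000, seed = preset$seed,
                          cell_id = "sim", genotype = "WT",
                          series_resistance_mohm = 15) {
  rec <- simulate_neuron(preset, default_step_protocol(), fs = fs, seed = seed,
                         cell_id = cell_id, genotype = genotype,
                         series_resistance_mohm = series_resistance_mohm)
  brief <- simulate_neuron(preset, brief_step_protocol(), fs = fs,
                           seed = seed + 1L, protocol_name = "brief_10ms",
                           cell_id = cell_id, genotype = genotype)
  tr <- simulate_mahp_train(preset, fs = fs, seed = seed + 2L)
  rec$sweeps$brief_10ms <- brief$sweeps$brief_10ms
  rec$protocols$brief_10ms <- brief$protocols$brief_10ms
  rec$sweeps$mahp_train <- list(tr$sweep)
  rec$meta$spike_times$brief_10ms <- brief$meta$spike_times$brief_10ms
  rec$meta$mahp <- list(train_end_s = tr$train_end_s,
                        baseline_start_s = tr$baseline_start_s)
  rec
}

#' Ground truth for a synthetic sEPSC trace
#'
#' Draws Poisson event times and log-normal amplitudes for a spontaneous
#' excitatory postsynaptic current recording, together with the biexponential
#' kernel time constants.
#'
#' @param duration_s Trace duration (s).
#' @param rate_hz Mean event rate (Hz).
#' @param amp_mean_pa,amp_sd_pa Mean and SD of the event amplitude
#'   distribution (pA, log-normal).
#' @param rise_tau_ms,decay_tau_ms Kernel time constants (ms);
#'   `decay_tau_ms` must exceed `rise_tau_ms`.
#' @param baseline_noise_sd_pa Gaussian baseline noise SD (pA).
#' @param seed RNG seed.
#' @return An object of class `sepsc_truth` with strictly increasing
#'   `event_times_s` and positive `event_amplitudes_pa`.
#' @export
sepsc_ground_truth <- function(duration_s, rate_hz = 2, amp_mean_pa = 20,
                               amp_sd_pa = 8, rise_tau_ms = 1.5,
                               decay_tau_ms = 6, baseline_noise_sd_pa = 2,
                               seed = 1L) {
  stopifnot(duration_s > 0, rate_hz >= 0)
  if (decay_tau_ms <= rise_tau_ms)
    stop("decay_tau_ms must exceed rise_tau_ms")
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_s)
  times <- sort(runif(n, 0, duration_s))
  # log-normal parameterized by mean/sd on the natural scale
  s2 <- log(1 + (amp_sd_pa / amp_mean_pa)^2)
  amps <- rlnorm(n, meanlog = log(amp_mean_pa) - s2 / 2, sdlog = sqrt(s2))
  structure(list(event_times_s = times, event_amplitudes_pa = amps,
                 rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 rate_hz = rate_hz, baseline_noise_sd_pa = baseline_noise_sd_pa,
                 duration_s = duration_s, seed = seed),
            class = "sepsc_truth")
}

# Unit-peak biexponential kernel sampled at fs, length ~ 8 decay constants.
.biexp_kernel <- function(rise_tau_ms, decay_tau_ms, fs, length_ms = NULL) {
  if (is.null(length_ms)) length_ms <- 8 * decay_tau_ms
  t <- seq(0, length_ms, by = 1000 / fs)
  k <- exp(-t / decay_tau_ms) - exp(-t / rise_tau_ms)
  k / max(k)
}

#' Render a voltage-clamp trace containing sEPSC events
#'
#' The trace is Gaussian baseline noise plus one unit-peak biexponential
#' kernel per ground-truth event, scaled to the event amplitude and signed
#' negative (inward current at a -70 mV holding potential).
#'
#' @param truth A [sepsc_ground_truth()].
#' @param fs Sampling rate (Hz).
#' @param seed RNG seed for the baseline noise.
#' @return A voltage-clamp [new_sweep()] (y in pA); the ground truth is
#'   attached as attribute `"truth"` for scoring.
#' @export
simulate_sepsc_trace <- function(truth, fs = 10000, seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "sepsc_truth"))
  set.seed(seed)
  n <- round(truth$duration_s * fs)
  y <- if (truth$baseline_noise_sd_pa > 0)
    rnorm(n, 0, truth$baseline_noise_sd_pa) else numeric(n)
  kern <- .biexp_kernel(truth$rise_tau_ms, truth$decay_tau_ms, fs)
  L <- length(kern)
  for (j in seq_along(truth$event_times_s)) {
    i0 <- round(truth$event_times_s[j] * fs) + 1L
    if (i0 > n) next
    idx <- i0:min(i0 + L - 1L, n)
    y[idx] <- y[idx] - truth$event_amplitudes_pa[j] * kern[seq_along(idx)]
  }
  sw <- new_sweep((seq_len(n) - 1) / fs, y, rep(-70, n), fs, "voltage_clamp")
  attr(sw, "truth") <- truth
  sw
}

#' Generate a balanced labeled cohort of simulated cells
#'
#' Builds `n_per_class_per_genotype` cells for each firing class (RF, WB,
#' SB) and genotype (WT, AS).  Cell-to-cell variability is introduced as
#' mild multiplicative jitter on the passive parameters; genotype effects
#' are applied as additive offsets to named preset fields via `effect_spec`
#' (e.g. `list(AS = list(e_l_mv = -2.5, b_pa = -20))` for a hyperpolarized
#' resting potential and a reduced afterhyperpolarization).
#'
#' @param n_per_class_per_genotype Cells per class per genotype (>= 1).
#' @param effect_spec Named list by genotype of named numeric offsets to
#'   preset fields; unknown field names are an error.
#' @param seed Cohort seed; every cell derives its own sub-seed from it.
#' @param noise_sd Current-noise SD (pA) for every cell.
#' @param jitter_cv Coefficient of variation of the per-cell parameter
#'   jitter applied to `C_pf` and `g_l_ns`.
#' @param sepsc If `TRUE`, attach a gap-free sEPSC voltage-clamp sweep.
#' @param sepsc_duration_s Duration of that sweep (s).
#' @return A list of [cell_recording()] objects; each carries its
#'   generating class in `meta$true_label`.
#' @export
make_cohort <- function(n_per_class_per_genotype, effect_spec = list(),
                        seed = 1L, noise_sd = 5, jitter_cv = 0.05,
                        sepsc = FALSE, sepsc_duration_s = 120) {
  stopifnot(n_per_class_per_genotype >= 1)
  jitter_fields <- c("C_pf", "g_l_ns")
  allowed <- names(neuron_preset("RF"))
  for (g in names(effect_spec)) {
    if (!g %in% c("WT", "AS")) stop("effect_spec genotype must be WT or AS")
    bad <- setdiff(names(effect_spec[[g]]), setdiff(allowed, "label"))
    if (length(bad)) stop("unknown effect key(s): ", paste(bad, collapse = ", "))
  }
  cohort <- list()
  idx <- 0L
  for (g in c("WT", "AS")) {
    for (cls in c("RF", "WB", "SB")) {
      for (i in seq_len(n_per_class_per_genotype)) {
        idx <- idx + 1L
        cell_seed <- seed * 1000L + idx
        set.seed(cell_seed)
        p <- neuron_preset(cls, noise_sd = noise_sd, seed = cell_seed)
        for (f in jitter_fields)
          p[[f]] <- p[[f]] * exp(rnorm(1, 0, jitter_cv))
        for (f in names(effect_spec[[g]]))
          p[[f]] <- p[[f]] + effect_spec[[g]][[f]]
        rs <- runif(1, 8, 25)
        rec <- simulate_cell(p, seed = cell_seed,
                             cell_id = sprintf("%s_%s_%02d", g, cls, i),
                             genotype = g, series_resistance_mohm = rs)
        rec$meta$true_label <- cls
        if (sepsc) {
          tr <- sepsc_ground_truth(sepsc_duration_s, seed = cell_seed + 500L)
          rec$sweeps$sepsc_gapfree <- list(simulate_sepsc_trace(tr))
          rec$meta$sepsc_truth <- tr
        }
        cohort[[idx]] <- rec
      }
    }
  }
  cohort
}
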