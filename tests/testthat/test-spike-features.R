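# One simulated suprathreshold sweep, reused across tests in this file.
sim_rec <- simulate_neuron(neuron_preset("WB", seed = 5))
sim_sw <- sim_rec$sweeps$steps_1s[[which(
  sim_rec$protocols$steps_1s$amplitudes_pA == 200)]]

test_that("detect_spikes matches the brute-force oracle on a simulated sweep", {
  got <- detect_spikes(sim_sw)
  want <- oracle_detect_spikes(sim_sw$y, sim_sw$fs)
  expect_identical(got$peak_index, want)
  expect_gt(length(want), 3)
  expect_equal(got$peak_times_s, sim_sw$t[want])
  expect_equal(got$peak_voltages_mv, sim_sw$y[want])
})

test_that("detect_spikes ignores subthreshold and slow deflections", {
  fs <- 2e4
  t <- (0:9999) / fs
  # slow sine crossing 0 mV: big but with dV/dt far below 30 V/s
  slow <- new_sweep(t, 40 * sin(2 * pi * 2 * t), numeric(1e4), fs)
  expect_length(detect_spikes(slow)$peak_index, 0)
  # sharp but subthreshold bump never crossing the 0 mV level
  y <- rep(-65, 1e4); y[5000 + (-3:3)] <- c(-60, -40, -20, -10, -20, -40, -60)
  expect_length(detect_spikes(new_sweep(t, y, numeric(1e4), fs))$peak_index, 0)
})

test_that("waveform parameters match per-sample oracles", {
  st <- detect_spikes(sim_sw)
  for (tpk in st$peak_times_s[1:3]) {
    ipk <- round(tpk * sim_sw$fs) + 1L
    thr <- ap_threshold(sim_sw, tpk)
    expect_equal(thr, oracle_threshold(sim_sw$y, sim_sw$fs, ipk),
                 tolerance = 1e-12)
    wf <- ap_params(sim_sw, tpk)
    expect_equal(wf$threshold_mv, thr)
    expect_equal(wf$amplitude_mv, sim_sw$y[ipk] - thr)
    expect_equal(wf$half_width_ms,
                 oracle_half_width(sim_sw$y, sim_sw$fs, ipk, thr),
                 tolerance = 1e-9)
    expect_gt(wf$amplitude_mv, 40)
    expect_lt(wf$half_width_ms, 3)
  }
})

test_that("threshold and amplitude are invariant to a baseline offset", {
  st <- detect_spikes(sim_sw)
  tpk <- st$peak_times_s[1]
  base <- ap_params(sim_sw, tpk)
  for (off in c(-5, -2, 2, 5)) {
    sh <- sim_sw
    sh$y <- sh$y + off
    wf <- ap_params(sh, tpk)
    expect_equal(wf$threshold_mv, base$threshold_mv + off, tolerance = 1e-9)
    expect_equal(wf$amplitude_mv, base$amplitude_mv, tolerance = 1e-9)
    expect_equal(wf$half_width_ms, base$half_width_ms, tolerance = 1e-9)
  }
})

test_that("half-width shrinks when the waveform is compressed in time", {
  # a synthetic lone AP; resampling the same shape on a faster clock must
  # scale the measured half-width down proportionally
  make_ap <- function(fs, squeeze) {
    t <- (0:round(0.05 * fs)) / fs
    y <- -65 + 95 * exp(-((t - 0.025) * squeeze / 0.001)^2)
    new_sweep(t, y, numeric(length(t)), fs)
  }
  widths <- vapply(c(1, 1.5, 2, 3), function(s) {
    sw <- make_ap(4e4, s)
    tpk <- detect_spikes(sw)$peak_times_s[1]
    ap_params(sw, tpk)$half_width_ms
  }, 0)
  expect_true(all(diff(widths) < 0))
  # approximate 3x scaling; the dV/dt-defined threshold shifts slightly
  # with the compression, so exact proportionality is not expected
  expect_equal(widths[1] / widths[4], 3, tolerance = 0.1)
})

test_that("ap_threshold errors without a 30 V/s upstroke", {
  fs <- 2e4
  t <- (0:9999) / fs
  sw <- new_sweep(t, 40 * sin(2 * pi * 2 * t), numeric(1e4), fs)
  expect_error(ap_threshold(sw, 0.125), "30 V/s")
})

test_that("the reference AP is the closest-to-5-ms first spike", {
  rec <- simulate_neuron(neuron_preset("WB", seed = 6), brief_step_protocol(),
                         protocol_name = "brief_10ms")
  sel <- select_ap_for_waveform(rec)
  proto <- rec$protocols$brief_10ms
  target <- (proto$step_start_ms + 5) / 1000
  # enumeration oracle: first spike of every suprathreshold sweep
  best_d <- Inf; best_amp <- NA
  for (k in order(proto$amplitudes_pA)) {
    pk <- oracle_detect_spikes(rec$sweeps$brief_10ms[[k]]$y,
                               rec$sweeps$brief_10ms[[k]]$fs)
    if (!length(pk)) next
    d <- abs(rec$sweeps$brief_10ms[[k]]$t[pk[1]] - target)
    if (d < best_d - 1e-12) { best_d <- d; best_amp <- proto$amplitudes_pA[k] }
  }
  expect_identical(sel$step_pa, best_amp)
  expect_equal(abs(sel$waveform$peak_time_s - target), best_d, tolerance = 1e-9)
  expect_s3_class(sel$waveform, "ap_waveform")
})

test_that("ties in the reference-AP rule go to the lower current", {
  # two sweeps with first spikes equidistant from the 5 ms target
  fs <- 2e4
  proto <- step_protocol(20, 10, c(100, 200), tail_ms = 30)
  n <- round(0.06 * fs)
  t <- (seq_len(n) - 1) / fs
  mk <- function(tpk) {
    y <- rep(-65, n)
    i0 <- round(tpk * fs) + 1
    up <- seq(-20, 0); dn <- seq(1, 20)
    y[i0 + up] <- -65 + 95 * (up + 20) / 20
    y[i0 + dn] <- 30 - 95 * dn / 20
    new_sweep(t, y, numeric(n), fs)
  }
  rec <- cell_recording("tie", "WT",
                        sweeps = list(brief_10ms = list(mk(0.024), mk(0.026))),
                        protocols = list(brief_10ms = proto))
  sel <- select_ap_for_waveform(rec)
  expect_identical(sel$step_pa, 100)
})

test_that("rheobase is the smallest suprathreshold brief step", {
  rec <- simulate_neuron(neuron_preset("RF", noise_sd = 0),
                         brief_step_protocol(), protocol_name = "brief_10ms")
  rb <- rheobase(rec)
  amps <- rec$protocols$brief_10ms$amplitudes_pA
  fires <- vapply(seq_along(amps), function(k)
    length(detect_spikes(rec$sweeps$brief_10ms[[k]])$peak_index) > 0, TRUE)
  expect_identical(rb, min(amps[fires]))
  expect_true(all(!fires[amps < rb]))
  # noise-free, the measured rheobase equals the independent ODE oracle
  expect_identical(rb, oracle_brief_rheobase(neuron_preset("RF", noise_sd = 0),
                                             amps))
})

test_that("rheobase is NA when no brief step fires", {
  rec <- simulate_neuron(neuron_preset("RF", noise_sd = 0),
                         brief_step_protocol(max_pa = 100),
                         protocol_name = "brief_10ms")
  expect_true(is.na(rheobase(rec)))
})
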