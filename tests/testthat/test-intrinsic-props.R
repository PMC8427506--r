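# One full simulated cell per class, shared across the tests in this file.
cells <- list(RF = simulate_cell(neuron_preset("RF", seed = 21), cell_id = "rf"),
              WB = simulate_cell(neuron_preset("WB", seed = 22), cell_id = "wb"),
              SB = simulate_cell(neuron_preset("SB", seed = 23), cell_id = "sb"))

test_that("RMP is the mean of the first 100 ms of the zero-current sweep", {
  for (rec in cells) {
    k <- which(rec$protocols$steps_1s$amplitudes_pA == 0)
    sw <- rec$sweeps$steps_1s[[k]]
    expect_equal(rmp(rec), oracle_rmp(sw$y, sw$fs), tolerance = 1e-12)
    expect_lt(rmp(rec), -60)
  }
})

test_that("f-I curve counts spikes inside the step window", {
  rec <- cells$WB
  fi <- fi_curve(rec)
  expect_identical(names(fi), as.character(seq(50, 300, 50)))
  proto <- rec$protocols$steps_1s
  win <- c(proto$step_start_ms, proto$step_start_ms + proto$step_dur_ms) / 1000
  for (a in c(100, 200, 300)) {
    k <- which(proto$amplitudes_pA == a)
    pk <- oracle_detect_spikes(rec$sweeps$steps_1s[[k]]$y,
                               rec$sweeps$steps_1s[[k]]$fs)
    tt <- rec$sweeps$steps_1s[[k]]$t[pk]
    expect_equal(unname(fi[as.character(a)]),
                 sum(tt >= win[1] & tt <= win[2]))
  }
  expect_true(all(diff(fi) >= 0))   # monotone over this range for this cell
  expect_warning(fi_curve(rec, steps_pa = c(150, 170)), "missing")
})

test_that("input resistance matches the analytic passive value", {
  # for the linear AdEx subthreshold membrane, steady state gives
  # R_in = 1 / (gL + a); jitter-free presets make this exact up to noise
  for (cls in names(cells)) {
    p <- neuron_preset(cls)
    r <- input_resistance(cells[[cls]])
    expect_equal(as.numeric(r), 1000 / (p$g_l_ns + p$a_ns), tolerance = 0.05)
    expect_identical(attr(r, "mode"), "multi")
    r1 <- input_resistance(cells[[cls]], mode = "single")
    expect_equal(as.numeric(r1), as.numeric(r), tolerance = 0.1)
    expect_identical(attr(r1, "steps_pa"), -100)
  }
})

test_that("input resistance equals the per-sample window oracle", {
  rec <- cells$RF
  proto <- rec$protocols$steps_1s
  dv <- numeric(0); used <- numeric(0)
  for (a in c(-150, -100, -50)) {
    k <- which(proto$amplitudes_pA == a)
    sw <- rec$sweeps$steps_1s[[k]]
    fs <- sw$fs
    ib <- round((proto$step_start_ms - 100) / 1000 * fs):round(proto$step_start_ms / 1000 * fs)
    se <- proto$step_start_ms + proto$step_dur_ms
    iss <- round((se - 200) / 1000 * fs):round(se / 1000 * fs)
    sb <- 0; for (i in ib) sb <- sb + sw$y[i]
    ss <- 0; for (i in iss) ss <- ss + sw$y[i]
    dv <- c(dv, ss / length(iss) - sb / length(ib))
    used <- c(used, a)
  }
  want <- 1000 * sum(dv * used) / sum(used^2)
  expect_equal(as.numeric(input_resistance(rec)), want, tolerance = 1e-9)
})

test_that("input resistance errors without hyperpolarizing sweeps", {
  rec <- simulate_neuron(neuron_preset("RF", seed = 30),
                         step_protocol(200, 1000, c(50, 100)))
  expect_error(input_resistance(rec), "hyperpolarizing")
})

test_that("mAHP is the post-train trough relative to pre-train baseline", {
  for (rec in cells) {
    sw <- rec$sweeps$mahp_train[[1]]
    fs <- sw$fs
    got <- mahp(rec)
    # oracle: baseline over the 100 ms before the first pulse; trough from
    # just after the last spike (last sample above 0 mV) to sweep end
    first_pulse <- which(sw$i_cmd != 0)[1]
    ib <- (first_pulse - round(0.1 * fs)):(first_pulse - 1)
    sb <- 0; for (i in ib) sb <- sb + sw$y[i]
    baseline <- sb / length(ib)
    last_spk <- max(which(sw$y > 0))
    tail <- sw$y[(last_spk + round(0.002 * fs)):length(sw$y)]
    expect_equal(got, min(tail) - baseline, tolerance = 0.1)
    expect_lt(got, 0)   # always a hyperpolarization after the 50 Hz train
  }
})

test_that("mAHP demands the mahp_train protocol and evoked spikes", {
  rec <- cells$RF
  rec$sweeps$mahp_train <- NULL
  expect_error(mahp(rec), "mahp_train")
})

test_that("ISI ratio follows the <3 spikes rule and the oracle", {
  rec <- cells$SB
  proto <- rec$protocols$steps_1s
  k <- which(proto$amplitudes_pA == 300)
  win <- c(proto$step_start_ms, proto$step_start_ms + proto$step_dur_ms) / 1000
  pk <- oracle_detect_spikes(rec$sweeps$steps_1s[[k]]$y,
                             rec$sweeps$steps_1s[[k]]$fs)
  tt <- rec$sweeps$steps_1s[[k]]$t[pk]
  tt <- tt[tt >= win[1] & tt <= win[2]]
  expect_gte(length(tt), 3)
  got <- isi_ratio(rec)
  expect_equal(got, oracle_isi_ratio(tt), tolerance = 1e-12)
  expect_gt(got, 0); expect_lte(got, 1)
  # bursting cells have a far smaller ratio than regular cells
  expect_lt(got, isi_ratio(cells$RF))
  # fewer than 3 spikes at 300 pA -> NA, not an error
  few <- rec
  flat <- few$sweeps$steps_1s[[k]]
  flat$y <- rep(-65, length(flat$y))
  few$sweeps$steps_1s[[k]] <- flat
  expect_true(is.na(isi_ratio(few)))
})

test_that("extract_features assembles the full per-cell row", {
  row <- extract_features(cells$WB)
  expect_identical(nrow(row), 1L)
  expect_identical(row$class, "WB")
  expect_identical(row$cell_id, "wb")
  expect_true(all(c("rmp_mv", "input_resistance_mohm", "mahp_mv",
                    "rheobase_pa", "threshold_mv", "amplitude_mv",
                    "half_width_ms", "isi_ratio", "max_rate_150pa_hz",
                    "fi_150pa_hz", "fi_300pa_hz") %in% names(row)))
  expect_equal(row$rmp_mv, rmp(cells$WB))
  expect_equal(row$max_rate_150pa_hz, unname(fi_curve(cells$WB)["150"]))
  expect_equal(row$rheobase_pa, rheobase(cells$WB))
  # QC-failed cells are refused
  bad <- cells$WB
  bad$qc_pass <- FALSE; bad$qc_reason <- "Rs"
  expect_error(extract_features(bad), "QC")
  co <- extract_features_cohort(list(cells$WB, bad, cells$RF))
  expect_identical(nrow(co), 2L)
  expect_identical(co$class, c("WB", "RF"))
})
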