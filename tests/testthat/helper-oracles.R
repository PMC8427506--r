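# Independent brute-force oracles used by the tests.  These re-implement
# the operational definitions directly from first principles (plain loops,
# no shared code with the package internals).

oracle_detect_spikes <- function(y, fs, level = 0, refractory_ms = 1,
                                 dvdt_v_per_s = 30, dvdt_window_ms = 5) {
  n <- length(y)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    if (y[i] <= level) next
    if (!(y[i] >= y[i - 1] && y[i] > y[i + 1])) next
    peaks <- c(peaks, i)
  }
  # refractory merge: within the window keep the taller peak
  w <- round(refractory_ms / 1000 * fs)
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && p - keep[length(keep)] < w) {
      if (y[p] > y[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  # upstroke validation: dV/dt >= threshold somewhere in the preceding window
  wd <- round(dvdt_window_ms / 1000 * fs)
  ok <- logical(length(keep))
  for (j in seq_along(keep)) {
    p <- keep[j]
    lo <- max(2, p - wd)
    for (i in lo:p) {
      d <- (y[min(i + 1, n)] - y[i - 1]) / (2 / fs) / 1000   # mV/ms == V/s
      if (!is.na(d) && d >= dvdt_v_per_s) { ok[j] <- TRUE; break }
    }
  }
  keep[ok]
}

oracle_threshold <- function(y, fs, ipk, dvdt_v_per_s = 30, window_ms = 5) {
  n <- length(y)
  lo <- max(2, ipk - round(window_ms / 1000 * fs))
  last <- NA_integer_
  for (i in lo:ipk) {
    d  <- (y[min(i + 1, n)] - y[i - 1]) / (2 / fs) / 1000
    dp <- if (i > lo && i - 2 >= 1)
      (y[i] - y[i - 2]) / (2 / fs) / 1000 else -Inf
    if (!is.na(d) && d >= dvdt_v_per_s && (is.na(dp) || dp < dvdt_v_per_s))
      last <- i
  }
  if (is.na(last)) stop("oracle: no upstroke")
  y[last]
}

oracle_half_width <- function(y, fs, ipk, thr) {
  half <- thr + (y[ipk] - thr) / 2
  # walk left from the peak to the last sub-half sample, interpolate
  i <- ipk
  while (i > 1 && y[i - 1] >= half) i <- i - 1
  if (i == 1) stop("oracle: no rising crossing")
  t_rise <- (i - 1) - 1 + (half - y[i - 1]) / (y[i] - y[i - 1])
  # walk right to the first sub-half sample, interpolate
  j <- ipk
  while (j < length(y) && y[j + 1] >= half) j <- j + 1
  if (j == length(y)) stop("oracle: no falling crossing")
  t_fall <- j - 1 + (y[j] - half) / (y[j] - y[j + 1])
  (t_fall - t_rise) / fs * 1000
}

# Burst segmentation oracle: split the spike train at ISIs >= 10 ms, then
# chunk each fast group left-to-right into bursts of at most 6 spikes;
# chunks of size 1 are singles, not bursts.
oracle_bursts <- function(times_s, isi_ms = 10, max_size = 6) {
  n <- length(times_s)
  if (n == 0) return(list(n_bursts = 0L, sizes = integer(0), n_single = 0L))
  fast <- diff(times_s) * 1000 < isi_ms
  grp <- cumsum(c(1L, !fast))
  sizes <- integer(0)
  n_single <- 0L
  for (g in split(seq_len(n), grp)) {
    s <- length(g)
    while (s > 0) {
      take <- min(s, max_size)
      if (take >= 2) sizes <- c(sizes, take) else n_single <- n_single + 1L
      s <- s - take
    }
  }
  list(n_bursts = length(sizes), sizes = sizes, n_single = n_single)
}

oracle_rmp <- function(y, fs, window_ms = 100) {
  s <- 0; k <- round(window_ms / 1000 * fs)
  for (i in 1:k) s <- s + y[i]
  s / k
}

oracle_isi_ratio <- function(times_s) {
  if (length(times_s) < 3) return(NA_real_)
  isi <- diff(times_s)
  min(isi) / mean(isi)
}

# Noise-free subthreshold AdEx integration (no reset): the smallest brief
# step that drives V past the escape cutoff is the analytic rheobase.
oracle_brief_rheobase <- function(p, amps, baseline_ms = 20, dur_ms = 10,
                                  tail_ms = 30, dt = 0.025) {
  for (amp in sort(amps)) {
    n <- round((baseline_ms + dur_ms + tail_ms) / dt)
    v <- p$e_l_mv; w <- 0; fired <- FALSE
    for (i in seq_len(n)) {
      t <- i * dt
      I <- if (t > baseline_ms && t <= baseline_ms + dur_ms) amp else 0
      ex <- p$g_l_ns * p$delta_t_mv *
        exp(min((v - p$v_t_mv) / p$delta_t_mv, 20))
      dv <- (-p$g_l_ns * (v - p$e_l_mv) + ex - w + I) / p$C_pf
      dw <- (p$a_ns * (v - p$e_l_mv) - w) / p$tau_w_ms
      v <- v + dt * dv; w <- w + dt * dw
      if (v >= p$v_cut_mv) { fired <- TRUE; break }
    }
    if (fired) return(amp)
  }
  NA_real_
}
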