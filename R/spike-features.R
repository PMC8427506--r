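#' Detect action potentials in a current-clamp sweep
#'
#' Spikes are local maxima above `peak_level_mv` separated by at least 1 ms
#' (peaks closer than that are merged, keeping the taller one), each
#' preceded within 5 ms by an upstroke whose centered-difference dV/dt
#' reaches 30 V/s.
#'
#' @param sweep A current-clamp [new_sweep()].
#' @param peak_level_mv Detection level (mV); peaks below it are ignored.
#' @return An object of class `spike_train`: `peak_times_s`,
#'   `peak_voltages_mv`, `peak_index`, ordered by time (possibly empty).
#' @export
detect_spikes <- function(sweep, peak_level_mv = .const$peak_level_mv) {
  stopifnot(inherits(sweep, "sweep"))
  if (sweep$mode != "current_clamp") stop("detect_spikes needs a current-clamp sweep")
  y <- sweep$y
  n <- length(y)
  cand <- which(y > peak_level_mv)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[y[cand] >= y[cand - 1] & y[cand] > y[cand + 1]]
  if (length(cand)) {
    # merge peaks within the refractory window, keep the taller
    ref_n <- .const$refractory_ms / 1000 * sweep$fs
    keep <- integer(0)
    cur <- cand[1]
    for (i in cand[-1]) {
      if (i - cur < ref_n) {
        if (y[i] > y[cur]) cur <- i
      } else {
        keep <- c(keep, cur)
        cur <- i
      }
    }
    keep <- c(keep, cur)
    # require a >= 30 V/s upstroke within the preceding 5 ms
    dvdt <- .dvdt_v_per_s(sweep)
    win <- round(0.005 * sweep$fs)
    ok <- vapply(keep, function(i) {
      lo <- max(2L, i - win)
      any(dvdt[lo:i] >= .const$dvdt_threshold_v_per_s, na.rm = TRUE)
    }, TRUE)
    keep <- keep[ok]
  } else keep <- integer(0)
  structure(list(peak_times_s = sweep$t[keep],
                 peak_voltages_mv = y[keep],
                 peak_index = keep, fs = sweep$fs),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes\n", length(x$peak_index)))
  invisible(x)
}

# Centered-difference first derivative in V/s (mV/ms numerically equal).
.dvdt_v_per_s <- function(sweep) {
  y <- sweep$y
  n <- length(y)
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2 * sweep$fs / 1000
  d
}

#' Action-potential threshold by the dV/dt criterion
#'
#' The threshold potential is the voltage at the last upward crossing of
#' dV/dt = 30 V/s that precedes the spike peak (searched over the 5 ms
#' before the peak; centered finite difference on the raw samples).
#'
#' @param sweep A current-clamp [new_sweep()].
#' @param peak_time_s Spike peak time (s).
#' @return Threshold potential (mV).
#' @export
ap_threshold <- function(sweep, peak_time_s) {
  ipk <- round(peak_time_s * sweep$fs) + 1L
  dvdt <- .dvdt_v_per_s(sweep)
  win <- round(0.005 * sweep$fs)
  lo <- max(2L, ipk - win)
  idx <- lo:ipk
  above <- dvdt[idx] >= .const$dvdt_threshold_v_per_s
  above[is.na(above)] <- FALSE
  # upward crossings: sample above threshold whose predecessor is below
  up <- which(above & !c(FALSE, above[-length(above)]))
  if (!length(up))
    stop("no 30 V/s upstroke within 5 ms before the peak")
  sweep$y[idx[up[length(up)]]]
}

#' Per-spike waveform parameters
#'
#' Amplitude is measured from the threshold to the peak; half-width is the
#' duration at half-maximal amplitude, with the level crossings located by
#' linear interpolation between samples.
#'
#' @inheritParams ap_threshold
#' @return An object of class `ap_waveform`: `threshold_mv`, `amplitude_mv`,
#'   `half_width_ms`, `peak_time_s`.
#' @export
ap_params <- function(sweep, peak_time_s) {
  ipk <- round(peak_time_s * sweep$fs) + 1L
  thr <- ap_threshold(sweep, peak_time_s)
  vpk <- sweep$y[ipk]
  amp <- vpk - thr
  if (amp <= 0) stop("non-positive amplitude")
  half <- thr + amp / 2
  y <- sweep$y
  # rising crossing: last upward crossing of the half level before the peak
  pre <- max(1L, ipk - round(0.005 * sweep$fs)):ipk
  seg <- y[pre]
  cross <- which(seg[-length(seg)] < half & seg[-1] >= half)
  if (!length(cross)) stop("rising half-amplitude crossing not found")
  ri <- pre[cross[length(cross)]]
  t_rise <- sweep$t[ri] + (half - y[ri]) / (y[ri + 1] - y[ri]) / sweep$fs
  # falling crossing: first downward crossing after the peak
  post <- ipk:min(length(y), ipk + round(0.01 * sweep$fs))
  seg <- y[post]
  cross <- which(seg[-length(seg)] >= half & seg[-1] < half)
  if (!length(cross) || post[cross[1]] + 1L > length(y))
    stop("falling half-amplitude crossing not found (sweep truncated?)")
  fj <- post[cross[1]]
  t_fall <- sweep$t[fj] + (y[fj] - half) / (y[fj] - y[fj + 1]) / sweep$fs
  structure(list(threshold_mv = thr, amplitude_mv = amp,
                 half_width_ms = (t_fall - t_rise) * 1000,
                 peak_time_s = sweep$t[ipk]),
            class = "ap_waveform")
}

#' Select the reference AP for waveform analysis
#'
#' Among the first APs of every suprathreshold sweep of the 10-ms
#' brief-pulse protocol, selects the one whose peak is closest to 5 ms
#' after the start of the current injection.  The second AP of a doublet is
#' never analyzed.  Ties are broken toward the lower-current sweep, then
#' the earlier sweep.
#'
#' @param rec A [cell_recording()] with a `brief_10ms` protocol.
#' @return A list: `waveform` (an `ap_waveform`), `step_pa`, `sweep_index`.
#' @export
select_ap_for_waveform <- function(rec) {
  sweeps <- .get_sweeps(rec, "brief_10ms")
  proto <- rec$protocols$brief_10ms
  target <- (proto$step_start_ms + 5) / 1000
  best <- NULL
  for (k in order(proto$amplitudes_pA)) {
    st <- detect_spikes(sweeps[[k]])
    if (!length(st$peak_index)) next
    tpk <- st$peak_times_s[1]
    d <- abs(tpk - target)
    if (is.null(best) || d < best$d - 1e-12) {
      best <- list(d = d, k = k, tpk = tpk)
    }
  }
  if (is.null(best)) stop("no spike in any brief-pulse sweep")
  list(waveform = ap_params(sweeps[[best$k]], best$tpk),
       step_pa = proto$amplitudes_pA[best$k], sweep_index = best$k)
}

#' Rheobase from the brief-pulse series
#'
#' The smallest 10-ms step amplitude whose sweep contains at least one
#' spike; `NA` when no sweep is suprathreshold (such cells are excluded
#' from rheobase summaries).
#'
#' @param rec A [cell_recording()] with a `brief_10ms` protocol.
#' @return Rheobase (pA) or `NA`.
#' @export
rheobase <- function(rec) {
  sweeps <- .get_sweeps(rec, "brief_10ms")
  amps <- rec$protocols$brief_10ms$amplitudes_pA
  for (k in order(amps)) {
    if (length(detect_spikes(sweeps[[k]])$peak_index)) return(amps[k])
  }
  NA_real_
}
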