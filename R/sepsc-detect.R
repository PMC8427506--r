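#' Biexponential detection template
#'
#' Unit-peak template `exp(-t/decay) - exp(-t/rise)`, normalized so its
#' maximum is 1, used by the sliding-template event detector.
#'
#' @param rise_tau_ms,decay_tau_ms Time constants (ms); decay must exceed
#'   rise.
#' @param length_ms Template length (ms).
#' @return An object of class `sepsc_template`.
#' @export
sepsc_template <- function(rise_tau_ms = 1.5, decay_tau_ms = 6, length_ms = 30) {
  if (decay_tau_ms <= rise_tau_ms) stop("decay_tau_ms must exceed rise_tau_ms")
  structure(list(rise_tau_ms = rise_tau_ms, decay_tau_ms = decay_tau_ms,
                 length_ms = length_ms), class = "sepsc_template")
}

#' Detect sEPSC events by sliding-template matching
#'
#' At every lag the template is fitted to the trace by least squares with a
#' free scale and offset (closed form).  The detection statistic is the
#' fitted scale divided by the standard error of the fit residuals; lags
#' where it exceeds `criterion` with a negative (inward) scale are
#' candidate events.  Candidates are accepted by matched pursuit: per pass,
#' the strongest candidates are taken (suppressing weaker candidates within
#' one template length, which are decay-tail echoes of the same event), the
#' fitted template is subtracted, and the residual is rescanned so that
#' overlapping events separate cleanly.  Remaining detections closer than
#' the template rise time are merged (keeping the strongest).
#'
#' @param sweep A voltage-clamp [new_sweep()] (y in pA).
#' @param template A [sepsc_template()].
#' @param criterion Detection threshold on scale / SE of fit (default 3).
#' @param max_pass Maximum number of detect-subtract passes.
#' @return An object of class `event_list`: `onset_times_s`,
#'   `amplitudes_pa` (positive magnitudes), `iei_ms` and the trace
#'   duration.
#' @export
detect_events <- function(sweep, template = sepsc_template(), criterion = 3.0,
                          max_pass = 6L) {
  stopifnot(inherits(sweep, "sweep"), inherits(template, "sepsc_template"))
  if (sweep$mode != "voltage_clamp")
    stop("detect_events needs a voltage-clamp sweep")
  fs <- sweep$fs
  w <- .biexp_kernel(template$rise_tau_ms, template$decay_tau_ms, fs,
                     template$length_ms)
  y <- sweep$y
  L <- length(w)
  n <- length(y)
  if (n < L) stop("trace shorter than the template")
  onsets <- integer(0)
  amps <- numeric(0)
  for (pass in seq_len(max_pass)) {
    cand <- .template_scan(y, w, criterion)
    if (!length(cand$onset)) break
    # strongest first; suppress weaker candidates within one template
    # length of an acceptance (this pass) -- decay-tail echoes
    ord <- order(cand$crit)
    taken <- integer(0)
    for (j in ord) {
      k <- cand$onset[j]
      if (length(taken) && any(abs(taken - k) < L)) next
      taken <- c(taken, k)
      onsets <- c(onsets, k)
      amps <- c(amps, cand$amp[j])
      idx <- k:min(k + L - 1L, n)
      y[idx] <- y[idx] + cand$amp[j] * w[seq_along(idx)]
    }
    if (!length(taken)) break
  }
  if (length(onsets)) {
    ord <- order(onsets)
    onsets <- onsets[ord]
    amps <- amps[ord]
    # merge events closer than the template rise time (keep the stronger)
    min_sep <- round(template$rise_tau_ms / 1000 * fs)
    keep <- 1L
    for (i in seq_along(onsets)[-1]) {
      if (onsets[i] - onsets[keep[length(keep)]] < min_sep) {
        if (amps[i] > amps[keep[length(keep)]])
          keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    onsets <- onsets[keep]
    amps <- amps[keep]
  }
  structure(list(onset_times_s = sweep$t[onsets],
                 amplitudes_pa = amps,
                 iei_ms = diff(sweep$t[onsets]) * 1000,
                 duration_s = n / fs),
            class = "event_list")
}

# One sliding least-squares template scan.  Returns the best lag of every
# contiguous run of lags whose criterion (scale / SE of fit) is at or below
# -criterion, with the fitted inward amplitude.
.template_scan <- function(y, w, criterion) {
  L <- length(w)
  n <- length(y)
  sw_ <- sum(w)
  sww <- sum(w * w)
  # running sums over each length-L window starting at lag k
  cy <- cumsum(c(0, y))
  cyy <- cumsum(c(0, y * y))
  nlag <- n - L + 1L
  sy <- cy[(L + 1):(n + 1)] - cy[1:nlag]
  syy <- cyy[(L + 1):(n + 1)] - cyy[1:nlag]
  # cross-correlation sum(w_j * y_{k+j-1}) via one-sided convolution filter
  f <- stats::filter(y, rev(w), method = "convolution", sides = 1)
  swy <- as.numeric(f[L:n])
  denom <- L * sww - sw_^2
  scale <- (L * swy - sw_ * sy) / denom
  offset <- (sy - scale * sw_) / L
  sse <- syy - scale * swy - offset * sy
  sse[sse < 0] <- 0
  se <- sqrt(sse / (L - 1))
  crit <- scale / pmax(se, .Machine$double.eps)
  hits <- which(crit <= -criterion)          # inward events: negative scale
  onset <- integer(0)
  amp <- numeric(0)
  cr <- numeric(0)
  if (length(hits)) {
    run_id <- cumsum(c(1L, diff(hits) > 1L))
    for (r in split(hits, run_id)) {
      k <- r[which.min(crit[r])]
      onset <- c(onset, k)
      amp <- c(amp, -scale[k])
      cr <- c(cr, crit[k])
    }
  }
  list(onset = onset, amp = amp, crit = cr)
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events over %.1f s\n",
              length(x$onset_times_s), x$duration_s))
  invisible(x)
}

#' Amplitude-gate an event list
#'
#' Keeps events with amplitudes between 6 and 100 pA inclusive (amplitudes
#' strictly below 6 or strictly above 100 pA are not considered) and
#' recomputes inter-event intervals on the survivors.  Idempotent.
#'
#' @param ev An [detect_events()] result.
#' @param min_pa,max_pa Gate bounds (pA), inclusive.
#' @return A gated `event_list`.
#' @export
gate_events <- function(ev, min_pa = .const$gate_min_pa,
                        max_pa = .const$gate_max_pa) {
  keep <- ev$amplitudes_pa >= min_pa & ev$amplitudes_pa <= max_pa
  ev$onset_times_s <- ev$onset_times_s[keep]
  ev$amplitudes_pa <- ev$amplitudes_pa[keep]
  ev$iei_ms <- diff(ev$onset_times_s) * 1000
  ev
}

#' Mean amplitude and event frequency
#'
#' @param ev A gated `event_list`.
#' @param duration_s Recording duration (s); defaults to the trace length
#'   stored in the event list.
#' @return A list: `mean_amplitude_pa` (NA when no events) and
#'   `frequency_hz` (count / duration).
#' @export
summarize_events <- function(ev, duration_s = ev$duration_s) {
  stopifnot(duration_s > 0)
  n <- length(ev$amplitudes_pa)
  list(mean_amplitude_pa = if (n) mean(ev$amplitudes_pa) else NA_real_,
       frequency_hz = n / duration_s)
}

#' Binned cumulative distribution
#'
#' Amplitudes are binned every 1 pA between 6 and 80 pA; inter-event
#' intervals every 10 ms between 0 and 1,000 ms.  The value at each right
#' edge is the cumulative fraction of the in-range values at or below it,
#' so the final value is 1 over the binned support.
#'
#' @param values Gated amplitudes (pA) or IEIs (ms).
#' @param kind `"amplitude"` or `"iei"`.
#' @return An object of class `binned_cdf`: `edges`, `cumfrac`, `n`
#'   (number of in-range values), `kind`.
#' @export
binned_cdf <- function(values, kind = c("amplitude", "iei")) {
  kind <- match.arg(kind)
  edges <- if (kind == "amplitude") .const$amp_bin_edges_pa else .const$iei_bin_edges_ms
  lo <- edges[1]
  hi <- edges[length(edges)]
  v <- values[values >= lo & values <= hi]
  n <- length(v)
  cumfrac <- if (n) vapply(edges, function(e) mean(v <= e), 0) else
    rep(NA_real_, length(edges))
  structure(list(edges = edges, cumfrac = cumfrac, n = n, kind = kind),
            class = "binned_cdf")
}

#' Match detected events to ground truth
#'
#' Greedy one-to-one matching of detected onsets to true event times within
#' a tolerance, for scoring a detector against a simulated trace.
#'
#' @param ev An `event_list`.
#' @param truth A [sepsc_ground_truth()].
#' @param tol_ms Matching tolerance (ms).
#' @return A list: `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
score_detection <- function(ev, truth, tol_ms = 5) {
  det <- ev$onset_times_s
  tru <- truth$event_times_s
  used <- logical(length(det))
  matched <- 0L
  for (t0 in tru) {
    d <- abs(det - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_ms / 1000) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_true = length(tru), n_detected = length(det), n_matched = matched,
       recall = if (length(tru)) matched / length(tru) else NA_real_,
       precision = if (length(det)) matched / length(det) else NA_real_)
}
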