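#' Segment a spike train into bursts
#'
#' A burst is a run of 2 to 6 APs whose internal inter-spike intervals are
#' all shorter than 10 ms (instantaneous frequency above 100 Hz).  Spikes
#' are grouped greedily left to right: consecutive spikes are joined while
#' the ISI stays below 10 ms and the group holds fewer than 6 spikes;
#' groups of one are single spikes, not bursts.
#'
#' @param train A [detect_spikes()] result (or any object with sorted
#'   `peak_times_s`).
#' @return A data frame with one row per burst: `first_spike`, `n_spikes`,
#'   `onset_s`, `intra_burst_freq_hz`; zero rows when there is no burst.
#'   The number of ungrouped single spikes is attached as attribute
#'   `"n_single"`.
#' @export
segment_bursts <- function(train) {
  tt <- train$peak_times_s
  groups <- list()
  if (length(tt)) {
    start <- 1L
    size <- 1L
    for (i in seq_along(tt)[-1]) {
      isi_ms <- (tt[i] - tt[i - 1]) * 1000
      if (isi_ms < .const$burst_isi_ms && size < .const$burst_max_size) {
        size <- size + 1L
      } else {
        groups[[length(groups) + 1L]] <- c(start, size)
        start <- i
        size <- 1L
      }
    }
    groups[[length(groups) + 1L]] <- c(start, size)
  }
  sizes <- vapply(groups, `[`, 0, 2)
  bursty <- which(sizes >= 2)
  out <- data.frame(
    first_spike = vapply(groups[bursty], `[`, 0, 1),
    n_spikes = sizes[bursty],
    onset_s = if (length(bursty)) tt[vapply(groups[bursty], `[`, 0, 1)] else numeric(0),
    intra_burst_freq_hz = vapply(groups[bursty], function(g) {
      span <- tt[g[1] + g[2] - 1] - tt[g[1]]
      (g[2] - 1) / span
    }, 0))
  attr(out, "n_single") <- sum(sizes == 1)
  out
}

#' Classify one suprathreshold sweep by its burst count
#'
#' Two or more bursts make the sweep strong bursting (SB), exactly one
#' burst weak bursting (WB), none regular firing (RF).  A sweep with no
#' spikes is uninformative (`NA`).
#'
#' @param bursts A [segment_bursts()] result.
#' @param n_single Number of single (non-burst) spikes in the sweep;
#'   defaults to the count attached by [segment_bursts()].
#' @return `"SB"`, `"WB"`, `"RF"` or `NA_character_`.
#' @export
classify_sweep <- function(bursts, n_single = attr(bursts, "n_single")) {
  nb <- nrow(bursts)
  if (nb == 0 && (is.null(n_single) || n_single == 0)) return(NA_character_)
  if (nb >= 2) "SB" else if (nb == 1) "WB" else "RF"
}

#' Classify a cell as SB, WB or RF
#'
#' The cell label is the sweep label at the reference sweep of the 1-s step
#' series: the lowest current step of at least 100 pA that elicited at
#' least 3 spikes (for typical cells this lands on the 150 pA step).
#' Per-sweep labels for all suprathreshold steps are retained as evidence.
#'
#' @param rec A [cell_recording()] with a `steps_1s` protocol.
#' @param min_reference_pa Smallest step amplitude eligible as reference.
#' @param min_spikes Minimum spike count for an informative sweep.
#' @return An object of class `class_label`: `label`, `reference_step_pa`,
#'   `n_bursts_at_reference`, and an `evidence` data frame (step_pa,
#'   n_spikes, n_bursts, label).  `label` is `NA` when no sweep is
#'   informative (such cells are excluded from distribution tables).
#' @export
classify_cell <- function(rec, min_reference_pa = 100, min_spikes = 3) {
  sweeps <- .get_sweeps(rec, "steps_1s")
  proto <- rec$protocols$steps_1s
  amps <- proto$amplitudes_pA
  ev <- data.frame(step_pa = amps, n_spikes = NA_integer_,
                   n_bursts = NA_integer_, label = NA_character_)
  win <- c(proto$step_start_ms, proto$step_start_ms + proto$step_dur_ms) / 1000
  for (k in seq_along(amps)) {
    if (amps[k] <= 0) next
    st <- detect_spikes(sweeps[[k]])
    inwin <- st$peak_times_s >= win[1] & st$peak_times_s <= win[2]
    st$peak_times_s <- st$peak_times_s[inwin]
    st$peak_index <- st$peak_index[inwin]
    b <- segment_bursts(st)
    ev$n_spikes[k] <- length(st$peak_times_s)
    ev$n_bursts[k] <- nrow(b)
    ev$label[k] <- classify_sweep(b)
  }
  ref <- which(amps >= min_reference_pa & !is.na(ev$n_spikes) &
                 ev$n_spikes >= min_spikes)
  ref <- ref[order(amps[ref])][1]
  if (is.na(ref)) {
    label <- NA_character_
    ref_pa <- NA_real_
    nb <- NA_integer_
  } else {
    label <- ev$label[ref]
    ref_pa <- amps[ref]
    nb <- ev$n_bursts[ref]
  }
  structure(list(label = label, reference_step_pa = ref_pa,
                 n_bursts_at_reference = nb, evidence = ev,
                 cell_id = rec$cell_id, genotype = rec$genotype),
            class = "class_label")
}

#' @export
print.class_label <- function(x, ...) {
  cat(sprintf("<class_label> %s: %s (reference %g pA, %s bursts)\n",
              x$cell_id, x$label, x$reference_step_pa,
              format(x$n_bursts_at_reference)))
  invisible(x)
}
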