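---
title: "Methods: simulation model, operational definitions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation model, operational definitions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subispike)
```

`subispike` analyzes whole-cell current-clamp recordings of subicular
pyramidal neurons — spike detection, action-potential waveform
measurements, burst-based firing-class assignment (strong bursting,
weak bursting, regular firing), intrinsic membrane properties, sEPSC
event detection in voltage clamp, and the group statistics used to
compare wild-type and mutant cohorts. Because raw recordings of this
kind are rarely shared, the package also contains a calibrated
simulator that generates labeled synthetic cohorts; every analysis
routine is validated against these.

This vignette documents the generative model, the operational
definitions used by the measurements, and the main design decisions.

## The neuron model

Cells are simulated with the adaptive exponential integrate-and-fire
(AdEx) model in physical units:

$$C \frac{dV}{dt} = -g_L (V - E_L) + g_L \Delta_T e^{(V - V_T)/\Delta_T} - w + I(t) + \eta(t)$$
$$\tau_w \frac{dw}{dt} = a (V - E_L) - w$$

with the usual reset: when $V$ crosses the cutoff (−30 mV), $V \to V_r$
and $w \to w + b$, followed by a 2.5 ms refractory clamp. $\eta(t)$ is
Ornstein–Uhlenbeck current noise (correlation time 5 ms, SD 5 pA by
default). Integration is forward Euler at 0.025 ms (40 kHz), implemented
in C++.

The integrate-and-fire reset truncates the action potential, so a
stereotyped waveform (half-cosine rise to +30 mV over 0.6 ms, half-cosine
fall to $V_r$ over 1.4 ms) is pasted at each spike time. This makes
threshold, amplitude and half-width measurable on the trace with the same
code paths that would process real data.

### Firing-class presets

The three firing phenotypes are produced purely by the reset geometry and
the adaptation parameters (`neuron_preset()`):

| preset | mechanism |
|---|---|
| `RF` | reset below threshold ($V_r = -60$ mV), slow strong adaptation: trains of single APs |
| `WB` | reset above threshold with a large spike-triggered increment $b$: one burst at stimulus onset (the adaptation current is still low), then tonic single spikes |
| `SB` | reset well above threshold, low $V_T$, large $b$: every escape from quiescence re-ignites into a 2–3 spike burst that terminates itself, and bursts recur as $w$ decays |

The parameter values were calibrated once, against an independent
ISI-scan oracle, so that each preset robustly expresses its class across
the cell-to-cell jitter used by `make_cohort()` (5% CV on $C$ and $g_L$)
and across genotype offsets; they are fixed constants of the package.

```{r}
p <- neuron_preset("SB")
p
rec <- simulate_cell(p, cell_id = "demo", genotype = "WT")
classify_cell(rec)
```

### What the generator does and does not emulate

Emulated: class-specific burst structure, monotone f–I curves, passive
input resistance $1/(g_L + a)$, brief-pulse rheobase, a resting potential
at $E_L$, realistic current noise, and a post-train
afterhyperpolarization.

Not emulated:

* **mAHP magnitude.** The 50 Hz / 3 s / 3,000 pA pulse train evokes
  ~150 spikes; the AdEx adaptation current accumulates linearly
  ($b$ per spike, no saturation) to several hundred pA, so the simulated
  afterhyperpolarization is tens of millivolts — an order of magnitude
  larger than physiological mAHPs. The *measurement* (`mahp()`) is exact
  for the trace it is given; only the simulated magnitude is exaggerated.
  Class and genotype contrasts remain meaningful in sign and ordering.
* Channel-level detail, dendritic structure, synaptic conductances in
  current clamp, electrode artifacts, slow drift.
* sEPSC traces are rendered directly in voltage clamp as biexponential
  events (rise 1.5 ms, decay 6 ms) on Gaussian baseline noise, not via
  the membrane model.

## Operational definitions

All thresholds live in one internal constant table and are used
consistently across modules:

* **Spike**: local maximum above 0 mV, peaks closer than 1 ms merged
  (taller kept), validated by a centered-difference dV/dt reaching
  30 V/s within the preceding 5 ms.
* **AP threshold**: voltage at the last upward crossing of
  dV/dt = 30 V/s before the peak. **Amplitude**: peak minus threshold.
  **Half-width**: width at half amplitude, crossings located by linear
  interpolation between samples.
* **Burst**: 2–6 APs whose internal ISIs are all < 10 ms, grouped
  greedily left-to-right; a run of 7 fast spikes therefore yields a
  6-spike burst plus a single.
* **Class label**: at the reference sweep — the lowest 1-s step of at
  least 100 pA that elicited at least 3 spikes — ≥ 2 bursts ⇒ SB,
  1 ⇒ WB, 0 ⇒ RF. Cells with no informative sweep are unclassified and
  excluded from distribution tables.
* **RMP**: mean of the first 100 ms of the zero-current sweep.
  **Input resistance**: through-origin regression of steady-state
  deflections on the −150/−100/−50 pA steps. **Rheobase**: smallest
  10-ms step (10 pA increments) that fires. **Reference AP** for
  waveform statistics: the first spike, across the brief-pulse series,
  whose peak is closest to 5 ms after pulse onset (ties to the lower
  current). **ISI ratio**: min/mean ISI at 300 pA; `NA` below 3 spikes.
  **mAHP**: post-train trough minus the 100 ms pre-train baseline.
* **QC**: cells with series resistance > 30 MΩ or RMP more depolarized
  than −60 mV are excluded before any group statistic (both bounds
  strict).
* **sEPSC detection**: sliding biexponential template (rise 1.5 ms,
  decay 6 ms, 30 ms long) fitted by least squares with free scale and
  offset at every lag; detection criterion 3.0 on scale/SE. Accepted
  events are subtracted and the residual rescanned (matched pursuit), so
  overlapping events separate and decay tails do not echo. Amplitudes
  are gated to 6–100 pA inclusive; cumulative distributions are binned
  at 1 pA (6–80 pA) and 10 ms (0–1,000 ms).

## Statistics

* `ttest_unpaired()`: classical pooled-variance two-sided t.
* `chisq_distribution()`: per-class 2×2 Pearson chi-square (class vs
  rest by genotype), no continuity correction by default.
* `anova2_rm()`: hand-computed split-plot (mixed) ANOVA — genotype
  tested against subjects-within-genotype, step and interaction against
  the subject-by-step residual; verified against
  `aov(y ~ g*s + Error(subj/s))` and calibrated to a 5% type-I rate on
  null cohorts. Post hoc: per-step pooled t with Bonferroni correction.
* `ks_binned()`: two-sample KS on the binned CDFs with the asymptotic
  p-value at effective $n_1 n_2/(n_1+n_2)$.

## Design decisions

* **Pipeline as functions, not a shell tool.** `run_pipeline()` with a
  `pipeline_config()` replaces a CLI: it is scriptable, testable and
  composable from R, writes the same artifact set (feature/label/stat
  CSVs plus a JSON manifest with a config hash and QC exclusions), and
  `Rscript` gives a one-command entry point where needed.
* **Plain-text I/O.** The `sweep_csv` format (long CSV + JSON sidecar
  with sampling rate, mode and units) keeps fixtures human-readable and
  dependency-free; units are normalized at ingestion so downstream code
  is unit-free. Binary acquisition formats are declared but not bundled.
* **Problem sizes** in examples and tests (cohorts of 6–60 cells, 120-s
  sEPSC traces) are the package's own choice, balancing statistical
  power against runtime.

## Reproducibility

Every simulation is deterministic given its seed; `run_pipeline()` runs
are byte-identical for equal configs. `scripts/acceptance.R --seed 1
--out report.json` re-computes the headline quantities (classifier
recovery, detection precision/recall, statistical calibration) into a
JSON report.
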