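Package: subispike
Title: Classification and Intrinsic-Property Analysis of Subicular Pyramidal Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the electrophysiological characterization of subicular
    pyramidal neurons from whole-cell patch-clamp sweeps: burst-based
    classification into regular-firing, weak-bursting and strong-bursting
    cells, extraction of intrinsic membrane properties (f-I curves, input
    resistance, resting membrane potential, medium afterhyperpolarization,
    rheobase, action-potential waveform parameters, interspike-interval
    ratio), sliding-template detection of spontaneous excitatory postsynaptic
    currents, and the associated group-comparison statistics (Student t,
    chi-square, mixed-design repeated-measures ANOVA with Bonferroni post hoc
    tests, binned two-sample Kolmogorov-Smirnov). Includes an adaptive
    exponential integrate-and-fire simulator that generates current-clamp and
    voltage-clamp recordings with known ground truth, so the whole pipeline is
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
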