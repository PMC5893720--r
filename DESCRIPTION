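Package: ephyskit
Title: Analysis and Simulation of Patch-Clamp Electrophysiology Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for cellular electrophysiology: sweep-based
    time-series containers with append-only provenance notes, spontaneous
    synaptic event detection (sliding-baseline threshold and template
    matching), spike detection and spike-train statistics (raster, FI
    relation, ISI histogram, PSTH), windowed statistics including rise times
    and Spearman stability selection, multiple-probability fluctuation
    analysis (MPFA) with h-statistic variance errors, weighted nonlinear
    fitting of multi-exponential synaptic waveforms and the multinomial
    variance-mean relation, and generative simulators for stochastic
    multinomial quantal release, the R*P short-term plasticity model, and
    conductance-driven integrate-and-fire neurons. Includes seeded synthetic
    fixture generators so every analysis stage is testable against known
    ground truth, plus a plain-text data-folder store and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
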