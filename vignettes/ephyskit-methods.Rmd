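---
title: "Models and methods in ephyskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ephyskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ephyskit)
```

`ephyskit` packages the quantitative core of a sweep-based patch-clamp
workflow: containers with provenance, event and spike detection, windowed
statistics, curve fitting, multiple-probability fluctuation analysis (MPFA),
and three generative simulators. This vignette explains the models, the
conventions, and the design choices a user should know before trusting the
numbers.

## Time and container conventions

All times are milliseconds; sample `i` (0-based) of a trace sits at
`t_start + i·dt`, and analysis windows `[xbgn, xend]` are closed on sample
times. 50 kHz sampling corresponds to `dt = 0.02`. Units are carried as
strings (`pA`, `mV`, `nS`); `pointwise_combine()` updates them in the one
physically common case (pA ÷ mV → nS, exact since pA/mV = nS) and otherwise
concatenates them — there is no general unit algebra. Every mutating
operation appends exactly one provenance note (timestamp, operation,
parameters), so a processed trace documents its own history; the plain-text
data-folder store (`write_folder()`/`read_folder()`) persists samples at 17
significant digits, which round-trips IEEE doubles exactly.

Filters (binomial smoothing, the Gaussian low-pass) pad by reflection at the
edges. Reflection avoids the endpoint bias that zero-padding would inject
into baseline windows at the very start of a sweep; the first and last few
samples are still less trustworthy than interior ones. The Gaussian
low-pass places its −3 dB point at the requested corner frequency
(`σ_t = √(ln 2)/(2π f_c)`), has unit DC gain and zero phase.

## Event detection

`detect_threshold()` implements the sliding-baseline detector: at sample
time `t` the baseline is the mean over `[t − offset − b, t − offset]`
(default `b` = 5 ms, `offset` = 2.5 ms), and a crossing fires when the
sample deviates beyond the level — in absolute units, or in multiples of
the rolling SD computed over the same baseline window. After a crossing the
peak is the polarity extremum within the peak window; "no turning point
inside the window" counts as a failed peak search and, with
`require_peak = TRUE`, the event is kept but marked rejected, mirroring how
automatic rejections are reviewed rather than silently dropped.

The onset has no canonical definition, so the rule here is explicit and
configurable: the last pre-crossing sample at which the signal is still
within `onset_frac` (default 10%) of the event amplitude from baseline.
Scanning resumes `min_sep` after the peak; events closer than that merge
into the earlier one.

`detect_template()` is the matched-filter alternative: at each offset the
data segment is fit to `s·w + c` in closed form, and the detection
criterion is `DC = s/σ_res` with `σ_res = √(SSE/(K−1))` (the `K−1`
denominator follows the classic sliding-template formulation; an
`ε = 10⁻¹²` guard keeps `DC` finite on perfect matches). Because `c`
absorbs any additive constant, `DC` is offset-invariant — a property the
tests assert numerically. Templates are normalized to baseline 0 and peak
+1, so negative-going events produce negative criterion excursions and the
usual working levels are −3 to −4.

## Windowed statistics and stability

`rise_time()` finds the polarity extremum in a peak window, then the last
linear-interpolated crossings of the `p_low` and `p_high` fractions before
it. On waveforms that have not reached their plateau the measured fractions
refer to the windowed peak, not the asymptote — the closed form
`rt = τ·ln 9` for a single-exponential rise is recovered only when the
peak window sits on the plateau. `rt_slope()` is the chord slope between
the two crossings; it scales with amplitude while the rise time does not,
which is why it separates fast from slow events robustly.

`stability_range()` screens for drift by Spearman rank correlation against
sweep order. The scan convention (a documented choice; only the test
itself is classical) is: extend a suffix window `[i, n]`, increasing `i`
from the start, and return the first window whose two-sided `p ≥ α`
(default α = 0.05, minimum length 10). The suffix scan matches the common
situation of an unstable early period followed by a stable tail; data that
become unstable at the end will simply fail, which is intended.

## MPFA statistics and the variance error

For each probability condition, `mpfa_stats()` reports the mean peak
current `I_p`, the unbiased peak variance minus the background-window
variance (subtraction on by default and switchable — backgrounds are
measured in the peak window reflected about the midpoint of the
pre-stimulus baseline window, so they share the measurement bandwidth), and
the standard error of the variance from h-statistics. The estimator is the
unbiased plug-in for

    Var(s²) = (μ₄ − σ⁴·(n−3)/(n−1)) / n

with μ₄ estimated by the unbiased fourth central moment
`n[(n²−2n+3)m₄ − 3(2n−3)m₂²] / ((n−1)(n−2)(n−3))` and σ⁴ by its unbiased
polykay. Both are exact-unbiasedness-verified in the test suite against
Gaussian closed forms and a 10⁴-resample bootstrap (agreement within 15% on
n = 150 fixtures). On degenerate (near-constant) samples the estimator can
come out non-positive; it then falls back to the Gaussian form
`2s⁴/(n−1)` with a warning, and a tiny floor keeps fit weights finite.

`fit_multinomial()` fits the variance–mean relation with both quantal CVs
held fixed (estimating CVs and `N` jointly from five points is hopelessly
ill-conditioned) and weights `1/var_err²`. With the CVs fixed the model is
linear in `(Q_p', 1/N)`, so the closed-form weighted parabola solve supplies
the start values — and serves as the independent oracle in the tests —
while the Levenberg–Marquardt fit with its analytic Jacobian produces the
reported estimates and standard errors.

## The quantal release simulator

`simulate_quantal()` follows the multinomial model literally: per trial and
site, release occurs when a uniform draw falls below `P`; each success
contributes its site amplitude perturbed by the within-site CV, placed at
the stimulus time plus Gaussian latency jitter, shaped by the unit-peak
synaptic waveform. The default configuration is the 5-site study condition
used throughout the package: `N = 5`, `Q_p = −20 pA`, `P = 0.5`,
`CV_QS = 0.3`, `σ_QL = 0.08 ms`, `CV_QII = 0.3`, 150 trials, 50 kHz, 12-ms
sweeps with the stimulus at 2 ms, waveform `τ_r = 0.116 ms`, `n = 1`,
biexponential decay 0.36/2.034 ms with amplitude split 86.72/13.28.

Site amplitude sets are drawn repeatedly until the sample mean *and* sample
CV are within the stated precision (default 1%) of their targets — whole
sets are redrawn, not adjusted, and draws whose sign contradicts `Q_p` are
resampled (the Gaussian tail would otherwise produce sign-flipped sites at
large CV). One site set is shared across all probability conditions of an
MPFA run, as a repeated-measures experiment on one synapse implies.

Two measurement effects matter when interpreting fits of simulated data.
First, the nominal latency-to-amplitude conversion: a latency SD of
0.08 ms induces an amplitude CV of about 0.19 at the waveform peak for
these kinetics (the simulator reports the induced value as
`cv_ql_induced`); the composite within-site CV used when fixing the fit is
`CV_QI = √(CV_QS² + CV_QL²) = 0.36` with the conventional `CV_QL = 0.2`.
Second, measuring every trial in a fixed 0.1-ms window centered on the
grand-average peak attenuates jittered single-quantum contributions, so the
fitted `|Q_p|` comes out 10–20% below the generating 20 pA and the fitted
`N` scatters around 5 — the same biases the procedure has on real
recordings, and the reason the reference protocol reports `N ≈ 5.3`,
`Q_p ≈ −16.8 pA` rather than the generating values.

## Short-term plasticity and the integrate-and-fire neuron

The R·P model is evaluated event-driven and exactly: between events both
variables relax in closed form (`X(t+Δ) = X_∞ + (X − X_∞)e^(−Δ/τ)`), at an
event the pre-event `(R, P, R·P)` is recorded and the jumps
`R → R − R·P`, `P → P + Δ(1−P)` applied. Under a regular train with
Δ = 0 the steady state `R* = (1 − e^(−T/τ_R)) / (1 − (1−P_inf)e^(−T/τ_R))`
is reproduced to 10⁻¹⁰, which the tests use as the convergence oracle.
`stp_conductance_train()` scales a maximal-conductance waveform by the
pre-event `R·P`, summing any number of independent input trains and up to
two components (direct and spillover) with independent dynamics.

`iaf_simulate()` uses exponential Euler, which is exact when conductances
are constant within a step; spike times are refined by solving the
exponential step solution for the sub-step crossing instant. Voltage is
clamped at the reset for the refractory period, and the painted `V_peak`
sample is cosmetic — it never enters any statistic. Default membrane
parameters (3 pF, 1 nS leak, −75 mV rest) are representative of a
cerebellar granule cell. One caveat, measured and documented rather than
hidden: step-halving reproduces spike *counts* exactly and typical spike
times to a fraction of the coarse step, but a near-grazing threshold
crossing has O(1) sensitivity to any perturbation, so the worst-case
deviation over a long train can modestly exceed one coarse step. The tests
therefore assert count equality, median deviation below `dt/2`, and a
2·`dt` worst-case bound.

## Synthetic fixtures: what they do and do not show

The fixture generators produce white-Gaussian-noise recordings with
embedded events of exact, known times and amplitudes (a single-pole-filtered
noise option exists for more realistic spectra). Detection thresholds in
the tests are set in absolute units, so noise whiteness does not flatter
the detectors; still, passing on fixtures demonstrates the *contracts* —
recall, precision, timing accuracy, parameter recovery — not performance on
real recordings with drifting baselines, correlated noise, and overlapping
events. The standard detection fixture is 20 events of −20 pA on 2 pA
noise (SNR 10) at 50 kHz, at least 50 ms apart; fixture sizes throughout
the suite are chosen so the full test run completes in a few minutes on one
CPU, with Monte-Carlo noise floors measured over 20-s traces.

## Numerical choices

* Optimizer: Levenberg–Marquardt (`minpack.lm`), tolerances 10⁻¹⁰, with
  analytic Jacobian for the variance–mean relation and numeric elsewhere;
  held parameters are pinned, excluded from the Jacobian, and reported with
  SE 0.
* Start values are computed from smoothed copies of the data (synexp) or by
  exponential peeling (double exponential); fits are unbounded except where
  a precondition applies (the synexp onset must lie inside the fit window,
  time constants must stay positive).
* `synexp_unit_peak()` locates the waveform extremum by golden-section
  search to 10⁻⁶ ms; dense-grid oracles in the tests confirm it.
* Poisson trains with a refractory dead time use a shifted exponential with
  the rate corrected so the asymptotic mean rate equals the nominal one —
  plain rejection would bias the rate low. Whether the correction is
  applied is visible: the minimum interval always exceeds the dead time and
  the empirical rate matches the request within 1% over long trains.
* Divisions by zero in pointwise operations raise errors rather than
  producing infinities; clipped intervals are replaced by straight lines
  between the samples just outside them.

## Known limitations

No general unit algebra; no colored-noise realism by default; ABF import
requires external conversion to text; multi-compartment and
Hodgkin–Huxley-style models are out of scope, as are spike sorting and
multi-electrode analysis. The MPFA background-variance subtraction and the
exact h-statistic expression are documented conventions validated against
oracles, not a claim about any particular interactive implementation.
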