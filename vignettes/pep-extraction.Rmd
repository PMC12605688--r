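---
title: "Beat-to-beat PEP extraction: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-to-beat PEP extraction: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepbeat)
```

## The measurement problem

The pre-ejection period (PEP) is the interval between the onset of
ventricular depolarization and the opening of the aortic valve. In
psychophysiology it serves as a non-invasive beat-to-beat index of cardiac
sympathetic drive. Operationally, PEP is measured between two fiducial
points on two synchronized signals:

* the **Q-peak** — the trough of the ECG Q wave immediately before the
  R-peak (used instead of Q-wave onset because the trough can be annotated
  more reliably), and
* the **B-point** — the upstroke notch/inflection on the first derivative of
  the thoracic impedance signal (dZ/dt) that marks aortic valve opening,

so that `PEP = (loc_B - loc_Q)` in milliseconds. The B-point is notoriously
polymorphic: depending on the beat it may appear as an incisive notch, a
plateau, a mere inflection, or nothing identifiable at all. Automated
detectors therefore differ widely, and this package exists to compose them
into complete extraction pipelines and to benchmark those pipelines against
reference annotations under a standardized evaluation scheme.

## Signal chain

1. **Filtering.** ECG: 5th-order Butterworth band-pass 0.67–45 Hz; dZ/dt:
   4th-order Butterworth band-pass 0.5–25 Hz. Both are applied
   forward–backward (zero-phase). A causal filter would delay every fiducial
   by its group delay and bias PEP; zero-phase filtering has no such shift
   (the test suite checks a zero cross-correlation lag on a band-limited
   pulse). Numerically, each band-pass is realized as a same-order high-pass
   plus low-pass cascade of second-order sections obtained by per-pole-pair
   bilinear transformation: the expanded transfer-function polynomial of a
   5th-order filter with a 0.67 Hz edge at 1000 Hz sampling is unstable in
   double precision, while biquad sections are well conditioned. Before
   high-pass filtering the signal mean is removed (DC cannot pass anyway,
   and this suppresses the start-up transient exactly); edges are handled by
   odd-reflection padding sized to the slowest pole's time constant.

2. **Cycle segmentation.** R-peaks are detected with an in-package
   derivative–energy detector (band-pass 5–15 Hz, differentiate, square,
   150 ms moving-window integration, adaptive threshold with 250 ms
   refractory period, peak snapping to the local ECG maximum). The detector
   is pluggable — `run_pipeline()` accepts any function returning R-peak
   indices. Each R-peak after the first defines a cardiac cycle from 35 % of
   the preceding RR interval before the R-peak to 65 % after it.

3. **Fiducial extraction.** Q-peak (3 algorithms) and C/B-point
   (1 + 12 algorithms) run independently on the two channels; only the
   negative-PEP policy couples them afterwards.

4. **Outlier correction.** B-point series are stationarized (0.1 Hz
   4th-order Butterworth low-pass subtracted), outliers flagged by the
   unscaled 3-MAD rule, and corrected by linear interpolation or
   forward/backward autoregression (or passed through unchanged).

### A note on index rounding

All sample indices are 0-based and all ms-to-sample conversions use base R
`round()` (round-half-to-even). This choice is load-bearing for the cycle
split: for every integer RR, `round(0.35 RR)` and the complementary
`RR - round(0.35 RR)` tile the record exactly, with no gap or overlap
between consecutive constant-RR cycles. (Half-away-from-zero rounding
violates this: at RR = 10 it assigns 4 + 7 = 11 samples.) The cycle end is
computed as `r + RR - round(0.35 RR)` rather than `r + round(0.65 RR)` so
that tiling also survives floating-point representation of the half-cases.

### Derivatives

Several B-point detectors search d²Z/dt² and d³Z/dt³. Derivatives are
estimated by central differences after a short moving average (window
`round(5 fs / 1000)` samples, minimum 3) before each differencing pass; raw
repeated differencing at 500–1000 Hz amplifies noise quadratically per order
and destroys the third-derivative extrema the detectors need. The window is
short enough that a 10 Hz component is attenuated by less than 1 %.

## The algorithms

**Q-peak.** (i) Fixed offset: Q = R − t, t defaulting to 40 ms (the Q–R
interval is assumed stable within a person; offsets 32–42 ms are part of the
expanded benchmark grid). (ii) Amplitude threshold: the last sample before R
below `−1.2·R/scale`; the scale (default 2000) deliberately replaces the
sampling rate of the original formulation, which would otherwise make the
threshold depend on fs although signal amplitude does not. (iii) Wavelet
delineation: an à-trous quadratic-spline wavelet transform whose detail
coefficients behave like smoothed derivatives; the R upslope appears as a
positive modulus maximum at scale 2², a genuine Q wave as a preceding
negative modulus maximum. The Q-evidence threshold (0.06 of the R upslope
maximum) is a documented constant of this implementation, chosen so that
beats with no Q deflection produce a *missing* result rather than a guess;
the synthetic generator's zero-amplitude-Q mode exercises exactly this path.

**C-point.** The within-cycle maximum of dZ/dt. Among multiple candidate
peaks (local maxima with ≥ 10 % prominence after the R-peak) the one whose
R–C interval is closest to the mean of up to three preceding cycles wins;
with no history the global maximum wins; no peak at all yields a missing
C-point, which propagates to every C-anchored B detector as reason `NoC`.

**B-point.** Twelve detectors spanning four families: local
extrema/zero-crossings of dZ/dt or its derivatives (`ste85`, `she90`,
`deb93sd`, `arb17ic`, `arb17sd`, `arb17td`), fixed regressions on the R–C
interval (`loz07lr`, `loz07qr`, coefficients never refit), geometric
constructions (`dro22` maximum chord distance; `for18` monotone-segment
analysis anchored at the A-point), and staged searches (`pal21`, `mil22`).
Where the original formulations leave constants unstated, this package
documents its choices as defaults: `pal21` uses window `[C−150 ms, C)` with
slope threshold `0.5·(dZ/dt(C) − min)/150 ms` (relaxed to half in stage 2,
global-minimum fallback in stage 3); `mil22` uses the quadratic ramp
`w(k) = (k/N)²` over the 300 ms window before C; `loz07*` predictions are
anchored at the R-peak because the R–C interval is R-anchored; `for18`
implements the zero-crossing/local-maximum fallback chain within the first
third of the most significant (longest, then largest-gain, then latest)
strictly increasing run. Every missing B-point carries exactly one reason
code from `{InvBWindow, NegPEP, NoC, NoIsoCross, NoLocMin, NoMonIncr,
NoZCross}`; all C-relative windows clip at the cycle start and report
`InvBWindow` when fewer than two samples survive.

**Outlier correction.** The beat series is treated as uniformly sampled at
`1/mean(RR)` Hz for the 0.1 Hz low-pass — the simplest consistent reading of
filtering a per-beat series at a Hz cutoff. The MAD is unscaled (no 1.4826
consistency factor) and applied with no special cases: with MAD = 0 any
deviation from the median is flagged, and an all-constant series flags
nothing. Because the low-pass inevitably absorbs part of a single-beat
spike into the trend (about 18–20 % at resting heart rates, per the filter's
impulse response), the detection threshold effectively applies to the
remaining ~80 % of spike magnitude. The autoregressive corrector uses order
p = 4 fit by least squares on up to 30 clean context beats per side (the
original publication leaves both unstated); collinear lag matrices from
noiseless low-order processes resolve to the minimal-lag solution. By
default the correction stage also interpolates cycles whose B-point is
missing (`interpolate_missing = TRUE`) — this is what allows correction to
*reduce* the number of invalid PEPs — and never touches a clean beat.

## Evaluation engine

Estimated cycles are matched to reference cycles greedily in time order; a
pair is accepted when both borders fall within ±50 ms — the "100 ms
tolerance centered around the borders" read as a symmetric window of total
width 100 ms. With cycles longer than 300 ms and a ±50 ms gate, matches
cannot cross, so the greedy matching is optimal. Unmatched estimates are
false positives and are excluded; unmatched references are reported
separately as `unmatched_ref` rather than folded into the invalid count,
since the spec of the invalid taxonomy concerns cycles the pipeline saw.

Errors per matched valid cycle: `E = PEP_ref − PEP_est`, `AE = |E|`,
`ARE = AE/PEP_ref` (stored as a fraction, printed as percent). Two
aggregations are always computed: *per datapoint* (mean within each
grouping-key combination — participant × condition × phase by default, with
the keys configurable via `by=` — then averaged across datapoints) and *per
sample* (mean ± SD over all cycles, weighting each cycle equally). The two
differ exactly when datapoint sizes differ; the canonical 4-cycle example
(`AE = {10}` and `{30,30,30}`) gives 20 vs 25 ms.

Inter-rater agreement uses ICC(3,2): two-way mixed, absolute agreement,
average measures over two fixed raters, computed from the two-way ANOVA mean
squares, with the F-based single-measures confidence bounds transformed to
average measures by the Spearman–Brown relation. The implementation is
validated in the test suite against an independent `aov()`-based oracle.

## The synthetic generator

Every stage above is testable without recorded data because
`synth_recording()` produces beat trains with *exact* fiducial ground truth:
all four indices (Q, R, B, C) are fixed first, and the waveforms are then
constructed around them. The ECG beat is a sum of Gaussian bumps (P, Q, R,
S, T) with the Q trough centered exactly on the truth sample; the dZ/dt beat
is piecewise smooth with its global maximum exactly at C. The four B-point
morphology classes mirror the annotation taxonomy:

* **notch** — a smooth 20 ms descent into a strict local minimum exactly at
  B, then a steep sine-shaped systolic upslope (B is the onset of the rapid
  upslope, so detectors following the notch, the chord distance, or the
  staged slope search all recover it);
* **plateau** — a 15 ms zero-slope shelf starting at B before the rise;
* **inflection** — a quintic smoothstep rise whose curvature changes sign
  exactly at B, with no extremum;
* **featureless** — a single strictly monotone linear rise spanning the
  cycle, with no A-wave and nothing identifiable at B. This class is what
  drives the local-minimum rule (`ste85`) to a `NoLocMin` miss while the
  chord-distance rule (`dro22`) still returns a value.

Defaults are a resting adult: 60 bpm, PEP 100 ms (normal physiological range
60–170 ms), R–C 150 ms, Q–R gap 40 ms, fs 1000 Hz. RR jitter is i.i.d.
Gaussian truncated at ±20 % of the mean RR so the 35/65 segmentation stays
valid. Noise (broadband Gaussian, sinusoidal baseline drift, powerline) is
added after concatenation. Identical configurations are bit-identical: the
generator runs under a private RNG stream and restores the caller's seed.

What the generator does **not** emulate: hemodynamic pressure/flow coupling,
respiration-driven amplitude modulation, electrode motion artifacts,
ectopic beats, and within-recording morphology switches. Passing tests on
synthetic data therefore demonstrate algorithmic correctness — each detector
finds the feature it defines, windows clip correctly, reasons are conserved —
not field performance on noisy human recordings, where B-point errors of
10–20 ms are the realistic scale.

## Problem sizes and runtime choices

The test suite uses 30 s trains (≈ 30 beats) for per-detector checks and a
121 s train (≈ 120 beats) for end-to-end PEP recovery; the brute-force
equivalence checks run 200 randomized trials at n ≤ 50. The acceptance
script (`scripts/acceptance.R`) regenerates all of its inputs from the seed
it is given and recomputes every reported number at run time; these sizes
keep a full run in seconds while leaving every code path exercised.

## Known limitations

* The wavelet delineator implements the modulus-maxima logic with
  documented, fixed thresholds; it is not a byte-for-byte reimplementation
  of any library delineator, and its misses on Q-less beats are by design.
* `pal21` and `mil22` constants are this package's documented
  approximations of underspecified originals.
* The beat-series time base for the 0.1 Hz stationarization filter is the
  uniform `1/mean(RR)` grid; recordings with strong heart-rate trends
  stretch this approximation.
* Native readers for proprietary acquisition formats (.acq, TFM .mat) and
  EDF are out of scope; recordings enter via plain CSV.
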