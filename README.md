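# pepbeat

Beat-to-beat extraction and benchmarking of the cardiac **pre-ejection
period (PEP)** from synchronized ECG and impedance-cardiography (ICG)
recordings, in R.

The PEP is the interval from the onset of ventricular depolarization to the
opening of the aortic valve — a widely used non-invasive marker of cardiac
sympathetic activity. On a beat-to-beat basis it is operationalized as

```
PEP = loc(B-point) − loc(Q-peak)   [ms]
```

where the Q-peak is the trough of the ECG Q wave just before the R-peak and
the B-point is the upstroke feature on dZ/dt (the first derivative of
thoracic impedance) marking aortic valve opening. Because the B-point may
appear as a notch, a plateau, an inflection, or nothing identifiable at all,
many competing detectors exist. `pepbeat` implements the full chain needed
to compose and benchmark them:

* **Preprocessing** — zero-phase Butterworth band-passes (ECG 0.67–45 Hz,
  dZ/dt 0.5–25 Hz), smoothed central-difference derivatives up to order 3,
  zero-phase resampling for mixed-rate recordings.
* **Segmentation** — in-package Pan–Tompkins-style R-peak detector
  (pluggable), cycles spanning −35 %/+65 % of the preceding RR interval.
* **Q-peak detection** (3 algorithms) — fixed R-offset (`van13`), amplitude
  threshold `−1.2·R/scale` (`for18`), and à-trous quadratic-spline wavelet
  delineation (`mar04`).
* **C-point and B-point detection** (1 + 12 algorithms) — dZ/dt-max C-point
  with R–C history disambiguation; B-point by local extrema and
  zero-crossings of dZ/dt and its derivatives (`ste85`, `she90`, `deb93sd`,
  `arb17ic`, `arb17sd`, `arb17td`), fixed R–C regressions (`loz07lr`:
  `B = 0.55·RC + 4.45`; `loz07qr`: `B = −0.0032·RC² + 1.233·RC − 31.59`),
  chord distance (`dro22`), monotone-segment analysis (`for18`), staged
  slope search (`pal21`), weighted window (`mil22`).
* **Outlier correction** — 3-MAD rule on stationarized B series (0.1 Hz
  low-pass subtracted), corrected by linear interpolation or
  forward/backward AR(4) prediction, plus a pass-through dummy.
* **Pipelines and evaluation** — 3 × 12 × 3 = 108 pipeline grid (288 with
  the R-offset expanded over 32–42 ms), reference-injection for isolated
  algorithm evaluation, cycle matching at ±50 ms border tolerance, E/AE/ARE
  metrics with per-sample and per-datapoint aggregation, invalid-PEP
  bookkeeping by reason code, and ICC(3,2) inter-rater agreement.
* **Synthetic generator** — ECG/ICG beat trains with *exact* fiducial
  ground truth and four B-point morphology classes (notch, plateau,
  inflection, featureless), so every stage is testable with no data
  download.

## Worked example

```r
library(pepbeat)

# 60 s synthetic recording: 60 bpm, PEP 100 ms, notch-morphology B-points
sim <- synth_recording(synth_config(duration_s = 60, pep_ms = 100, seed = 42))

cfg <- pep_pipeline("van13", "dro22", "linint", q_params = list(t_ms = 40))
res <- run_pipeline(sim$recording, cfg)
res
#> <pep_pipeline> van13(t_ms=40) + dro22 + linint  [neg_pep=nan]
#>   59 cycles, 59 valid PEP (100.0%), mean PEP 104.0 ms

head(res$pep[, c("cycle_id", "q_peak", "c_point", "b_point", "pep_ms", "valid")], 4)
#>   cycle_id q_peak c_point b_point pep_ms valid
#> 1        1   1458    1651    1562    104  TRUE
#> 2        2   2458    2651    2562    104  TRUE
#> 3        3   3458    3651    3562    104  TRUE
#> 4        4   4458    4651    4562    104  TRUE

# benchmark against the generator's exact annotations
m  <- match_cycles(sim$annotations, res$partition, fs = sim$recording$fs)
m
#> <match_result> 59 matched, 0 unmatched reference (FN), 0 unmatched estimated (FP)

aggregate_errors(per_sample_errors(m, sim$annotations, res$pep,
                                   fs = sim$recording$fs))
#> <aggregate_report>
#>   per-sample:    MAE 4.00 +/- 0.00 ms, ME -4.00 ms, MARE 4.0% (n=59)
#>   per-datapoint: MAE 4.00 ms over 1 datapoints
#>   invalid: 0 of 59 cycles
```

Reading the numbers: every detected cycle matched its reference cycle; the
chord-distance B detector lands 2 ms late and the fixed 40 ms Q offset 2 ms
early on this waveform shape, so the pipeline overestimates PEP by a
constant 4 ms (ME = −4 ms under the `E = PEP_ref − PEP_est` convention),
well inside the ±5 ms recovery band expected on clean data. The full
pipeline grid comes from `enumerate_pipelines()` (108 rows, or 288 with
`expand_van_lien = TRUE`).

A thin command-line wrapper with `simulate` / `extract` / `evaluate`
subcommands lives at `inst/scripts/pepbeat-cli.R`.

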