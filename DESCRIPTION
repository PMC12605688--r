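Package: pepbeat
Title: Beat-to-Beat Pre-Ejection Period Extraction from ECG and Impedance Cardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and benchmarking of the cardiac pre-ejection period (PEP)
    on a beat-to-beat basis from synchronized electrocardiogram (ECG) and
    impedance cardiogram (dZ/dt) recordings. Implements Q-peak detection from
    the ECG (fixed R-offset, amplitude-threshold, and discrete-wavelet-transform
    delineation), C-point and twelve B-point detection algorithms on dZ/dt and
    its derivatives, median-absolute-deviation outlier detection on
    stationarized B-point series with linear-interpolation and autoregressive
    correction, composable PEP extraction pipelines, and a standardized
    evaluation engine (cycle matching, error metrics, per-sample and
    per-datapoint aggregation, intraclass correlation). A synthetic ECG/ICG
    generator with exact fiducial ground truth makes every stage testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
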