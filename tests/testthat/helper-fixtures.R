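# Shared synthetic fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

notch_train <- function() {
  fixture("notch30", function() {
    synth_recording(synth_config(duration_s = 30, fs = 1000, pep_ms = 100, seed = 3))
  })
}

featureless_train <- function() {
  fixture("flat30", function() {
    synth_recording(synth_config(duration_s = 30, fs = 1000, pep_ms = 100,
                                 b_morphology = "featureless", seed = 4))
  })
}

# preprocessed signals + detected partition + C-points for the notch train
notch_chain <- function() {
  fixture("notch30_chain", function() {
    out <- notch_train()
    fs <- out$recording$fs
    ecg <- preprocess_ecg(out$recording$ecg, fs)
    dzdt <- preprocess_dzdt(out$recording$dzdt, fs)
    part <- partition_cycles(detect_r_peaks(ecg, fs), fs, length(ecg))
    list(out = out, fs = fs, ecg = ecg, dzdt = dzdt, part = part,
         cp = detect_c_points(dzdt, part, fs),
         truth = out$truth[-1, ])  # first beat has no cycle
  })
}

featureless_chain <- function() {
  fixture("flat30_chain", function() {
    out <- featureless_train()
    fs <- out$recording$fs
    ecg <- preprocess_ecg(out$recording$ecg, fs)
    dzdt <- preprocess_dzdt(out$recording$dzdt, fs)
    part <- partition_cycles(detect_r_peaks(ecg, fs), fs, length(ecg))
    list(out = out, fs = fs, ecg = ecg, dzdt = dzdt, part = part,
         cp = detect_c_points(dzdt, part, fs),
         truth = out$truth[-1, ])
  })
}

# single-cycle fixture for hand-constructed B-point cases: wraps a dzdt vector
# into a one-row partition/cpoint pair (all indices 0-based)
one_cycle <- function(dzdt, r_peak, c_point, start = 0L, end = length(dzdt),
                      rr_prev = 1000L) {
  part <- data.frame(cycle_id = 1L, start = as.integer(start),
                     r_peak = as.integer(r_peak), end = as.integer(end),
                     rr_prev = as.integer(rr_prev))
  class(part) <- c("cycle_partition", "data.frame")
  cp <- data.frame(cycle_id = 1L, c_point = as.integer(c_point),
                   rc_ms = (c_point - r_peak), reason = NA_character_,
                   stringsAsFactors = FALSE)
  list(part = part, cp = cp)
}

# independent ANOVA-table oracle for the average-measures absolute-agreement ICC
icc_aov_oracle <- function(a, b) {
  n <- length(a)
  d <- data.frame(y = c(a, b), subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- suppressWarnings(stats::anova(stats::aov(y ~ subj + rater, data = d))[["Mean Sq"]])
  (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / n)
}
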