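#' Configuration for the synthetic ECG/ICG generator
#'
#' Defines a beat train with exact fiducial ground truth. The defaults emulate
#' a resting adult: 60 bpm, PEP 100 ms (normal physiological range 60--170 ms),
#' R--C interval 150 ms, Q--R gap 40 ms. The ECG beat is a sum of Gaussian
#' bumps (P, Q, R, S, T) with the Q trough placed exactly on the ground-truth
#' sample; the dZ/dt beat is a piecewise-smooth wave: A-wave dip, then a
#' morphology-class-specific B feature exactly at the ground-truth B sample,
#' then a rise to the within-beat maximum exactly at the C sample, then a
#' descent below baseline and recovery.
#'
#' Morphology classes map to local features at B:
#' \describe{
#'   \item{notch}{a strict local minimum (incisive notch) at B;}
#'   \item{plateau}{a 15 ms zero-slope shelf starting at B;}
#'   \item{inflection}{a curvature sign change at B with no extremum;}
#'   \item{featureless}{a pure monotone rise with no identifiable mark at B.}
#' }
#'
#' @param duration_s recording length in seconds (> 0).
#' @param fs sampling rate in Hz (>= 250).
#' @param heart_rate_bpm mean heart rate, 40--180 bpm.
#' @param hr_jitter_sd per-beat RR jitter as a fraction of the mean RR
#'   (i.i.d. Gaussian, truncated at +/- 20 % so the 35/65 cycle segmentation
#'   stays valid).
#' @param pep_ms target Q-to-B interval per beat in ms (recycled per beat).
#' @param rc_ms R-to-C interval in ms; must exceed `pep_ms`.
#' @param qr_gap_ms Q-to-R interval in ms.
#' @param b_morphology one of `"notch"`, `"plateau"`, `"inflection"`,
#'   `"featureless"`.
#' @param q_amplitude depth of the ECG Q deflection in signal units; `0`
#'   synthesizes beats without any Q wave.
#' @param noise list with `gaussian_sd`, `baseline_drift_amp`,
#'   `baseline_drift_freq` (Hz), `powerline_amp`, `powerline_freq` (Hz).
#' @param seed integer; identical configurations produce bit-identical output.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_s = 60, fs = 1000, heart_rate_bpm = 60,
                         hr_jitter_sd = 0, pep_ms = 100, rc_ms = 150,
                         qr_gap_ms = 40,
                         b_morphology = c("notch", "plateau", "inflection", "featureless"),
                         q_amplitude = 0.12,
                         noise = list(), seed = 1L) {
  assert_scalar_numeric(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_numeric(fs, "fs", lower = 250)
  assert_scalar_numeric(heart_rate_bpm, "heart_rate_bpm", lower = 40, upper = 180)
  assert_scalar_numeric(rc_ms, "rc_ms", lower = 1e-9)
  if (any(pep_ms <= 0) || any(pep_ms >= rc_ms)) {
    stop("configuration error: need 0 < pep_ms < rc_ms", call. = FALSE)
  }
  b_morphology <- match.arg(b_morphology)
  defaults <- list(gaussian_sd = 0, baseline_drift_amp = 0, baseline_drift_freq = 0.2,
                   powerline_amp = 0, powerline_freq = 50)
  noise <- utils::modifyList(defaults, noise)
  structure(list(duration_s = duration_s, fs = fs, heart_rate_bpm = heart_rate_bpm,
                 hr_jitter_sd = hr_jitter_sd, pep_ms = pep_ms, rc_ms = rc_ms,
                 qr_gap_ms = qr_gap_ms, b_morphology = b_morphology,
                 q_amplitude = q_amplitude, noise = noise, seed = as.integer(seed)),
            class = "synth_config")
}

gauss_bump <- function(t_ms, center_ms, sigma_ms, amp) {
  amp * exp(-((t_ms - center_ms)^2) / (2 * sigma_ms^2))
}

# quintic smoothstep: 0 -> 1, zero slope at both ends, inflection at midpoint
smoothstep <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, 10 * u^3 - 15 * u^4 + 6 * u^5))

half_cos_rise <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, 0.5 * (1 - cos(pi * u))))

#' Synthesize one cardiac beat with exact fiducials
#'
#' Builds the noiseless ECG and dZ/dt segments of a single beat on a sample
#' grid relative to the R-peak, together with the exact 0-based fiducial
#' offsets. Used internally by [synth_recording()]; exposed for inspection and
#' kernel-level tests.
#'
#' @param config a [synth_config()].
#' @param beat_params list with `rr_ms` (preceding RR interval in ms) and
#'   optional `pep_ms` overriding the configured value for this beat.
#' @return List with `offsets` (integer sample offsets relative to R), `ecg`,
#'   `dzdt`, and `truth` (offsets of q/b/c relative to R, in samples).
#' @export
synth_beat_kernel <- function(config, beat_params = list()) {
  fs <- config$fs
  rr_ms <- beat_params$rr_ms %||% (60000 / config$heart_rate_bpm)
  pep <- beat_params$pep_ms %||% config$pep_ms[1]
  if (pep >= config$rc_ms) stop("configuration error: pep_ms >= rc_ms", call. = FALSE)
  gap <- config$qr_gap_ms

  # exact truth in samples, then back to exact ms so features land on samples
  q_off <- -ms_to_samples(gap, fs)
  b_off <- q_off + ms_to_samples(pep, fs)
  c_off <- ms_to_samples(config$rc_ms, fs)
  b_ms <- samples_to_ms(b_off, fs)
  c_ms <- samples_to_ms(c_off, fs)
  q_ms <- samples_to_ms(q_off, fs)

  offsets <- seq.int(-ms_to_samples(400, fs), ms_to_samples(min(650, 0.68 * rr_ms), fs))
  t <- samples_to_ms(offsets, fs)
  k <- min(1, rr_ms / 1000)  # interval compression at high heart rate

  ecg <- gauss_bump(t, -180 * k, 25, 0.12) +
    gauss_bump(t, q_ms, 5, -config$q_amplitude) +
    gauss_bump(t, 0, 9, 1.0) +
    gauss_bump(t, 28, 7, -0.18) +
    gauss_bump(t, min(280, 280 * k * 1.15), 60 * k, 0.35)

  C_amp <- 2.0
  dzdt <- numeric(length(t))
  morph <- config$b_morphology
  if (morph == "notch") {
    # incisive notch: smooth descent into a strict minimum at B, then the
    # rapid systolic upslope leaving B with high initial slope
    d <- 0.4
    dzdt <- gauss_bump(t, b_ms - 50, 12, -0.5)
    down <- t >= b_ms - 20 & t < b_ms
    dzdt[down] <- dzdt[down] - d * 0.5 * (1 - cos(pi * (t[down] - b_ms + 20) / 20))
    up <- t >= b_ms & t <= c_ms
    dzdt[up] <- -d + (C_amp + d) * sin(pi * (t[up] - b_ms) / (2 * (c_ms - b_ms)))
  } else if (morph == "plateau") {
    shelf_end <- b_ms + 15
    dzdt <- C_amp * half_cos_rise((t - shelf_end) / (c_ms - shelf_end)) * (t <= c_ms) +
      gauss_bump(t, b_ms - 40, 10, -0.5)
  } else if (morph == "inflection") {
    m <- 2 * b_ms - c_ms
    dzdt <- C_amp * smoothstep((t - m) / (c_ms - m)) * (t <= c_ms) +
      gauss_bump(t, m - 45, 10, -0.5)
  } else { # featureless: one long strictly monotone linear rise spanning the
           # cycle, no A-wave dip, nothing identifiable at B
    m <- -0.35 * rr_ms
    up <- t >= m & t <= c_ms
    dzdt[up] <- C_amp * (t[up] - m) / (c_ms - m)
  }
  # descent from the C maximum below baseline, then recovery to baseline
  desc <- t > c_ms & t <= c_ms + 180
  dzdt[desc] <- -0.5 + (C_amp + 0.5) * 0.5 * (1 + cos(pi * (t[desc] - c_ms) / 180))
  rec <- t > c_ms + 180 & t <= c_ms + 330
  dzdt[rec] <- -0.5 * 0.5 * (1 + cos(pi * (t[rec] - c_ms - 180) / 150))

  list(offsets = offsets, ecg = ecg, dzdt = dzdt,
       truth = list(q = q_off, b = b_off, c = c_off))
}

#' Generate a synthetic recording with ground truth
#'
#' Concatenates beat kernels at RR intervals drawn from the configured heart
#' rate (with optional truncated-Gaussian jitter), adds noise after
#' concatenation, and returns the recording together with the exact fiducial
#' ground truth and a per-cycle annotation table in the package's CSV dialect.
#'
#' @param config a [synth_config()].
#' @return List with `recording` (a [pep_recording()]), `truth` (data.frame:
#'   `beat`, 0-based `r_peak`, `q_peak`, `b_point`, `c_point`, `pep_ms`), and
#'   `annotations` (data.frame as read by [read_annotations()]; the first beat
#'   has no preceding RR and therefore no annotation row).
#' @examples
#' out <- synth_recording(synth_config(duration_s = 10, seed = 7))
#' head(out$truth)
#' @export
synth_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  rr_mean_s <- 60 / config$heart_rate_bpm

  with_local_seed(config$seed, {
    r_times <- numeric(0)
    tcur <- rr_mean_s / 2
    while (tcur <= config$duration_s - 0.15 * rr_mean_s) {
      r_times <- c(r_times, tcur)
      jit <- if (config$hr_jitter_sd > 0) {
        max(-0.2, min(0.2, stats::rnorm(1, 0, config$hr_jitter_sd)))
      } else 0
      tcur <- tcur + rr_mean_s * (1 + jit)
    }
    nb <- length(r_times)
    r_idx <- as.integer(round(r_times * fs))
    rr_samp <- c(as.integer(round(rr_mean_s * fs)), diff(r_idx))
    pep_beat <- rep_len(config$pep_ms, nb)

    ecg <- numeric(n)
    dzdt <- numeric(n)
    truth <- data.frame(beat = integer(nb), r_peak = integer(nb), q_peak = integer(nb),
                        b_point = integer(nb), c_point = integer(nb), pep_ms = numeric(nb))
    for (i in seq_len(nb)) {
      ker <- synth_beat_kernel(config, list(rr_ms = samples_to_ms(rr_samp[i], fs),
                                            pep_ms = pep_beat[i]))
      pos <- r_idx[i] + ker$offsets          # 0-based target samples
      keep <- pos >= 0L & pos < n
      ecg[pos[keep] + 1L] <- ecg[pos[keep] + 1L] + ker$ecg[keep]
      dzdt[pos[keep] + 1L] <- dzdt[pos[keep] + 1L] + ker$dzdt[keep]
      truth[i, ] <- list(i, r_idx[i], r_idx[i] + ker$truth$q,
                         r_idx[i] + ker$truth$b, r_idx[i] + ker$truth$c,
                         samples_to_ms(ker$truth$b - ker$truth$q, fs))
    }

    nz <- config$noise
    tt <- (seq_len(n) - 1L) / fs
    if (nz$gaussian_sd > 0) {
      ecg <- ecg + stats::rnorm(n, 0, nz$gaussian_sd)
      dzdt <- dzdt + stats::rnorm(n, 0, nz$gaussian_sd)
    }
    if (nz$baseline_drift_amp > 0) {
      drift <- nz$baseline_drift_amp * sin(2 * pi * nz$baseline_drift_freq * tt)
      ecg <- ecg + drift; dzdt <- dzdt + drift
    }
    if (nz$powerline_amp > 0) {
      pl <- nz$powerline_amp * sin(2 * pi * nz$powerline_freq * tt)
      ecg <- ecg + pl; dzdt <- dzdt + pl
    }

    rec <- pep_recording(ecg, dzdt, fs, fs, participant = "synthetic")
    ann <- synth_annotations(truth, fs, n)
    list(recording = rec, truth = truth, annotations = ann)
  })
}

# Per-cycle annotation table from ground truth; cycle borders follow the same
# preceding-RR 35/65 rule the segmentation module uses, so truth annotations
# and detected partitions are directly comparable.
synth_annotations <- function(truth, fs, n) {
  nb <- nrow(truth)
  if (nb < 2L) {
    return(data.frame(cycle_id = integer(0), start = integer(0), r_peak = integer(0),
                      end = integer(0), q_peak = integer(0), b_point = integer(0),
                      artifact = logical(0), participant = character(0),
                      condition = character(0), phase = character(0)))
  }
  i <- 2:nb
  rr <- truth$r_peak[i] - truth$r_peak[i - 1L]
  data.frame(
    cycle_id = seq_along(i),
    start = as.integer(truth$r_peak[i] - round(0.35 * rr)),
    r_peak = truth$r_peak[i],
    end = pmin(as.integer(truth$r_peak[i] + round(0.65 * rr)), n),
    q_peak = truth$q_peak[i],
    b_point = truth$b_point[i],
    artifact = FALSE,
    participant = "synthetic", condition = NA_character_, phase = NA_character_
  )
}
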