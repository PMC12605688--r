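#' Detect R-peaks in a preprocessed ECG
#'
#' Derivative-plus-adaptive-threshold detector in the Pan--Tompkins style:
#' band-pass 5--15 Hz to isolate QRS energy, differentiate, square, integrate
#' over a 150 ms moving window, threshold adaptively with a 250 ms refractory
#' period, then snap each detection to the nearest local maximum of the ECG
#' within +/- 75 ms. The detector is pluggable: any function returning 0-based
#' R-peak indices can replace it in [run_pipeline()].
#'
#' @param ecg preprocessed ECG vector.
#' @param fs sampling rate in Hz.
#' @return Strictly increasing 0-based sample indices; empty for flat or empty
#'   signals.
#' @export
detect_r_peaks <- function(ecg, fs) {
  ecg <- as.numeric(ecg)
  n <- length(ecg)
  if (n < fs %/% 2 || max(ecg) - min(ecg) < 1e-12) return(integer(0))

  qrs <- butter_bandpass(ecg, fs, 5, 15, order = 2)
  feat <- central_diff(qrs)^2
  w <- max(3L, ms_to_samples(150, fs))
  feat <- moving_average(feat, w)

  refractory <- ms_to_samples(250, fs)
  # adaptive threshold: running estimate of signal peak level
  thr <- 0.3 * max(feat[seq_len(min(n, as.integer(2 * fs)))])
  spk <- thr / 0.3
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (feat[i] > thr && feat[i] >= feat[i - 1L] && feat[i] >= feat[i + 1L]) {
      if (length(peaks) == 0L || i - peaks[length(peaks)] > refractory) {
        peaks <- c(peaks, i)
        spk <- 0.875 * spk + 0.125 * feat[i]
        thr <- 0.3 * spk
        i <- i + refractory %/% 2L
        next
      }
    }
    i <- i + 1L
  }
  if (length(peaks) == 0L) return(integer(0))

  # snap to the local ECG maximum around the integrated-energy peak
  half <- ms_to_samples(75, fs)
  r <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(n, p + half)
    lo + which.max(ecg[lo:hi]) - 1L
  }, integer(1))
  r <- sort(unique(r))
  # enforce refractory on the snapped peaks (keep the larger of close pairs)
  keep <- rep(TRUE, length(r))
  for (j in seq_along(r)[-1]) {
    if (!any(keep[seq_len(j - 1L)])) next
    prev <- max(which(keep[seq_len(j - 1L)]))
    if (r[j] - r[prev] <= refractory) {
      if (ecg[r[j]] > ecg[r[prev]]) keep[prev] <- FALSE else keep[j] <- FALSE
    }
  }
  as.integer(r[keep] - 1L)   # 0-based
}

#' Partition a recording into cardiac cycles
#'
#' Each R-peak after the first defines one cycle spanning from 35 % of the
#' preceding RR interval before the R-peak to 65 % of it after, so that
#' consecutive cycles tile the record exactly at constant RR. The first R-peak
#' has no preceding interval and yields no cycle.
#'
#' @param r_peaks strictly increasing 0-based R-peak indices.
#' @param fs sampling rate in Hz.
#' @param n_samples optional signal length used to clip cycle borders.
#' @return A data.frame of class `cycle_partition` with 0-based columns
#'   `cycle_id`, `start`, `r_peak`, `end` (half-open `[start, end)`) and
#'   `rr_prev` (preceding RR in samples).
#' @examples
#' partition_cycles(c(1000, 2000, 3000), fs = 1000)
#' @export
partition_cycles <- function(r_peaks, fs, n_samples = NULL) {
  r_peaks <- as.integer(r_peaks)
  if (length(r_peaks) < 2L) {
    out <- data.frame(cycle_id = integer(0), start = integer(0), r_peak = integer(0),
                      end = integer(0), rr_prev = integer(0))
    class(out) <- c("cycle_partition", "data.frame")
    return(out)
  }
  if (any(diff(r_peaks) <= 0L)) stop("`r_peaks` must be strictly increasing", call. = FALSE)
  i <- 2:length(r_peaks)
  rr <- r_peaks[i] - r_peaks[i - 1L]
  start <- as.integer(r_peaks[i] - round(0.35 * rr))
  # end = r + 65% of RR, realized as r + RR - round(0.35 RR) so that
  # consecutive constant-RR cycles tile exactly (robust to floating-point
  # half-cases in round(0.65 RR))
  end <- as.integer(r_peaks[i] + rr - round(0.35 * rr))
  if (!is.null(n_samples)) {
    start <- pmax(start, 0L)
    end <- pmin(end, as.integer(n_samples))
  }
  out <- data.frame(cycle_id = seq_along(i), start = start, r_peak = r_peaks[i],
                    end = end, rr_prev = as.integer(rr))
  class(out) <- c("cycle_partition", "data.frame")
  out
}
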