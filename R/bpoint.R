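# C-point detection and the twelve B-point extraction algorithms.
#
# Reason codes for missing fiducials (shared with the pipeline layer):
#   NoC         no C-point in the cycle
#   NoLocMin    required local minimum absent
#   NoZCross    no zero-crossing found
#   NoIsoCross  no crossing of the within-cycle mean
#   NoMonIncr   no usable monotonically increasing segment
#   InvBWindow  invalid (empty after clipping) B-point search window
#   NegPEP      negative PEP (set at pipeline level)

B_REASONS <- c("InvBWindow", "NegPEP", "NoC", "NoIsoCross", "NoLocMin",
               "NoMonIncr", "NoZCross")

bpoint_result <- function(partition, b_point, reason) {
  out <- data.frame(cycle_id = partition$cycle_id, b_point = as.integer(b_point),
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("bpoint_result", "data.frame")
  out
}

#' Detect C-points in the dZ/dt signal
#'
#' The C-point is the maximum of dZ/dt within a cardiac cycle (dZ/dt_max).
#' Candidate peaks are the local maxima of dZ/dt after the R-peak with
#' prominence of at least 10 % of the cycle's amplitude range; among multiple
#' candidates the peak whose R--C interval is closest to the mean R--C
#' interval of up to three preceding cycles is selected (the global maximum
#' when no history exists). Cycles without any peak yield a missing C-point.
#'
#' @param dzdt preprocessed dZ/dt vector.
#' @param partition a [partition_cycles()] result.
#' @param fs sampling rate in Hz.
#' @return Data.frame `cpoint_result`: `cycle_id`, 0-based `c_point` (NA when
#'   missing), `rc_ms` (R--C interval), `reason`.
#' @export
detect_c_points <- function(dzdt, partition, fs) {
  n <- length(dzdt)
  nc <- nrow(partition)
  c_point <- rep(NA_integer_, nc)
  rc_ms <- rep(NA_real_, nc)
  reason <- rep(NA_character_, nc)
  rc_hist <- numeric(0)
  for (i in seq_len(nc)) {
    idx <- clip_window(partition$r_peak[i] + 2L, partition$end[i] + 1L, n) # (r, end)
    if (length(idx) < 3L) { reason[i] <- "NoC"; next }
    seg <- dzdt[idx]
    pk <- local_maxima(seg)
    rng <- diff(range(seg))
    if (length(pk) && rng > 0) {
      prom <- vapply(pk, function(p) {
        left <- min(seg[seq_len(p)]); right <- min(seg[p:length(seg)])
        seg[p] - max(left, right)
      }, numeric(1))
      pk <- pk[prom >= 0.1 * rng]
    }
    if (length(pk) == 0L) { reason[i] <- "NoC"; next }
    cand <- idx[pk] - 1L                      # 0-based
    cand_rc <- samples_to_ms(cand - partition$r_peak[i], fs)
    sel <- if (length(rc_hist) == 0L) {
      which.max(seg[pk])
    } else {
      which.min(abs(cand_rc - mean(rc_hist)))
    }
    c_point[i] <- cand[sel]
    rc_ms[i] <- cand_rc[sel]
    rc_hist <- c(rc_hist, rc_ms[i])
    if (length(rc_hist) > 3L) rc_hist <- rc_hist[-1L]
  }
  out <- data.frame(cycle_id = partition$cycle_id, c_point = c_point,
                    rc_ms = rc_ms, reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("cpoint_result", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# shared helpers; all windows are 1-based index vectors into the signal

# search window [start, c) of cycle i, 1-based
pre_c_window <- function(partition, i, c0, n) {
  clip_window(partition$start[i] + 1L, c0 + 1L, n)
}

#' B-point detection on dZ/dt and its derivatives
#'
#' Dispatches one of the twelve B-point extraction algorithms. Methods (keys
#' as used in the pipeline registry):
#' \describe{
#'   \item{ste85}{last local minimum of dZ/dt before the C-point.}
#'   \item{she90}{last zero-crossing of dZ/dt before the C-point (first
#'     nonnegative sample of the crossing).}
#'   \item{deb93sd}{last local minimum of the second derivative before C.}
#'   \item{loz07lr}{linear regression on the R--C interval:
#'     `B = 0.55 * RC + 4.45` ms after the R-peak.}
#'   \item{loz07qr}{quadratic regression:
#'     `B = -0.0032 * RC^2 + 1.233 * RC - 31.59` ms after the R-peak.}
#'   \item{arb17ic}{last crossing of dZ/dt through its within-cycle mean
#'     ("isoelectric crossing") before C.}
#'   \item{arb17sd}{maximum of the second derivative in the 50 ms window
#'     starting 150 ms before C.}
#'   \item{arb17td}{maximum of the third derivative within 300 ms before C.}
#'   \item{for18}{zero-crossing / local-maximum search of the third
#'     derivative in the first third of the most significant monotonically
#'     increasing dZ/dt segment between the A-point and C.}
#'   \item{pal21}{staged search in a C-anchored window: local minimum closest
#'     to C, else first supra-threshold slope, relaxed threshold, global
#'     minimum fallback.}
#'   \item{dro22}{maximum vertical distance between dZ/dt and the straight
#'     line joining the C-point to the point 150 ms earlier.}
#'   \item{mil22}{last local minimum of dZ/dt multiplied by a monotone weight
#'     rising from 0 to 1 over the 300 ms before C (quadratic ramp).}
#' }
#' Missing C-points propagate as reason `"NoC"`; every missing B carries
#' exactly one reason code.
#'
#' @param dzdt preprocessed dZ/dt vector.
#' @param partition a [partition_cycles()] result.
#' @param cpoints a [detect_c_points()] result.
#' @param fs sampling rate in Hz.
#' @param method one of the keys above.
#' @return A `bpoint_result` data.frame: `cycle_id`, 0-based `b_point`,
#'   `reason`.
#' @export
detect_b_points <- function(dzdt, partition, cpoints, fs,
                            method = c("ste85", "she90", "deb93sd", "loz07lr",
                                       "loz07qr", "arb17ic", "arb17sd", "arb17td",
                                       "for18", "pal21", "dro22", "mil22")) {
  method <- match.arg(method)
  switch(method,
    ste85 = bpoint_extremum_family(dzdt, partition, cpoints, fs, "ste85"),
    she90 = bpoint_extremum_family(dzdt, partition, cpoints, fs, "she90"),
    deb93sd = bpoint_extremum_family(dzdt, partition, cpoints, fs, "deb93sd"),
    arb17ic = bpoint_extremum_family(dzdt, partition, cpoints, fs, "arb17ic"),
    arb17sd = bpoint_extremum_family(dzdt, partition, cpoints, fs, "arb17sd"),
    arb17td = bpoint_extremum_family(dzdt, partition, cpoints, fs, "arb17td"),
    loz07lr = bpoint_lozano(partition, cpoints, fs, form = "linear"),
    loz07qr = bpoint_lozano(partition, cpoints, fs, form = "quadratic"),
    for18 = bpoint_forouzanfar(dzdt, partition, cpoints, fs),
    pal21 = bpoint_pale(dzdt, partition, cpoints, fs),
    dro22 = bpoint_drost(dzdt, partition, cpoints, fs),
    mil22 = bpoint_miljkovic(dzdt, partition, cpoints, fs)
  )
}

#' @rdname detect_b_points
#' @export
bpoint_extremum_family <- function(dzdt, partition, cpoints, fs,
                                   method = c("ste85", "she90", "deb93sd",
                                              "arb17ic", "arb17sd", "arb17td")) {
  method <- match.arg(method)
  n <- length(dzdt)
  sig <- switch(method,
    deb93sd = , arb17sd = differentiate(dzdt, fs, 2L),
    arb17td = differentiate(dzdt, fs, 3L),
    dzdt)
  nc <- nrow(partition)
  b <- rep(NA_integer_, nc)
  reason <- rep(NA_character_, nc)
  for (i in seq_len(nc)) {
    c0 <- cpoints$c_point[i]
    if (is.na(c0)) { reason[i] <- "NoC"; next }
    if (method %in% c("ste85", "she90", "deb93sd", "arb17ic")) {
      win <- pre_c_window(partition, i, c0, n)
      if (length(win) < 2L) { reason[i] <- "InvBWindow"; next }
      seg <- sig[win]
      if (method == "ste85" || method == "deb93sd") {
        m <- local_minima(seg)
        if (length(m) == 0L) { reason[i] <- "NoLocMin"; next }
        b[i] <- win[m[length(m)]] - 1L
      } else if (method == "she90") {
        z <- last_upward_zero_crossing(seg)
        if (is.na(z)) { reason[i] <- "NoZCross"; next }
        b[i] <- win[z] - 1L
      } else { # arb17ic: last upward crossing through the within-cycle mean
        cyc <- clip_window(partition$start[i] + 1L, partition$end[i] + 1L, n)
        z <- last_upward_zero_crossing(seg - mean(dzdt[cyc]))
        if (is.na(z)) { reason[i] <- "NoIsoCross"; next }
        b[i] <- win[z] - 1L
      }
    } else if (method == "arb17sd") {
      lo <- c0 - ms_to_samples(150, fs); hi <- c0 - ms_to_samples(100, fs)
      win <- clip_window(max(lo, partition$start[i]) + 1L, hi + 2L, n) # closed window
      win <- win[win <= c0]
      if (length(win) < 2L) { reason[i] <- "InvBWindow"; next }
      b[i] <- win[which.max(sig[win])] - 1L
    } else { # arb17td
      lo <- c0 - ms_to_samples(300, fs)
      win <- clip_window(max(lo, partition$start[i]) + 1L, c0 + 1L, n)
      if (length(win) < 2L) { reason[i] <- "InvBWindow"; next }
      b[i] <- win[which.max(sig[win])] - 1L
    }
  }
  bpoint_result(partition, b, reason)
}

#' @rdname detect_b_points
#' @param form `"linear"` or `"quadratic"` regression form.
#' @export
bpoint_lozano <- function(partition, cpoints, fs, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  nc <- nrow(partition)
  b <- rep(NA_integer_, nc)
  reason <- rep(NA_character_, nc)
  for (i in seq_len(nc)) {
    c0 <- cpoints$c_point[i]
    if (is.na(c0)) { reason[i] <- "NoC"; next }
    rc <- samples_to_ms(c0 - partition$r_peak[i], fs)
    b_ms <- lozano_b_ms(rc, form)
    cand <- partition$r_peak[i] + ms_to_samples(b_ms, fs)
    if (cand >= c0 || cand < partition$start[i]) { reason[i] <- "InvBWindow"; next }
    b[i] <- cand
  }
  bpoint_result(partition, b, reason)
}

#' Regression prediction of the R-to-B offset
#'
#' Fixed-coefficient regression of the B-point location (ms after the R-peak)
#' on the R--C interval: linear `0.55 * RC + 4.45`, quadratic
#' `-0.0032 * RC^2 + 1.233 * RC - 31.59`. The coefficients are constants from
#' the original regression models and are never refit.
#'
#' @param rc_ms R--C interval in ms.
#' @param form `"linear"` or `"quadratic"`.
#' @return Predicted R-to-B offset in ms.
#' @export
lozano_b_ms <- function(rc_ms, form = c("linear", "quadratic")) {
  form <- match.arg(form)
  if (form == "linear") 0.55 * rc_ms + 4.45
  else -0.0032 * rc_ms^2 + 1.233 * rc_ms - 31.59
}

#' @rdname detect_b_points
#' @export
bpoint_drost <- function(dzdt, partition, cpoints, fs) {
  n <- length(dzdt)
  nc <- nrow(partition)
  b <- rep(NA_integer_, nc)
  reason <- rep(NA_character_, nc)
  off <- ms_to_samples(150, fs)
  for (i in seq_len(nc)) {
    c0 <- cpoints$c_point[i]
    if (is.na(c0)) { reason[i] <- "NoC"; next }
    lo <- max(c0 - off, partition$start[i])
    win <- clip_window(lo + 1L, c0 + 2L, n)        # closed [lo, c]
    if (length(win) < 2L) { reason[i] <- "InvBWindow"; next }
    y0 <- dzdt[win[1]]; y1 <- dzdt[win[length(win)]]
    line <- y0 + (y1 - y0) * (seq_along(win) - 1L) / (length(win) - 1L)
    d <- line - dzdt[win]
    best <- max(which(d == max(d)))                 # ties -> latest index
    b[i] <- win[best] - 1L
  }
  bpoint_result(partition, b, reason)
}

#' @rdname detect_b_points
#' @export
bpoint_forouzanfar <- function(dzdt, partition, cpoints, fs) {
  n <- length(dzdt)
  d3 <- differentiate(dzdt, fs, 3L)
  nc <- nrow(partition)
  b <- rep(NA_integer_, nc)
  reason <- rep(NA_character_, nc)
  for (i in seq_len(nc)) {
    c0 <- cpoints$c_point[i]
    if (is.na(c0)) { reason[i] <- "NoC"; next }
    awin_lo <- max(c0 - partition$rr_prev[i] %/% 3L, partition$start[i])
    awin <- clip_window(awin_lo + 1L, c0 + 1L, n)
    if (length(awin) < 3L) { reason[i] <- "InvBWindow"; next }
    m <- local_minima(dzdt[awin])
    if (length(m) == 0L) { reason[i] <- "NoLocMin"; next }
    a1 <- awin[m[length(m)]]                        # A-point, 1-based
    seg <- clip_window(a1, c0 + 2L, n)              # [A, c] closed
    runs <- increasing_runs(dzdt[seg])
    if (nrow(runs) == 0L) { reason[i] <- "NoMonIncr"; next }
    # most significant: longest, ties by amplitude gain, then later onset
    len <- runs$to - runs$from
    gain <- dzdt[seg[runs$to]] - dzdt[seg[runs$from]]
    ord <- order(-len, -gain, -runs$from)
    run <- runs[ord[1L], ]
    third <- seg[run$from:(run$from + max(1L, (run$to - run$from) %/% 3L))]
    zc <- last_upward_zero_crossing(d3[third])
    if (!is.na(zc)) { b[i] <- third[zc] - 1L; next }
    mx <- local_maxima(d3[third])
    if (length(mx) > 0L) { b[i] <- third[mx[length(mx)]] - 1L; next }
    reason[i] <- "NoMonIncr"                        # fallback chain exhausted
  }
  bpoint_result(partition, b, reason)
}

# maximal strictly increasing runs of x; data.frame(from, to) of 1-based
# positions into x, only runs of length >= 2 samples
increasing_runs <- function(x) {
  up <- diff(x) > 0
  if (!any(up)) return(data.frame(from = integer(0), to = integer(0)))
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(from = starts[keep], to = ends[keep] + 1L)
}

#' @rdname detect_b_points
#' @export
bpoint_pale <- function(dzdt, partition, cpoints, fs) {
  n <- length(dzdt)
  nc <- nrow(partition)
  b <- rep(NA_integer_, nc)
  reason <- rep(NA_character_, nc)
  off <- ms_to_samples(150, fs)
  for (i in seq_len(nc)) {
    c0 <- cpoints$c_point[i]
    if (is.na(c0)) { reason[i] <- "NoC"; next }
    lo <- max(c0 - off, partition$start[i])
    win <- clip_window(lo + 1L, c0 + 1L, n)          # [lo, c)
    if (length(win) < 2L) { reason[i] <- "InvBWindow"; next }
    seg <- dzdt[win]
    # slope threshold scales with the C amplitude over the window span
    theta <- 0.5 * (dzdt[c0 + 1L] - min(seg)) / 150   # units per ms
    slope <- (seg[-1L] - seg[-length(seg)]) * fs / 1000
    found <- NA_integer_
    for (th in c(theta, theta / 2)) {
      m <- local_minima(seg)
      if (length(m) > 0L) { found <- m[length(m)]; break }   # closest to C
      s <- which(slope > th)
      if (length(s) > 0L) { found <- s[1L]; break }
    }
    if (is.na(found)) {
      full <- pre_c_window(partition, i, c0, n)
      b[i] <- full[which.min(dzdt[full])] - 1L       # stage-3 global minimum
    } else {
      b[i] <- win[found] - 1L
    }
  }
  bpoint_result(partition, b, reason)
}

#' @rdname detect_b_points
#' @param weight optional weight function of `k/N` on `[0, 1]`; default the
#'   quadratic ramp `(k/N)^2`.
#' @export
bpoint_miljkovic <- function(dzdt, partition, cpoints, fs,
                             weight = function(u) u^2) {
  n <- length(dzdt)
  nc <- nrow(partition)
  b <- rep(NA_integer_, nc)
  reason <- rep(NA_character_, nc)
  off <- ms_to_samples(300, fs)
  for (i in seq_len(nc)) {
    c0 <- cpoints$c_point[i]
    if (is.na(c0)) { reason[i] <- "NoC"; next }
    lo <- max(c0 - off, partition$start[i])
    win <- clip_window(lo + 1L, c0 + 1L, n)
    if (length(win) < 2L) { reason[i] <- "InvBWindow"; next }
    y <- weight(seq_along(win) / length(win)) * dzdt[win]
    m <- local_minima(y)
    b[i] <- if (length(m) > 0L) win[m[length(m)]] - 1L else win[which.min(y)] - 1L
  }
  bpoint_result(partition, b, reason)
}
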