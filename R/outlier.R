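# B-point outlier detection and correction.
#
# The beat series holds B-point times (ms from recording start) per cardiac
# cycle, with R-peak times as beat timestamps. Outliers are detected on the
# *stationarized* series (original minus 0.1 Hz low-pass) with the 3-MAD rule
# and corrected by linear interpolation or forward/backward autoregression;
# a dummy corrector passes data through unchanged.

#' Beat-to-beat B-point series
#'
#' @param b_time_ms B-point times in ms from recording start (NA = missing).
#' @param beat_time_ms R-peak times in ms (strictly increasing).
#' @return A `beat_series` data.frame with columns `beat_time_ms`,
#'   `b_time_ms`, `valid`.
#' @export
beat_series <- function(b_time_ms, beat_time_ms) {
  if (length(b_time_ms) != length(beat_time_ms))
    stop("lengths of `b_time_ms` and `beat_time_ms` differ", call. = FALSE)
  if (length(beat_time_ms) > 1L && any(diff(beat_time_ms) <= 0))
    stop("`beat_time_ms` must be strictly increasing", call. = FALSE)
  out <- data.frame(beat_time_ms = as.numeric(beat_time_ms),
                    b_time_ms = as.numeric(b_time_ms),
                    valid = !is.na(b_time_ms))
  class(out) <- c("beat_series", "data.frame")
  out
}

#' Stationarize a beat series
#'
#' Subtracts the 0.1 Hz fourth-order Butterworth low-pass of the B-point
#' series from the series itself, removing slow drift (posture, respiration,
#' tonic autonomic shifts) while preserving beat-scale spikes. The beat series
#' is treated as uniformly sampled at `1 / mean(RR)` Hz; missing beats are
#' filled by linear interpolation before filtering and restored to missing
#' afterwards. With fewer than `min_beats` valid beats the series is returned
#' unfiltered with attribute `passthrough = TRUE`.
#'
#' @param series a [beat_series()].
#' @param min_beats minimum valid beats for the filter warm-up (default 8).
#' @return Numeric vector of detrended B-times (NA where the input was
#'   missing), with attribute `passthrough`.
#' @export
stationarize <- function(series, min_beats = 8L) {
  stopifnot(inherits(series, "beat_series"))
  x <- series$b_time_ms
  ok <- series$valid
  if (sum(ok) < min_beats) {
    out <- x - stats::median(x[ok])
    attr(out, "passthrough") <- TRUE
    return(out)
  }
  xi <- fill_linear(x, series$beat_time_ms)
  fs_beat <- 1000 / mean(diff(series$beat_time_ms))
  if (fs_beat / 2 <= 0.1) {
    out <- x - stats::median(x[ok])
    attr(out, "passthrough") <- TRUE
    return(out)
  }
  lp <- signal::butter(4, 0.1 / (fs_beat / 2), type = "low")
  # remove the offset and reflect-pad before filtering so that filtfilt edge
  # transients cannot masquerade as outliers
  np <- length(xi)
  mu <- stats::median(xi)
  x0 <- xi - mu
  pad <- min(np - 1L, max(30L, as.integer(ceiling(10 * fs_beat / 0.1))))
  xp <- c(2 * x0[1] - x0[(pad + 1L):2L], x0, 2 * x0[np] - x0[(np - 1L):(np - pad)])
  trend <- signal::filtfilt(lp, xp)[(pad + 1L):(pad + np)] + mu
  out <- x - trend
  attr(out, "passthrough") <- FALSE
  out
}

fill_linear <- function(x, t) {
  ok <- !is.na(x)
  if (all(ok)) return(x)
  if (sum(ok) == 0L) return(rep(0, length(x)))
  if (sum(ok) == 1L) return(rep(x[ok], length(x)))
  stats::approx(t[ok], x[ok], xout = t, rule = 2)$y
}

#' Detect B-point outliers with the 3-MAD rule
#'
#' A beat is an outlier when its stationarized B-value lies more than three
#' times the median absolute deviation from the median of the stationarized
#' series. The MAD is unscaled (no 1.4826 normal-consistency factor). A
#' constant series (MAD = 0) yields no outliers.
#'
#' @param detrended numeric vector from [stationarize()] (NAs allowed).
#' @return Logical mask, `NA` positions are `FALSE`.
#' @export
detect_outliers <- function(detrended) {
  x <- as.numeric(detrended)
  ok <- !is.na(x)
  mask <- rep(FALSE, length(x))
  if (sum(ok) == 0L) return(mask)
  med <- stats::median(x[ok])
  mad0 <- stats::median(abs(x[ok] - med))
  # plain rule, no special-casing: with MAD = 0 any deviation from the median
  # exceeds 3 MAD, and an all-constant series flags nothing
  mask[ok] <- abs(x[ok] - med) > 3 * mad0
  mask
}

#' Correct B-point outliers
#'
#' `correct_linear()` replaces each flagged (or, optionally, missing) beat by
#' linear interpolation between the nearest unflagged beats in beat time; edge
#' outliers copy the nearest unflagged value. `correct_autoregressive()`
#' replaces each flagged beat by the average of a forward AR(p) prediction
#' (least-squares fit on up to `context` preceding clean beats) and a backward
#' AR(p) prediction on the time-reversed following beats; one-sided when only
#' one side has enough context, linear fallback when neither does.
#' `correct_dummy()` returns the series unchanged. No corrector ever modifies
#' an unflagged beat.
#'
#' @param series a [beat_series()].
#' @param mask logical outlier mask from [detect_outliers()].
#' @param interpolate_missing also fill beats with missing B-points (default
#'   `TRUE`; this is how correction can reduce the number of invalid PEPs).
#' @return A corrected [beat_series()]; replaced positions are recorded in
#'   attribute `corrected`.
#' @export
correct_linear <- function(series, mask, interpolate_missing = TRUE) {
  stopifnot(inherits(series, "beat_series"), length(mask) == nrow(series))
  bad <- mask | (interpolate_missing & !series$valid)
  good <- !bad & series$valid
  out <- series
  if (!any(bad) || !any(good)) {
    attr(out, "corrected") <- rep(FALSE, nrow(series))
    return(out)
  }
  t <- series$beat_time_ms
  out$b_time_ms[bad] <- stats::approx(t[good], series$b_time_ms[good],
                                      xout = t[bad], rule = 2)$y
  out$valid <- !is.na(out$b_time_ms)
  attr(out, "corrected") <- bad
  out
}

#' @rdname correct_linear
#' @param p autoregressive order (default 4).
#' @param context maximum clean beats used to fit each AR model (default 30).
#' @export
correct_autoregressive <- function(series, mask, p = 4L, context = 30L,
                                   interpolate_missing = TRUE) {
  stopifnot(inherits(series, "beat_series"), length(mask) == nrow(series))
  bad <- which(mask | (interpolate_missing & !series$valid))
  good <- !(mask | !series$valid)
  out <- series
  attr(out, "corrected") <- rep(FALSE, nrow(series))
  if (length(bad) == 0L || sum(good) < 2L) return(out)
  x <- series$b_time_ms
  for (i in bad) {
    pre <- x[seq_len(i - 1L)][good[seq_len(i - 1L)]]
    post <- if (i < length(x)) rev(x[(i + 1L):length(x)][good[(i + 1L):length(x)]]) else numeric(0)
    fwd <- ar_predict_next(utils::tail(pre, context), p)
    bwd <- ar_predict_next(utils::tail(post, context), p)
    est <- mean(c(fwd, bwd), na.rm = TRUE)
    if (is.nan(est)) {  # neither side usable: linear fallback
      t <- series$beat_time_ms
      g <- which(good)
      est <- if (length(g) >= 2L) stats::approx(t[g], x[g], xout = t[i], rule = 2)$y
             else x[g][1]
    }
    out$b_time_ms[i] <- est
    attr(out, "corrected")[i] <- TRUE
  }
  out$valid <- !is.na(out$b_time_ms)
  out
}

# one-step AR(p) least-squares prediction from the end of `ctx`;
# NA when the context is too short. Collinear lag columns (e.g. noiseless
# low-order processes) get zero coefficients via rank-revealing lm.fit.
ar_predict_next <- function(ctx, p) {
  n <- length(ctx)
  if (n < p + 1L) {
    if (n == 0L) return(NA_real_)
    return(ctx[n])  # too short to fit: persistence forecast
  }
  m <- n - p
  y <- ctx[(p + 1L):n]
  X <- sapply(seq_len(p), function(k) ctx[(p + 1L - k):(n - k)])
  X <- matrix(X, nrow = m)
  fit <- stats::lm.fit(X, y)
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  sum(beta * ctx[n - seq_len(p) + 1L])
}

#' @rdname correct_linear
#' @export
correct_dummy <- function(series, mask) {
  out <- series
  attr(out, "corrected") <- rep(FALSE, nrow(series))
  out
}
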