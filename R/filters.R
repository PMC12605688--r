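# Preprocessing filters and derivative estimation.
#
# Band-pass filtering is realized as a same-order high-pass + low-pass cascade
# rather than a single transfer-function band-pass: with a 0.67 Hz lower edge
# at fs = 1000 Hz the direct band-pass polynomial is numerically unstable,
# while the cascade is well conditioned and has the same nominal passband.
# All filters run forward-backward (filtfilt), i.e. zero-phase: causal
# filtering would delay fiducial points and bias PEP.

butter_bandpass <- function(x, fs, low, high, order) {
  nyq <- fs / 2
  if (high >= nyq) stop("configuration error: fs too low for ", high, " Hz cutoff",
                        call. = FALSE)
  x <- sos_filtfilt(x, order, low / nyq, "high")
  sos_filtfilt(x, order, high / nyq, "low")
}

# Butterworth low/high-pass realized as cascaded first/second-order sections
# (per-pole-pair bilinear transform). The expanded transfer-function
# polynomial of a high-order filter with a near-DC edge (0.67 Hz at 1000 Hz)
# is numerically unstable; biquad sections are not.
butter_sections <- function(order, w, type = c("low", "high")) {
  type <- match.arg(type)
  k <- seq_len(order)
  pa <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # prototype poles, LHP
  wc <- tan(pi * w / 2)                                    # prewarped cutoff
  pa <- if (type == "low") wc * pa else wc / pa
  zp <- (1 + pa) / (1 - pa)                                # bilinear poles
  zz <- if (type == "low") -1 else 1                       # bilinear zeros
  zref <- if (type == "low") 1 else -1                     # unit-gain reference
  polyval <- function(cf, z) sum(cf * z^(rev(seq_along(cf)) - 1))
  secs <- list()
  used <- rep(FALSE, order)
  for (i in k) {
    if (used[i]) next
    if (abs(Im(pa[i])) < 1e-12 * max(1, abs(Re(pa[i])))) {
      a <- c(1, -Re(zp[i])); b <- c(1, -zz)
      used[i] <- TRUE
    } else {
      j <- which(!used & seq_len(order) != i &
                   abs(pa - Conj(pa[i])) < 1e-9 * abs(pa[i]))[1]
      a <- c(1, -2 * Re(zp[i]), abs(zp[i])^2)
      b <- c(1, -2 * zz, zz^2)
      used[c(i, j)] <- TRUE
    }
    g <- Re(polyval(a, zref) / polyval(b, zref))
    secs[[length(secs) + 1L]] <- list(b = b * g, a = a)
  }
  secs
}

sos_filtfilt <- function(x, order, w, type) {
  n <- length(x)
  mu <- 0
  if (type == "high") {  # DC never passes; removing it first kills the
    mu <- mean(x)        # dominant start-up transient exactly
    x <- x - mu
  }
  # odd-reflection padding long enough to absorb the start-up transient of the
  # slowest pole (time constant ~ 1/(pi w) samples); filtfilt itself starts
  # from zero initial conditions
  pad <- min(n - 1L, as.integer(ceiling(6 / (pi * w))))
  xp <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  for (s in butter_sections(order, w, type)) {
    xp <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), xp)
  }
  xp[(pad + 1L):(pad + n)]
}

#' Preprocess raw ECG / dZ/dt signals
#'
#' Zero-phase Butterworth band-pass filtering with the conventional passbands
#' for cardiac work: ECG 0.67--45 Hz (5th order), dZ/dt 0.5--25 Hz (4th
#' order). Removes baseline drift and powerline interference while leaving the
#' QRS complex and the systolic dZ/dt wave intact.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz; must exceed twice the upper cutoff.
#' @return Filtered signal, same length as the input.
#' @export
preprocess_ecg <- function(x, fs) {
  assert_scalar_numeric(fs, "fs", lower = 90)
  butter_bandpass(as.numeric(x), fs, 0.67, 45, order = 5)
}

#' @rdname preprocess_ecg
#' @export
preprocess_dzdt <- function(x, fs) {
  assert_scalar_numeric(fs, "fs", lower = 50)
  butter_bandpass(as.numeric(x), fs, 0.5, 25, order = 4)
}

moving_average <- function(x, w) {
  if (w < 2L) return(x)
  k <- rep(1 / w, w)
  # centered MA with edge replication to keep length and avoid edge collapse
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], w - 1L - pad))
  as.numeric(stats::filter(xp, k, sides = 1))[w:(length(xp))][seq_along(x)]
}

#' Estimate signal derivatives
#'
#' Central-difference derivative of order 1--3 in units/s^order. The signal is
#' smoothed with a short moving average (window `round(5 * fs / 1000)` samples,
#' minimum 3) before each differencing pass; repeated raw differencing of
#' 500--1000 Hz signals amplifies noise enough to destroy the third-derivative
#' extrema that several B-point detectors search for.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param order derivative order, 1, 2 or 3.
#' @return Numeric vector, same length as `x` (one-sided differences at the
#'   edges).
#' @export
differentiate <- function(x, fs, order = 1L) {
  order <- as.integer(order)
  if (!order %in% 1:3) stop("`order` must be 1, 2 or 3", call. = FALSE)
  x <- as.numeric(x)
  if (length(x) <= 2L * order) stop("length error: signal too short to differentiate",
                                    call. = FALSE)
  w <- max(3L, as.integer(round(5 * fs / 1000)))
  for (k in seq_len(order)) {
    x <- moving_average(x, w)
    x <- central_diff(x) * fs
  }
  x
}

central_diff <- function(x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / 2
  d[1] <- x[2] - x[1]
  d[n] <- x[n] - x[n - 1L]
  d
}
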