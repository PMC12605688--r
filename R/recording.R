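#' Synchronized ECG + dZ/dt recording
#'
#' Container for one recording: an ECG channel (typically mV) and the first
#' derivative of the thoracic impedance signal (dZ/dt, Ohm/s), together with
#' their sampling rates and optional grouping metadata (participant, condition,
#' phase). Channels with different sampling rates are harmonized by resampling
#' the higher-rate channel down to the lower rate, so that downstream modules
#' can assume a single sampling rate.
#'
#' @param ecg numeric vector of ECG samples.
#' @param dzdt numeric vector of dZ/dt samples.
#' @param fs_ecg,fs_dzdt sampling rates in Hz.
#' @param participant,condition,phase optional metadata labels.
#' @param harmonize if `TRUE` (default) and the rates differ, the higher-rate
#'   channel is resampled down with a polyphase rational resampler.
#' @return An object of class `pep_recording` with elements `ecg`, `dzdt`,
#'   `fs` (the common rate after harmonization) and a `meta` list.
#' @examples
#' rec <- pep_recording(sin(seq(0, 2, by = 1e-3)), cos(seq(0, 2, by = 1e-3)),
#'                      fs_ecg = 1000, fs_dzdt = 1000)
#' rec
#' @export
pep_recording <- function(ecg, dzdt, fs_ecg, fs_dzdt = fs_ecg,
                          participant = NA_character_, condition = NA_character_,
                          phase = NA_character_, harmonize = TRUE) {
  ecg <- as.numeric(ecg)
  dzdt <- as.numeric(dzdt)
  if (anyNA(ecg) || any(!is.finite(ecg))) stop("non-finite sample in `ecg`", call. = FALSE)
  if (anyNA(dzdt) || any(!is.finite(dzdt))) stop("non-finite sample in `dzdt`", call. = FALSE)
  assert_scalar_numeric(fs_ecg, "fs_ecg", lower = 1e-9)
  assert_scalar_numeric(fs_dzdt, "fs_dzdt", lower = 1e-9)
  if (harmonize && fs_ecg != fs_dzdt) {
    fs <- min(fs_ecg, fs_dzdt)
    if (fs_ecg > fs) ecg <- resample_signal(ecg, fs_ecg, fs)
    if (fs_dzdt > fs) dzdt <- resample_signal(dzdt, fs_dzdt, fs)
    fs_ecg <- fs_dzdt <- fs
    nmin <- min(length(ecg), length(dzdt))  # rational resampling can differ by 1
    ecg <- ecg[seq_len(nmin)]; dzdt <- dzdt[seq_len(nmin)]
  }
  structure(
    list(ecg = ecg, dzdt = dzdt, fs = fs_ecg,
         meta = list(participant = participant, condition = condition, phase = phase)),
    class = "pep_recording"
  )
}

#' @export
print.pep_recording <- function(x, ...) {
  cat(sprintf("<pep_recording>  %d samples @ %g Hz (%.1f s)\n",
              length(x$ecg), x$fs, length(x$ecg) / x$fs))
  m <- x$meta
  lab <- m[!vapply(m, function(v) is.na(v) || !nzchar(v), logical(1))]
  if (length(lab)) cat("  ", paste(names(lab), unlist(lab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Zero-phase downsampling: anti-alias Butterworth low-pass (forward-backward,
# so no group delay to bias fiducial timings) followed by cubic-spline
# evaluation on the target grid.
resample_signal <- function(x, fs_from, fs_to) {
  stopifnot(fs_to <= fs_from)
  y <- sos_filtfilt(x, order = 8, w = 0.9 * fs_to / fs_from, type = "low")
  n_to <- as.integer(floor(length(x) * fs_to / fs_from))
  t_from <- (seq_along(x) - 1L) / fs_from
  stats::spline(t_from, y, xout = (seq_len(n_to) - 1L) / fs_to,
                method = "fmm")$y
}

#' Read a recording from a signal CSV
#'
#' Expects a columnar text file with named ECG and dZ/dt columns (defaults
#' `ecg` and `dzdt`; a time column is ignored). Sampling rates are given either
#' as arguments or in the `layout` list. When the two rates differ, the
#' higher-rate channel is resampled down so both channels share the lower rate.
#'
#' @param path path to a CSV file.
#' @param fs_ecg,fs_dzdt sampling rates in Hz (required; a missing rate is a
#'   format error).
#' @param layout list with optional `ecg_col` / `dzdt_col` column names.
#' @inheritParams pep_recording
#' @return A [pep_recording()].
#' @export
load_recording <- function(path, fs_ecg = NULL, fs_dzdt = fs_ecg,
                           layout = list(), participant = NA_character_,
                           condition = NA_character_, phase = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("format error: empty signal file ", path, call. = FALSE)
  ecg_col <- layout$ecg_col %||% "ecg"
  dzdt_col <- layout$dzdt_col %||% "dzdt"
  for (col in c(ecg_col, dzdt_col)) {
    if (!col %in% names(df)) stop("format error: missing column `", col, "`", call. = FALSE)
    if (!is.numeric(df[[col]])) stop("format error: non-numeric sample in `", col, "`", call. = FALSE)
  }
  if (is.null(fs_ecg)) stop("format error: sampling rate `fs_ecg` absent", call. = FALSE)
  if (is.null(fs_dzdt)) fs_dzdt <- fs_ecg
  pep_recording(df[[ecg_col]], df[[dzdt_col]], fs_ecg, fs_dzdt,
                participant = participant, condition = condition, phase = phase)
}

#' Write a recording to a signal CSV
#'
#' Columns `t_s, ecg, dzdt`, the dialect read back by [load_recording()].
#'
#' @param rec a [pep_recording()].
#' @param path output path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "pep_recording"))
  n <- length(rec$ecg)
  df <- data.frame(t_s = (seq_len(n) - 1L) / rec$fs, ecg = rec$ecg, dzdt = rec$dzdt)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-cycle annotation tables
#'
#' Annotation CSVs have columns
#' `cycle_id,start,r_peak,end,q_peak,b_point,artifact,participant,condition,phase`;
#' all sample indices are 0-based and an empty cell means missing.
#'
#' @param path CSV path.
#' @return A data.frame with those columns (`artifact` logical).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("cycle_id", "start", "r_peak", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column `", miss[1], "`", call. = FALSE)
  for (col in c("q_peak", "b_point", "artifact", "participant", "condition", "phase"))
    if (!col %in% names(df)) df[[col]] <- NA
  df$artifact <- as.logical(df$artifact) %in% TRUE
  df
}

#' @rdname read_annotations
#' @param ann annotation data.frame.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(ann, path, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
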