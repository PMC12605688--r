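# Pipeline composition: Q-peak + B-point + outlier correction -> PEP.

#' Configure a PEP extraction pipeline
#'
#' A pipeline is the combination of one Q-peak extraction algorithm, one
#' B-point extraction algorithm and an outlier-correction stage, plus the
#' policy for negative PEP values (a B-point detected before the Q-peak).
#'
#' @param q_method `"van13"`, `"for18"` or `"mar04"`.
#' @param b_method one of the twelve keys of [detect_b_points()].
#' @param outlier `"none"` (dummy pass-through), `"linint"` (linear
#'   interpolation) or `"for18ar"` (forward/backward autoregression).
#' @param q_params list of Q-stage parameters (`t_ms` for van13,
#'   `scaling_factor` for for18).
#' @param neg_pep `"nan"` (negative PEP becomes missing, the default) or
#'   `"zero"` (set to 0 ms).
#' @param interpolate_missing should the outlier-correction stage also fill
#'   cycles whose B-point is missing (default `TRUE`)?
#' @return A `pep_pipeline` config list.
#' @export
pep_pipeline <- function(q_method = c("van13", "for18", "mar04"),
                         b_method = "dro22",
                         outlier = c("none", "linint", "for18ar"),
                         q_params = list(),
                         neg_pep = c("nan", "zero"),
                         interpolate_missing = TRUE) {
  q_method <- match.arg(q_method)
  outlier <- match.arg(outlier)
  neg_pep <- match.arg(neg_pep)
  b_method <- match.arg(b_method, c("ste85", "she90", "deb93sd", "loz07lr",
                                    "loz07qr", "arb17ic", "arb17sd", "arb17td",
                                    "for18", "pal21", "dro22", "mil22"))
  structure(list(q_method = q_method, b_method = b_method, outlier = outlier,
                 q_params = q_params, neg_pep = neg_pep,
                 interpolate_missing = interpolate_missing),
            class = "pep_pipeline")
}

#' @export
print.pep_pipeline <- function(x, ...) {
  qp <- if (length(x$q_params)) {
    paste0("(", paste(names(x$q_params), unlist(x$q_params), sep = "=", collapse = ", "), ")")
  } else ""
  cat(sprintf("<pep_pipeline> %s%s + %s + %s  [neg_pep=%s]\n",
              x$q_method, qp, x$b_method, x$outlier, x$neg_pep))
  invisible(x)
}

#' Compute PEP from fiducial indices
#'
#' `PEP = (b_point - q_peak) / fs * 1000` ms. When the B-point precedes the
#' Q-peak the result is negative; policy `"nan"` turns it into a missing value
#' with reason `NegPEP`, policy `"zero"` reports 0 ms.
#'
#' @param q_peak,b_point 0-based sample indices (NA allowed).
#' @param fs sampling rate in Hz.
#' @param neg_pep `"nan"` or `"zero"`.
#' @return List with `pep_ms` and `reason` vectors.
#' @export
compute_pep <- function(q_peak, b_point, fs, neg_pep = c("nan", "zero")) {
  neg_pep <- match.arg(neg_pep)
  pep <- (b_point - q_peak) * 1000 / fs
  reason <- rep(NA_character_, length(pep))
  neg <- !is.na(pep) & pep <= 0
  if (neg_pep == "nan") {
    pep[neg] <- NA_real_
    reason[neg] <- "NegPEP"
  } else {
    pep[neg] <- 0
  }
  list(pep_ms = pep, reason = reason)
}

#' Run a PEP extraction pipeline on a recording
#'
#' Stages: preprocess both channels, detect R-peaks, partition into cardiac
#' cycles, detect C-points, extract Q-peaks and B-points independently, apply
#' outlier correction to the B-point beat series, compute per-cycle PEP. A
#' reference annotation table can replace either fiducial stream
#' (`inject = "q"` or `"b"`), enabling isolated evaluation of the other
#' algorithm; annotation rows are matched to detected cycles via R-peak
#' proximity (50 ms).
#'
#' @param rec a [pep_recording()].
#' @param config a [pep_pipeline()].
#' @param reference optional annotation data.frame (see [read_annotations()]).
#' @param inject `"none"`, `"q"` or `"b"`: which fiducial stream to take from
#'   `reference`.
#' @param r_peak_fun R-peak detector, a `function(ecg, fs)` returning 0-based
#'   indices; defaults to [detect_r_peaks()].
#' @param preprocess apply the band-pass filters (default `TRUE`; set `FALSE`
#'   if the channels are already filtered).
#' @return A list of class `pep_result`: `pep` (data.frame with `cycle_id`,
#'   `start`, `r_peak`, `end`, `q_peak`, `c_point`, `b_point`, `pep_ms`,
#'   `valid`, `reason`), plus intermediates `partition`, `cpoints`, `qres`,
#'   `bres`, `outlier_mask`, and `config`.
#' @export
run_pipeline <- function(rec, config, reference = NULL,
                         inject = c("none", "q", "b"),
                         r_peak_fun = detect_r_peaks, preprocess = TRUE) {
  stopifnot(inherits(rec, "pep_recording"), inherits(config, "pep_pipeline"))
  inject <- match.arg(inject)
  fs <- rec$fs
  ecg <- if (preprocess) preprocess_ecg(rec$ecg, fs) else rec$ecg
  dzdt <- if (preprocess) preprocess_dzdt(rec$dzdt, fs) else rec$dzdt

  r_peaks <- r_peak_fun(ecg, fs)
  partition <- partition_cycles(r_peaks, fs, n_samples = length(ecg))
  if (nrow(partition) == 0L) return(empty_pep_result(config))

  cpoints <- detect_c_points(dzdt, partition, fs)

  qres <- if (inject == "q") {
    inject_fiducial(partition, reference, "q_peak", fs)
  } else {
    switch(config$q_method,
      van13 = qpeak_van_lien(partition, fs,
                             t_ms = config$q_params$t_ms %||% 40),
      for18 = qpeak_forouzanfar(ecg, partition, fs,
                                scaling_factor = config$q_params$scaling_factor %||% 2000),
      mar04 = qpeak_martinez_dwt(ecg, partition, fs))
  }

  bres <- if (inject == "b") {
    inject_fiducial(partition, reference, "b_point", fs)
  } else {
    detect_b_points(dzdt, partition, cpoints, fs, method = config$b_method)
  }

  # outlier correction on the B-point beat series. The corrected quantity is
  # the R-anchored B offset (ms): interpolation between neighbouring beats and
  # the edge-copy rule are only meaningful on a stationary series, not on
  # absolute recording time.
  series <- beat_series(samples_to_ms(bres$b_point - partition$r_peak, fs),
                        samples_to_ms(partition$r_peak, fs))
  mask <- detect_outliers(stationarize(series))
  corrected <- switch(config$outlier,
    none = correct_dummy(series, mask),
    linint = correct_linear(series, mask,
                            interpolate_missing = config$interpolate_missing),
    for18ar = correct_autoregressive(series, mask,
                                     interpolate_missing = config$interpolate_missing))
  b_corr <- ifelse(is.na(corrected$b_time_ms), NA_integer_,
                   as.integer(partition$r_peak +
                                round(corrected$b_time_ms * fs / 1000)))
  b_reason <- bres$reason
  b_reason[!is.na(b_corr)] <- NA_character_   # correction restored these

  pp <- compute_pep(qres$q_peak, b_corr, fs, neg_pep = config$neg_pep)
  reason <- pp$reason
  q_missing <- is.na(qres$q_peak) & is.na(reason)
  reason[q_missing] <- ifelse(is.na(qres$reason[q_missing]), "NoQ",
                              qres$reason[q_missing])
  b_missing <- is.na(b_corr) & is.na(reason) & !q_missing
  reason[b_missing] <- b_reason[b_missing]
  valid <- !is.na(pp$pep_ms)

  pep <- data.frame(cycle_id = partition$cycle_id, start = partition$start,
                    r_peak = partition$r_peak, end = partition$end,
                    q_peak = qres$q_peak, c_point = cpoints$c_point,
                    b_point = b_corr, pep_ms = pp$pep_ms,
                    valid = valid, reason = reason, stringsAsFactors = FALSE)
  structure(list(pep = pep, partition = partition, cpoints = cpoints,
                 qres = qres, bres = bres, outlier_mask = mask, config = config),
            class = "pep_result")
}

empty_pep_result <- function(config) {
  pep <- data.frame(cycle_id = integer(0), start = integer(0), r_peak = integer(0),
                    end = integer(0), q_peak = integer(0), c_point = integer(0),
                    b_point = integer(0), pep_ms = numeric(0), valid = logical(0),
                    reason = character(0), stringsAsFactors = FALSE)
  structure(list(pep = pep, partition = NULL, cpoints = NULL, qres = NULL,
                 bres = NULL, outlier_mask = logical(0), config = config),
            class = "pep_result")
}

#' @export
print.pep_result <- function(x, ...) {
  print(x$config)
  n <- nrow(x$pep)
  nv <- sum(x$pep$valid)
  cat(sprintf("  %d cycles, %d valid PEP (%.1f%%)", n, nv, if (n) 100 * nv / n else 0))
  if (nv) cat(sprintf(", mean PEP %.1f ms", mean(x$pep$pep_ms, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

# replace a fiducial stream with annotated values, matched by R-peak proximity
inject_fiducial <- function(partition, reference, field, fs, tol_ms = 50) {
  if (is.null(reference)) stop("`reference` required for fiducial injection", call. = FALSE)
  tol <- ms_to_samples(tol_ms, fs)
  val <- rep(NA_integer_, nrow(partition))
  for (i in seq_len(nrow(partition))) {
    d <- abs(reference$r_peak - partition$r_peak[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tol && !isTRUE(reference$artifact[j])) {
      v <- reference[[field]][j]
      if (!is.na(v)) val[i] <- as.integer(v)
    }
  }
  out <- data.frame(cycle_id = partition$cycle_id, val = val,
                    reason = ifelse(is.na(val), "NoRef", NA_character_),
                    stringsAsFactors = FALSE)
  names(out)[2] <- field
  if (field == "b_point") {
    names(out)[2] <- "b_point"
    class(out) <- c("bpoint_result", "data.frame")
  } else {
    names(out)[2] <- "q_peak"
    class(out) <- c("qpeak_result", "data.frame")
  }
  out
}

#' Enumerate the benchmark pipeline grid
#'
#' Full Cartesian product of Q-peak methods x B-point methods x outlier
#' methods. With the fixed-offset Q method collapsed to a single entry the
#' default registry yields 3 x 12 x 3 = 108 pipelines; expanding it to its six
#' offsets (32--42 ms in 2 ms steps) yields 8 x 12 x 3 = 288.
#'
#' @param expand_van_lien expand the fixed-offset Q method over
#'   `t_ms = c(32, 34, 36, 38, 40, 42)`.
#' @param q_methods,b_methods,outlier_methods registry axes; defaults are the
#'   full benchmark.
#' @return A data.frame with one row per pipeline (`q_method`, `q_t_ms`,
#'   `b_method`, `outlier`) and an attribute-free `configs` list column is
#'   avoided; use [pep_pipeline()] on a row to instantiate.
#' @export
enumerate_pipelines <- function(expand_van_lien = FALSE,
                                q_methods = c("van13", "for18", "mar04"),
                                b_methods = c("ste85", "she90", "deb93sd",
                                              "loz07lr", "loz07qr", "arb17ic",
                                              "arb17sd", "arb17td", "for18",
                                              "pal21", "dro22", "mil22"),
                                outlier_methods = c("none", "linint", "for18ar")) {
  if (length(q_methods) == 0L || length(b_methods) == 0L || length(outlier_methods) == 0L) {
    return(data.frame(q_method = character(0), q_t_ms = numeric(0),
                      b_method = character(0), outlier = character(0)))
  }
  q <- data.frame(q_method = q_methods, q_t_ms = NA_real_)
  if (expand_van_lien && "van13" %in% q_methods) {
    keep <- q[q$q_method != "van13", , drop = FALSE]
    van <- data.frame(q_method = "van13", q_t_ms = c(32, 34, 36, 38, 40, 42))
    q <- rbind(van, keep)
  } else {
    q$q_t_ms[q$q_method == "van13"] <- 40
  }
  grid <- expand.grid(i = seq_len(nrow(q)), b_method = b_methods,
                      outlier = outlier_methods, stringsAsFactors = FALSE)
  out <- data.frame(q_method = q$q_method[grid$i], q_t_ms = q$q_t_ms[grid$i],
                    b_method = grid$b_method, outlier = grid$outlier,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
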