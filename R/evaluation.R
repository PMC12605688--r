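# Evaluation engine: cycle matching, error metrics, aggregation, ICC.

#' Match estimated to reference cardiac cycles
#'
#' Greedy one-to-one matching in time order: a detected cycle matches a
#' reference cycle when both its start and end borders lie within a 100 ms
#' tolerance centered on the reference borders, i.e. within +/- 50 ms each.
#' Unmatched estimated cycles are false positives (excluded downstream);
#' unmatched reference cycles are reported separately.
#'
#' @param ref annotation data.frame with 0-based `start`, `end`, `cycle_id`.
#' @param est a [partition_cycles()] result (or any table with those columns).
#' @param fs sampling rate in Hz.
#' @param tol_ms total border tolerance in ms (default 100).
#' @return List of class `match_result`: `pairs` (data.frame `ref_cycle_id`,
#'   `est_cycle_id`), `unmatched_ref`, `unmatched_est`.
#' @export
match_cycles <- function(ref, est, fs, tol_ms = 100) {
  half <- tol_ms / 2
  ref <- ref[order(ref$start), , drop = FALSE]
  est <- est[order(est$start), , drop = FALSE]
  nr <- nrow(ref); ne <- nrow(est)
  pairs_ref <- integer(0); pairs_est <- integer(0)
  i <- 1L; j <- 1L
  while (i <= nr && j <= ne) {
    ds <- samples_to_ms(est$start[j] - ref$start[i], fs)
    de <- samples_to_ms(est$end[j] - ref$end[i], fs)
    if (abs(ds) <= half && abs(de) <= half) {
      pairs_ref <- c(pairs_ref, ref$cycle_id[i])
      pairs_est <- c(pairs_est, est$cycle_id[j])
      i <- i + 1L; j <- j + 1L
    } else if (est$start[j] < ref$start[i]) {
      j <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(list(
    pairs = data.frame(ref_cycle_id = pairs_ref, est_cycle_id = pairs_est),
    unmatched_ref = setdiff(ref$cycle_id, pairs_ref),
    unmatched_est = setdiff(est$cycle_id, pairs_est)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d matched, %d unmatched reference (FN), %d unmatched estimated (FP)\n",
              nrow(x$pairs), length(x$unmatched_ref), length(x$unmatched_est)))
  invisible(x)
}

#' Per-cycle PEP errors
#'
#' For each matched cycle with a valid estimated PEP: error
#' `E = PEP_ref - PEP_est` (ms), absolute error `AE = |E|`, absolute relative
#' error `ARE = AE / PEP_ref` (stored as a fraction). Matched cycles whose
#' estimate is missing are counted invalid, with their reason codes; rows with
#' non-positive reference PEP are rejected with a data-quality flag.
#'
#' @param match a [match_cycles()] result.
#' @param ref annotation table with reference `q_peak` and `b_point` (0-based
#'   samples) or a `pep_ref_ms` column.
#' @param est_pep the `pep` data.frame of a [run_pipeline()] result.
#' @param fs sampling rate in Hz.
#' @param group optional data.frame of grouping keys aligned with `ref` rows
#'   (e.g. participant / condition / phase).
#' @return List of class `error_rows`: `rows` (data.frame with `pep_ref_ms`,
#'   `pep_est_ms`, `e_ms`, `ae_ms`, `are`, grouping keys), `invalid`
#'   (data.frame `ref_cycle_id`, `reason`), `n_rejected`.
#' @export
per_sample_errors <- function(match, ref, est_pep, fs, group = NULL) {
  pr <- match$pairs
  ref_idx <- match(pr$ref_cycle_id, ref$cycle_id)
  est_idx <- match(pr$est_cycle_id, est_pep$cycle_id)
  pep_ref <- if ("pep_ref_ms" %in% names(ref)) {
    ref$pep_ref_ms[ref_idx]
  } else {
    samples_to_ms(ref$b_point[ref_idx] - ref$q_peak[ref_idx], fs)
  }
  pep_est <- est_pep$pep_ms[est_idx]
  reason <- est_pep$reason[est_idx]

  bad_ref <- !is.na(pep_ref) & pep_ref <= 0
  usable <- !is.na(pep_ref) & !bad_ref
  invalid <- usable & is.na(pep_est)
  keep <- usable & !is.na(pep_est)

  rows <- data.frame(ref_cycle_id = pr$ref_cycle_id[keep],
                     est_cycle_id = pr$est_cycle_id[keep],
                     pep_ref_ms = pep_ref[keep], pep_est_ms = pep_est[keep])
  rows$e_ms <- rows$pep_ref_ms - rows$pep_est_ms
  rows$ae_ms <- abs(rows$e_ms)
  rows$are <- rows$ae_ms / rows$pep_ref_ms
  if (!is.null(group)) rows <- cbind(rows, group[ref_idx[keep], , drop = FALSE])
  structure(list(
    rows = rows,
    invalid = data.frame(ref_cycle_id = pr$ref_cycle_id[invalid],
                         reason = ifelse(is.na(reason[invalid]), "Unknown",
                                         reason[invalid])),
    n_rejected = sum(bad_ref)
  ), class = "error_rows")
}

#' Aggregate error metrics
#'
#' Two aggregation levels: *per datapoint* (all cycles sharing one set of
#' grouping keys, e.g. participant x condition x phase) -- ME / MAE / MARE are
#' means within each datapoint, then averaged across datapoints -- and *per
#' sample* -- mean and SD taken directly over all cycles, weighting every
#' cycle equally. Invalid PEPs are counted overall and per reason code.
#'
#' @param errors an [per_sample_errors()] result (or a plain data.frame of
#'   rows with `e_ms`, `ae_ms`, `are`).
#' @param by character vector of grouping columns present in the rows;
#'   `NULL` treats all rows as one datapoint.
#' @return List of class `aggregate_report`: `per_datapoint` (one row per
#'   datapoint), `datapoint_means` (ME/MAE/MARE averaged over datapoints),
#'   `per_sample` (mean and SD of E/AE/ARE over all cycles), `invalid`
#'   (`n_invalid`, `n_valid`, `n_total`, `per_reason`).
#' @export
aggregate_errors <- function(errors, by = NULL) {
  rows <- if (inherits(errors, "error_rows")) errors$rows else errors
  invalid <- if (inherits(errors, "error_rows")) errors$invalid
             else data.frame(ref_cycle_id = integer(0), reason = character(0))
  n <- nrow(rows)
  if (n == 0L) {
    return(structure(list(
      per_datapoint = data.frame(), datapoint_means = c(me_ms = NA_real_,
        mae_ms = NA_real_, mare = NA_real_),
      per_sample = data.frame(metric = c("e_ms", "ae_ms", "are"),
                              mean = NA_real_, sd = NA_real_, n = 0L),
      invalid = list(n_invalid = nrow(invalid), n_valid = 0L,
                     n_total = nrow(invalid),
                     per_reason = table(invalid$reason))
    ), class = "aggregate_report"))
  }
  key <- if (is.null(by)) rep("all", n) else interaction(rows[by], drop = TRUE)
  groups <- split(seq_len(n), key)
  per_dp <- do.call(rbind, lapply(names(groups), function(g) {
    ii <- groups[[g]]
    data.frame(datapoint = g, n = length(ii), me_ms = mean(rows$e_ms[ii]),
               mae_ms = mean(rows$ae_ms[ii]), mare = mean(rows$are[ii]))
  }))
  rownames(per_dp) <- NULL
  dp_means <- c(me_ms = mean(per_dp$me_ms), mae_ms = mean(per_dp$mae_ms),
                mare = mean(per_dp$mare))
  per_sample <- data.frame(
    metric = c("e_ms", "ae_ms", "are"),
    mean = c(mean(rows$e_ms), mean(rows$ae_ms), mean(rows$are)),
    sd = c(stats::sd(rows$e_ms), stats::sd(rows$ae_ms), stats::sd(rows$are)),
    n = n)
  structure(list(
    per_datapoint = per_dp, datapoint_means = dp_means, per_sample = per_sample,
    invalid = list(n_invalid = nrow(invalid), n_valid = n,
                   n_total = n + nrow(invalid),
                   per_reason = table(invalid$reason))
  ), class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat("<aggregate_report>\n")
  cat(sprintf("  per-sample:    MAE %.2f +/- %.2f ms, ME %.2f ms, MARE %.1f%% (n=%d)\n",
              x$per_sample$mean[2], x$per_sample$sd[2], x$per_sample$mean[1],
              100 * x$per_sample$mean[3], x$per_sample$n[1]))
  cat(sprintf("  per-datapoint: MAE %.2f ms over %d datapoints\n",
              x$datapoint_means[["mae_ms"]], nrow(x$per_datapoint)))
  cat(sprintf("  invalid: %d of %d cycles\n", x$invalid$n_invalid, x$invalid$n_total))
  invisible(x)
}

#' Intraclass correlation ICC(3,2)
#'
#' Two-way mixed-effects, absolute-agreement, average-measures intraclass
#' correlation for two fixed raters (McGraw & Wong A,k form), computed from
#' the two-way ANOVA mean squares, with an F-based 95 % confidence interval
#' (single-measures bounds transformed by the Spearman--Brown relation).
#'
#' @param rater1,rater2 paired numeric vectors (complete cases only are used;
#'   at least 5 required).
#' @param conf_level confidence level (default 0.95).
#' @return List with `icc`, `lower`, `upper`, `n`.
#' @export
icc_3_2 <- function(rater1, rater2, conf_level = 0.95) {
  ok <- stats::complete.cases(rater1, rater2)
  x <- cbind(as.numeric(rater1)[ok], as.numeric(rater2)[ok])
  n <- nrow(x); k <- 2
  if (n < 5L) stop("need at least 5 paired complete cases", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + msc + mse == 0) stop("zero variance: ICC undefined", call. = FALSE)
  denom1 <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom1 <= 0) stop("zero between-target variance: ICC undefined", call. = FALSE)
  icc1 <- (msr - mse) / denom1                       # ICC(A,1)
  icck <- (msr - mse) / (msr + (msc - mse) / n)      # ICC(A,k)

  if (mse == 0 || icc1 >= 1) {  # perfect agreement: degenerate CI
    return(list(icc = icck, lower = icck, upper = icck, n = n))
  }
  # F-based CI for ICC(A,1), Spearman-Brown to average measures
  alpha <- 1 - conf_level
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f1 * mse) / (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f2 * msr - mse) / (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)
  list(icc = icck, lower = sb(l1), upper = sb(u1), n = n)
}
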