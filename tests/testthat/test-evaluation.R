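test_that("cycle matching applies the centered 100 ms border tolerance", {
  ref <- data.frame(cycle_id = 1:3, start = c(0L, 1000L, 2000L),
                    end = c(1000L, 2000L, 3000L))
  m0 <- match_cycles(ref, ref, fs = 1000)
  expect_equal(nrow(m0$pairs), 3L)
  expect_length(m0$unmatched_ref, 0)
  est <- data.frame(cycle_id = 1:3, start = c(0L, 1049L, 2060L),
                    end = c(970L, 1970L, 3060L))
  m1 <- match_cycles(ref, est, fs = 1000)
  expect_true(all(c(1L, 2L) %in% m1$pairs$ref_cycle_id))  # +49/-30 matches
  expect_true(3L %in% m1$unmatched_ref)                   # +60 does not
  expect_true(3L %in% m1$unmatched_est)
  # symmetry up to FP/FN exchange
  m2 <- match_cycles(est, ref, fs = 1000)
  expect_equal(nrow(m2$pairs), nrow(m1$pairs))
  expect_equal(m2$unmatched_ref, m1$unmatched_est)
})

test_that("per-cycle error rows follow the E/AE/ARE definitions", {
  ref <- data.frame(cycle_id = 1:3, start = c(0L, 1000L, 2000L),
                    end = c(1000L, 2000L, 3000L), pep_ref_ms = c(100, 95, 88))
  est_pep <- data.frame(cycle_id = 1:3, pep_ms = c(90, 95, 100),
                        reason = NA_character_)
  m <- match_cycles(ref, ref, fs = 1000)
  m$pairs$est_cycle_id <- 1:3
  er <- per_sample_errors(m, ref, est_pep, fs = 1000)
  expect_equal(er$rows$e_ms, c(10, 0, -12))
  expect_equal(er$rows$ae_ms, c(10, 0, 12))
  expect_equal(er$rows$are, c(0.10, 0, 12 / 88))
  # invalid estimates are counted with their reasons, not dropped silently
  est2 <- est_pep; est2$pep_ms[2] <- NA; est2$reason[2] <- "NoLocMin"
  er2 <- per_sample_errors(m, ref, est2, fs = 1000)
  expect_equal(nrow(er2$rows), 2L)
  expect_equal(er2$invalid$reason, "NoLocMin")
})

test_that("per-datapoint and per-sample aggregation weight cycles differently", {
  rows <- data.frame(e_ms = c(10, 30, 30, 30), ae_ms = c(10, 30, 30, 30),
                     are = c(0.1, 0.3, 0.3, 0.3),
                     datapoint = c("a", "b", "b", "b"))
  rep_ <- aggregate_errors(rows, by = "datapoint")
  expect_equal(unname(rep_$datapoint_means[["mae_ms"]]), 20)
  expect_equal(rep_$per_sample$mean[rep_$per_sample$metric == "ae_ms"], 25)
  # equal group sizes: both aggregations coincide
  rows2 <- data.frame(e_ms = c(1, 3, 5, 7), ae_ms = c(1, 3, 5, 7),
                      are = c(0.01, 0.03, 0.05, 0.07),
                      datapoint = c("a", "a", "b", "b"))
  r2 <- aggregate_errors(rows2, by = "datapoint")
  expect_equal(unname(r2$datapoint_means[["mae_ms"]]),
               r2$per_sample$mean[r2$per_sample$metric == "ae_ms"])
  # triangle inequality between MAE and |ME|
  expect_gte(r2$per_sample$mean[2], abs(r2$per_sample$mean[1]))
})

test_that("invalid counts are conserved across reason codes", {
  ref <- data.frame(cycle_id = 1:10, start = (0:9) * 1000L, end = (1:10) * 1000L,
                    pep_ref_ms = rep(100, 10))
  est_pep <- data.frame(cycle_id = 1:10, pep_ms = c(rep(100, 6), NA, NA, NA, 100),
                        reason = c(rep(NA, 6), "NoC", "NoLocMin", "NoC", NA))
  m <- match_cycles(ref, ref, fs = 1000)
  er <- per_sample_errors(m, ref, est_pep, fs = 1000)
  rep_ <- aggregate_errors(er)
  expect_equal(rep_$invalid$n_invalid, 3L)
  expect_equal(sum(rep_$invalid$per_reason), rep_$invalid$n_invalid)
  expect_equal(as.integer(rep_$invalid$per_reason[["NoC"]]), 2L)
  expect_equal(rep_$invalid$n_total, 10L)
})

test_that("ICC(3,2) matches the independent ANOVA oracle", {
  expect_equal(icc_3_2(1:10 + 0.0, 1:10 + 0.0)$icc, 1)
  r <- icc_3_2(1:5, 2:6)
  expect_equal(r$icc, icc_aov_oracle(1:5, 2:6), tolerance = 1e-10)
  set.seed(99)
  for (trial in 1:20) {
    n <- sample(6:50, 1)
    a <- rnorm(n, 100, 15)
    b <- a * runif(1, 0.8, 1.2) + rnorm(n, 0, 5)
    expect_equal(icc_3_2(a, b)$icc, icc_aov_oracle(a, b), tolerance = 1e-8)
  }
  # independent vectors: agreement near zero
  set.seed(123)
  x <- rnorm(100); y <- rnorm(100)
  expect_lt(abs(icc_3_2(x, y)$icc), 0.3)
  expect_error(icc_3_2(1:3, 1:3), "at least 5")
})
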