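test_that("stationarization removes constants and slow drift, preserves spikes per filter response", {
  tms <- seq(0, by = 1000, length.out = 100)
  s_const <- beat_series(rep(80, 100), tms)
  expect_lt(max(abs(stationarize(s_const))), 1e-8)
  # slow drift (1 ms/beat over 100 beats) is largely removed
  drift <- 100 + seq(0, 99)
  d <- stationarize(beat_series(drift, tms))
  expect_lt(diff(range(d)), 0.2 * diff(range(drift)))
  # single-beat spike: preserved up to the trend absorption of the 0.1 Hz
  # low-pass, computed independently from the filter's impulse response
  xs <- rep(100, 100); xs[50] <- 160
  ds <- stationarize(beat_series(xs, tms))
  lp <- signal::butter(4, 0.1 / 0.5, type = "low")
  imp <- signal::filtfilt(lp, c(rep(0, 100), 1, rep(0, 100)))
  absorbed <- 60 * max(imp)
  expect_equal(ds[50] - stats::median(ds[-50]), 60 - absorbed, tolerance = 0.05 * 60)
  # too few beats -> flagged pass-through
  short <- beat_series(c(80, 82, 81), c(0, 1000, 2000))
  expect_true(attr(stationarize(short), "passthrough"))
})

test_that("3-MAD rule flags exactly the aberrant beats on stationarized input", {
  expect_equal(which(detect_outliers(c(0, 0, 0, 0, 60))), 5L)
  expect_equal(sum(detect_outliers(rep(5, 20))), 0L)        # MAD = 0
  set.seed(21)
  x <- runif(50, -2, 2); x[25] <- x[25] + 40
  expect_equal(which(detect_outliers(x)), 25L)
  # invariance to adding a constant
  expect_equal(detect_outliers(x + 1000), detect_outliers(x))
})

test_that("linear interpolation corrects flagged beats between clean neighbors", {
  tms <- seq(0, by = 1000, length.out = 3)
  s <- beat_series(c(10, 99, 30), tms)
  out <- correct_linear(s, c(FALSE, TRUE, FALSE))
  expect_equal(out$b_time_ms, c(10, 20, 30))
  # leading outlier copies the first valid value
  s2 <- beat_series(c(99, 10, 12), tms)
  expect_equal(correct_linear(s2, c(TRUE, FALSE, FALSE))$b_time_ms[1], 10)
  # two adjacent outliers interpolate to 20 and 30
  s3 <- beat_series(c(10, 99, 99, 40), seq(0, by = 1000, length.out = 4))
  expect_equal(correct_linear(s3, c(FALSE, TRUE, TRUE, FALSE))$b_time_ms, c(10, 20, 30, 40))
  # all-outlier series passes through
  s4 <- beat_series(c(1, 2), c(0, 1000))
  expect_equal(correct_linear(s4, c(TRUE, TRUE))$b_time_ms, c(1, 2))
})

test_that("autoregressive correction recovers exact values for noiseless AR(1)", {
  x <- 100 * 0.9^(0:29)
  s <- beat_series(x, seq(0, by = 1000, length.out = 30))
  mask <- rep(FALSE, 30); mask[15] <- TRUE
  out <- correct_autoregressive(s, mask)
  expect_equal(out$b_time_ms[15], x[15], tolerance = 1e-8)
  # constant series with one spike masked -> replaced by the constant
  xc <- rep(50, 20); xc[10] <- 110
  sc <- beat_series(xc, seq(0, by = 900, length.out = 20))
  mc <- rep(FALSE, 20); mc[10] <- TRUE
  expect_equal(correct_autoregressive(sc, mc)$b_time_ms[10], 50, tolerance = 1e-8)
  # white noise + spikes: correction moves masked beats toward the truth
  set.seed(8)
  truth <- 100 + rnorm(200, 0, 2)
  spiked <- truth
  bad <- c(30, 77, 111, 150, 180)
  spiked[bad] <- spiked[bad] + 50
  sw <- beat_series(spiked, seq(0, by = 1000, length.out = 200))
  mw <- rep(FALSE, 200); mw[bad] <- TRUE
  cw <- correct_autoregressive(sw, mw)
  expect_lt(sqrt(mean((cw$b_time_ms[bad] - truth[bad])^2)),
            sqrt(mean((spiked[bad] - truth[bad])^2)))
})

test_that("dummy correction is the identity and correctors never touch clean beats", {
  s <- beat_series(c(10, 20, NA, 40), seq(0, by = 1000, length.out = 4))
  expect_equal(correct_dummy(s, rep(TRUE, 4))$b_time_ms, s$b_time_ms)
  e <- beat_series(numeric(0), numeric(0))
  expect_equal(nrow(correct_dummy(e, logical(0))), 0L)
  set.seed(31)
  for (trial in 1:25) {
    n <- sample(10:40, 1)
    x <- 100 + rnorm(n, 0, 5)
    mask <- runif(n) < 0.2
    s <- beat_series(x, seq(0, by = 900, length.out = n))
    for (f in list(correct_linear, correct_autoregressive)) {
      out <- f(s, mask)
      expect_equal(out$b_time_ms[!mask], x[!mask])
    }
  }
})
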