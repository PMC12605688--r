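test_that("C-point selection uses the preceding R-C history", {
  # single interior maximum
  dz <- c(0, 0, 1, 3, 2, 1, 0, 0, 0, 0)
  oc <- one_cycle(dz, r_peak = 0L, c_point = NA, end = 10L)
  cp <- detect_c_points(dz, oc$part, fs = 1000)
  expect_equal(cp$c_point, 3L)
  # strictly monotone segment -> no peak
  cp2 <- detect_c_points(as.numeric(0:9), oc$part, 1000)
  expect_true(is.na(cp2$c_point))
  expect_equal(cp2$reason, "NoC")

  # two candidate peaks at RC 150 and 260 ms; history mean RC 160 -> pick 150
  fs <- 1000
  n <- 4000
  dz3 <- numeric(n)
  mk_peak <- function(center, amp) amp * exp(-((seq_len(n) - 1 - center)^2) / (2 * 15^2))
  # three history cycles with single peaks at RC 160
  r <- c(200L, 1000L, 1800L, 2600L)
  for (k in 1:3) dz3 <- dz3 + mk_peak(r[k] + 160, 2)
  dz3 <- dz3 + mk_peak(r[4] + 150, 1.5) + mk_peak(r[4] + 260, 2.0)
  part <- partition_cycles(c(r[1] - 800L, r), fs, n)
  cp3 <- detect_c_points(dz3, part, fs)
  expect_equal(cp3$c_point[4], r[4] + 150L, tolerance = 0)
})

test_that("extremum-family B detectors match hand-worked fixtures", {
  # last local minimum of dZ/dt before C
  dz <- c(0, -1, 0, 2, 5, 9)
  oc <- one_cycle(dz, r_peak = 0L, c_point = 5L, end = 6L)
  expect_equal(bpoint_extremum_family(dz, oc$part, oc$cp, 1000, "ste85")$b_point, 1L)
  # last negative-to-nonnegative crossing; B = first nonnegative sample
  dz2 <- c(-2, -1, 1, 3, 9)
  oc2 <- one_cycle(dz2, r_peak = 0L, c_point = 4L, end = 5L)
  expect_equal(bpoint_extremum_family(dz2, oc2$part, oc2$cp, 1000, "she90")$b_point, 2L)
  # no local minimum / no crossing -> reason codes
  mono <- as.numeric(0:5)
  oc3 <- one_cycle(mono, r_peak = 0L, c_point = 5L, end = 6L)
  r1 <- bpoint_extremum_family(mono, oc3$part, oc3$cp, 1000, "ste85")
  expect_true(is.na(r1$b_point)); expect_equal(r1$reason, "NoLocMin")
  r2 <- bpoint_extremum_family(mono + 1, oc3$part, oc3$cp, 1000, "she90")
  expect_equal(r2$reason, "NoZCross")
  # segment everywhere above the cycle mean -> no isoelectric crossing
  dz4 <- c(5, 6, 7, 8, 9, -30, -30, -30)   # cycle mean pulled below the pre-C part
  oc4 <- one_cycle(dz4, r_peak = 0L, c_point = 4L, end = 8L)
  r3 <- bpoint_extremum_family(dz4, oc4$part, oc4$cp, 1000, "arb17ic")
  expect_equal(r3$reason, "NoIsoCross")
  # missing C propagates
  ocna <- one_cycle(dz, r_peak = 0L, c_point = 5L, end = 6L)
  ocna$cp$c_point <- NA_integer_
  expect_equal(bpoint_extremum_family(dz, ocna$part, ocna$cp, 1000, "ste85")$reason, "NoC")
})

test_that("fixed second/third-derivative windows clip and invalidate correctly", {
  fs <- 1000
  # C only 100 ms into the cycle: the [c-150, c-100] window clips to < 2 samples
  n <- 600
  dz <- c(seq(0, 2, length.out = 100), seq(2, 0, length.out = 500))
  oc <- one_cycle(dz, r_peak = 0L, c_point = 99L, end = n)
  r <- bpoint_extremum_family(dz, oc$part, oc$cp, fs, "arb17sd")
  expect_true(is.na(r$b_point))
  expect_equal(r$reason, "InvBWindow")
  # with C at 400 ms the same method returns a value inside [c-150, c-100]
  dz2 <- c(seq(0, 0, length.out = 250), seq(0, 2, length.out = 150),
           seq(2, 0, length.out = 200))
  oc2 <- one_cycle(dz2, r_peak = 0L, c_point = 399L, end = 600L)
  r2 <- bpoint_extremum_family(dz2, oc2$part, oc2$cp, fs, "arb17sd")
  expect_true(r2$b_point >= 249 && r2$b_point <= 300)
  r3 <- bpoint_extremum_family(dz2, oc2$part, oc2$cp, fs, "arb17td")
  expect_true(!is.na(r3$b_point) && r3$b_point < 399)
})

test_that("regression B predictions follow the printed polynomials exactly", {
  expect_equal(lozano_b_ms(100, "linear"), 59.45, tolerance = 1e-12)
  expect_equal(lozano_b_ms(0, "linear"), 4.45, tolerance = 1e-12)
  expect_equal(lozano_b_ms(100, "quadratic"), -0.0032 * 1e4 + 123.3 - 31.59,
               tolerance = 1e-12)
  expect_equal(lozano_b_ms(100, "quadratic"), 59.71, tolerance = 1e-9)
  # index placement: R + round(B_ms * fs / 1000), invalid when >= C
  dz <- numeric(400)
  oc <- one_cycle(dz, r_peak = 100L, c_point = 200L, end = 400L)
  rb <- bpoint_lozano(oc$part, oc$cp, 1000, "linear")   # RC = 100 -> B at 159
  expect_equal(rb$b_point, 159L)
  oc2 <- one_cycle(dz, r_peak = 100L, c_point = 140L, end = 400L)
  rb2 <- bpoint_lozano(oc2$part, oc2$cp, 1000, "linear") # predicted 126 >= c? no, < c
  expect_equal(rb2$b_point, 100L + as.integer(round(lozano_b_ms(40, "linear"))))
  oc3 <- one_cycle(dz, r_peak = 100L, c_point = 104L, end = 400L)
  rb3 <- bpoint_lozano(oc3$part, oc3$cp, 1000, "linear") # predicted past C
  expect_equal(rb3$reason, "InvBWindow")
})

test_that("maximum chord-distance detection matches the analytic cubic solution", {
  # dzdt = 10 (k/150)^3 on a 1 ms grid; line 0 -> 10 over 150 ms;
  # max of 10k/150 - 10(k/150)^3 at k = 150/sqrt(3) -> 87
  dz <- c(rep(0, 100), 10 * ((0:150) / 150)^3, rep(10, 50))
  oc <- one_cycle(dz, r_peak = 50L, c_point = 250L, end = 301L)
  bd <- bpoint_drost(dz, oc$part, oc$cp, 1000)
  expect_equal(bd$b_point - 100L, 87L)
  # exactly linear window: zero distance everywhere, tie-break to C
  dzl <- seq(0, 30, length.out = 301)
  ocl <- one_cycle(dzl, r_peak = 50L, c_point = 250L, end = 301L)
  expect_equal(bpoint_drost(dzl, ocl$part, ocl$cp, 1000)$b_point, 250L)
  # clean synthetic notch: within 4 ms of ground truth
  ch <- notch_chain()
  bn <- bpoint_drost(ch$dzdt, ch$part, ch$cp, ch$fs)
  expect_true(all(abs(bn$b_point - ch$truth$b_point) <= 4, na.rm = TRUE))
})

test_that("monotone-segment detection confines the search to the first third of the dominant run", {
  fs <- 1000
  # A-point then two increasing runs: 40 samples, dip, 120 samples up to C
  seg1 <- seq(0, 0.5, length.out = 41)          # 40-sample rise
  dip <- seq(0.5, 0.2, length.out = 21)
  seg2 <- 2 * ((0:120) / 120)^2 + 0.2           # 120-sample rise to C
  dz <- c(rep(0.6, 80), seq(0.6, 0, length.out = 40), seg1[-1], dip[-1], seg2[-1],
          seq(seg2[121], 0, length.out = 60))
  c0 <- 80 + 39 + 40 + 20 + 120                  # C index (0-based)
  oc <- one_cycle(dz, r_peak = 10L, c_point = as.integer(c0), end = length(dz),
                  rr_prev = 900L)
  r <- bpoint_forouzanfar(dz, oc$part, oc$cp, fs)
  run2_start <- 80 + 39 + 40 + 20               # 0-based start of the 120-run
  expect_true(!is.na(r$b_point))
  expect_gte(r$b_point, run2_start - 2)
  expect_lte(r$b_point, run2_start + 41)
  # monotone decrease into C: no A-point local minimum
  dzm <- c(rep(2, 50), seq(2, 1, length.out = 200))
  ocm <- one_cycle(dzm, r_peak = 10L, c_point = 240L, end = 250L, rr_prev = 600L)
  rm_ <- bpoint_forouzanfar(dzm, ocm$part, ocm$cp, fs)
  expect_true(rm_$reason %in% c("NoLocMin", "NoC"))
})

test_that("staged slope search behaves per stage on constructed segments", {
  fs <- 1000
  # strictly monotone rise whose slope exceeds the threshold mid-window
  dz <- c(rep(0, 200), 0.0005 * (1:100), 0.05 + 0.08 * (1:100), rep(8.05, 20))
  c0 <- 399L
  oc <- one_cycle(dz, r_peak = 100L, c_point = c0, end = length(dz))
  r <- bpoint_pale(dz, oc$part, oc$cp, fs)
  expect_true(!is.na(r$b_point))
  expect_true(r$b_point >= 290 && r$b_point <= 320)  # first supra-threshold slope
  # clean synthetic notch: stage-1 local minimum at the truth B
  ch <- notch_chain()
  bp <- bpoint_pale(ch$dzdt, ch$part, ch$cp, ch$fs)
  expect_true(all(abs(bp$b_point - ch$truth$b_point) <= 4, na.rm = TRUE))
  # flat window: all stages fail, global minimum of [start, c) returned
  dzf <- c(5, 4, 3, 2, 1, rep(1, 200), 1, 1)
  ocf <- one_cycle(dzf, r_peak = 2L, c_point = 205L, end = length(dzf))
  rf <- bpoint_pale(dzf, ocf$part, ocf$cp, fs)
  expect_equal(rf$b_point, which.min(dzf[1:205]) - 1L)
})

test_that("weighted-window detection reduces to the plain local-minimum rule for unit weight", {
  ch <- notch_chain()
  bm <- bpoint_miljkovic(ch$dzdt, ch$part, ch$cp, ch$fs)
  expect_true(all(abs(bm$b_point - ch$truth$b_point) <= 6, na.rm = TRUE))
  b1 <- bpoint_miljkovic(ch$dzdt, ch$part, ch$cp, ch$fs, weight = function(u) rep(1, length(u)))
  bs <- bpoint_extremum_family(ch$dzdt, ch$part, ch$cp, ch$fs, "ste85")
  # same window here (C < 300 ms after cycle start), so unit weight == ste85
  both <- !is.na(b1$b_point) & !is.na(bs$b_point)
  expect_true(all(b1$b_point[both] == bs$b_point[both]))
  # empty window -> InvBWindow
  dz <- as.numeric(1:50)
  occ <- one_cycle(dz, r_peak = 0L, c_point = 0L, end = 50L)
  expect_equal(bpoint_miljkovic(dz, occ$part, occ$cp, 1000)$reason, "InvBWindow")
})

test_that("every B result satisfies start <= b < c with exactly one reason when missing", {
  ch <- notch_chain()
  methods <- c("ste85", "she90", "deb93sd", "loz07lr", "loz07qr", "arb17ic",
               "arb17sd", "arb17td", "for18", "pal21", "dro22", "mil22")
  for (m in methods) {
    b <- detect_b_points(ch$dzdt, ch$part, ch$cp, ch$fs, method = m)
    ok <- !is.na(b$b_point)
    expect_true(all(b$b_point[ok] >= ch$part$start[ok]), info = m)
    expect_true(all(b$b_point[ok] < ch$cp$c_point[ok]), info = m)
    expect_true(all(is.na(b$reason[ok])), info = m)
    expect_true(all(!is.na(b$reason[!ok])), info = m)
    expect_true(all(b$reason[!ok] %in% B_REASONS), info = m)
  }
})

test_that("notch beats are recovered by morphology-following detectors; featureless beats defeat the local-minimum rule", {
  ch <- notch_chain()
  for (m in c("ste85", "dro22", "pal21")) {
    b <- detect_b_points(ch$dzdt, ch$part, ch$cp, ch$fs, method = m)
    expect_true(all(abs(b$b_point - ch$truth$b_point) <= 4, na.rm = TRUE), info = m)
  }
  fl <- featureless_chain()
  bs <- detect_b_points(fl$dzdt, fl$part, fl$cp, fl$fs, method = "ste85")
  expect_true(all(is.na(bs$b_point)))
  expect_true(all(bs$reason == "NoLocMin"))
  bd <- detect_b_points(fl$dzdt, fl$part, fl$cp, fl$fs, method = "dro22")
  expect_true(all(!is.na(bd$b_point)))
})
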