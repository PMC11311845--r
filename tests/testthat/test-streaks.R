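test_that("preprocessing flattens background and normalizes contrast", {
  cfg <- cleanLineScanConfig(nLines = 64L, backgroundLevel = 5)
  st <- phantomState(0, 0)
  flat <- simulateSpaceTime(st, generateBeadField(c(0, 1, -1, -0.5), 0, 0,
                                                  seed = 1), cfg)
  expect_warning(pp <- preprocessSpaceTime(flat), "constant")
  expect_true(all(intensityMatrix(pp) == 0))

  cfg2 <- cleanLineScanConfig(nLines = 512L, backgroundLevel = 5)
  img <- simulateSpaceTime(phantomState(3.82, 30),
                          manualBeadField(0.2, -0.05), cfg2)
  pp2 <- intensityMatrix(preprocessSpaceTime(img))
  expect_true(all(pp2 >= 0 & pp2 <= 1))
  expect_equal(max(pp2), 1)
  expect_gt(sum(pp2 > 0.5), 10)  # the streak survives subtraction
})

test_that("sec(alpha) correction satisfies the textbook identities", {
  expect_identical(slopeToVelocity(3.82, 0), 3.82)
  expect_equal(slopeToVelocity(1.91, 60), 3.82, tolerance = 1e-12)
  expect_equal(slopeToVelocity(2.70, 45), 2.70 * sqrt(2), tolerance = 1e-12)
  expect_equal(slopeToVelocity(2.70, 45), 3.8184, tolerance = 1e-4)
  expect_error(slopeToVelocity(1, 89), "too steep")
  expect_error(slopeToVelocity(1, 90), "too steep")
})

test_that("sec correction inverts the cosine projection to machine precision", {
  set.seed(1)
  for (i in 1:50) {
    v <- stats::runif(1, -7, 7)
    a <- stats::runif(1, 0, 88.9)
    expect_equal(slopeToVelocity(v * cos(a * pi / 180), a), v,
                 tolerance = 1e-12)
  }
})

test_that("acquisition summaries follow hand arithmetic", {
  m <- data.frame(slope_mm_s = c(3.8, 4.0, 3.6))
  est <- summarizeAcquisition(m, alphaDeg = 0)
  expect_equal(meanVelocity(est), 3.8)
  expect_equal(est@sdMmS, 0.2)
  expect_equal(est@relativeSdPercent, 100 * 0.2 / 3.8)

  same <- summarizeAcquisition(data.frame(slope_mm_s = rep(2.5, 4)), 0)
  expect_identical(same@sdMmS, 0)

  none <- summarizeAcquisition(data.frame(slope_mm_s = numeric(0)), 30)
  expect_identical(none@nStreaks, 0L)
  expect_true(is.na(meanVelocity(none)))
})

test_that("a noise-free single-bead streak is measured within 3%", {
  cfg <- cleanLineScanConfig(nLines = 1024L)
  st <- phantomState(3.82, 30)
  yc <- -3.82 * sin(pi / 6) * (512 / 13600)
  img <- simulateSpaceTime(st, manualBeadField(0.25, yc), cfg)
  m <- detectStreakSlopes(img)
  expect_gte(nrow(m), 1)
  expect_lt(abs(stats::median(m$slope_mm_s) - 3.3082) / 3.3082, 0.03)
})

test_that("near-stationary beads yield near-zero (vertical-streak) slopes", {
  # a strictly static bead is removed with the static background by the
  # per-column median filter, so probe the v -> 0 limit just above it
  cfg <- cleanLineScanConfig(nLines = 1024L, seed = 3L)
  st <- phantomState(0.05, 0)
  img <- simulateSpaceTime(st, manualBeadField(c(0.15, 0.35), c(0, 0.002)),
                          cfg)
  m <- detectStreakSlopes(img)
  expect_gte(nrow(m), 1)
  expect_lt(max(abs(m$slope_mm_s)), 0.1)
})

test_that("pure noise produces no streak measurements", {
  cfg <- lineScanConfig(nLines = 1024L, backgroundLevel = 10, seed = 17L)
  st <- phantomState(3.82, 30)
  img <- simulateSpaceTime(st, generateBeadField(c(0, 1, -2, -1), 0, 0,
                                                 seed = 1), cfg)
  expect_identical(nrow(detectStreakSlopes(img)), 0L)
})

test_that("the estimator is invariant to global intensity scaling", {
  st <- phantomState(3.82, 30)
  cfg <- lineScanConfig(nLines = 1024L, seed = 7L)
  fld <- generateBeadField(lineScanFieldArea(st, cfg), 580, 40, seed = 7)
  img <- simulateSpaceTime(st, fld, cfg)
  scaled <- methods::initialize(img, intensity = intensityMatrix(img) * 7.3)
  m1 <- detectStreakSlopes(img)
  m2 <- detectStreakSlopes(scaled)
  expect_equal(m1$slope_mm_s, m2$slope_mm_s, tolerance = 1e-10)
})

test_that("estimateVelocity recovers truth end-to-end across (v, alpha)", {
  for (case in list(c(1.5, 0), c(3.82, 30), c(6, 20))) {
    v <- case[1]; a <- case[2]
    st <- phantomState(v, a)
    cfg <- lineScanConfig(seed = 31L)
    fld <- generateBeadField(lineScanFieldArea(st, cfg), 580, 40, seed = 31)
    est <- estimateVelocity(simulateSpaceTime(st, fld, cfg))
    expect_lt(abs(meanVelocity(est) - v) / v, 0.05)
  }
})

test_that("angle estimates agree with the 0-degree estimate below 45 degrees", {
  v <- 3.82
  est <- vapply(c(0, 40), function(a) {
    st <- phantomState(v, a)
    cfg <- lineScanConfig(seed = 41L)
    fld <- generateBeadField(lineScanFieldArea(st, cfg), 580, 40, seed = 41)
    meanVelocity(estimateVelocity(simulateSpaceTime(st, fld, cfg)))
  }, numeric(1))
  expect_lt(abs(est[2] - est[1]) / est[1], 0.05)
})
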