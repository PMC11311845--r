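test_that("predictStreak matches the closed-form streak geometry", {
  cfg <- lineScanConfig()
  st0 <- phantomState(3.82, 0)
  expect_equal(predictStreak(0.1, 0, 5, st0, cfg)@slopeMmS, 3.82)

  st30 <- phantomState(3.82, 30)
  p30 <- predictStreak(0.1, -0.1, 5, st30, cfg)
  expect_equal(p30@slopeMmS, 3.82 * cos(pi / 6))
  expect_equal(p30@slopeMmS, 3.3082, tolerance = 1e-4)

  st90 <- phantomState(3.82, 90)
  p90 <- predictStreak(0.1, -0.1, 5, st90, cfg)  # r_eff = 5 + 2*3 = 11 um
  expect_equal(p90@dwellS, 2 * 0.011 / 3.82)
  expect_equal(p90@dwellS, 5.76e-3, tolerance = 1e-3)

  # alpha = 0: dwell is the along-line FOV transit time
  pa0 <- predictStreak(0.1, 0, 5, st0, cfg)
  expect_equal(pa0@dwellS, scanAngleToLateral(1.5, st0@optics) / 3.82)

  # v = 0: dwell is the acquisition duration
  pv0 <- predictStreak(0.1, 0, 5, phantomState(0, 30), cfg)
  expect_equal(pv0@dwellS, cfg@nLines / cfg@lineRateHz)
})

test_that("streak dwell decreases monotonically with vessel angle", {
  cfg <- lineScanConfig()
  dwell <- vapply(seq(10, 90, by = 10), function(a)
    predictStreak(0.1, -0.05, 5, phantomState(3.82, a), cfg)@dwellS,
    numeric(1))
  expect_true(all(diff(dwell) < 0))
})

test_that("a stationary bead on the line gives a vertical streak", {
  cfg <- cleanLineScanConfig(nLines = 256L)
  st <- phantomState(0, 0)
  img <- simulateSpaceTime(st, manualBeadField(0.2, 0), cfg)
  m <- intensityMatrix(img)
  peaks <- apply(m, 1, which.max)
  expect_true(all(peaks == peaks[1]))
  expect_lt(abs(peaks[1] * img@pixelPitchMm - 0.2), 2 * img@pixelPitchMm)
})

test_that("noise-free centroid slope matches the analytic prediction", {
  cfg <- cleanLineScanConfig(nLines = 1024L)
  st <- phantomState(3.82, 30)
  yc <- -3.82 * sin(pi / 6) * (512 / 13600)  # cross the line mid-acquisition
  img <- simulateSpaceTime(st, manualBeadField(0.2, yc), cfg)
  cs <- streakCentroidSlope(img)
  pred <- predictStreak(0.2, yc, 5, st, cfg)
  predPx <- pred@slopeMmS * img@linePeriodS / img@pixelPitchMm
  expect_lt(abs(cs$slopePxPerLine - predPx) * cs$nLines, 0.5)
})

test_that("empty field with noise disabled renders flat background", {
  cfg <- cleanLineScanConfig(nLines = 64L, backgroundLevel = 7)
  st <- phantomState(3.82, 30)
  empty <- generateBeadField(c(0, 1, -1, 0.1), 0, 0, seed = 1)
  img <- simulateSpaceTime(st, empty, cfg)
  expect_true(all(intensityMatrix(img) == 7))
})

test_that("simulation output is bit-identical under the same seed", {
  st <- phantomState(3.82, 30)
  cfg <- lineScanConfig(nLines = 128L, seed = 99L)
  fld <- generateBeadField(lineScanFieldArea(st, cfg), 580, 40, seed = 99)
  expect_identical(intensityMatrix(simulateSpaceTime(st, fld, cfg)),
                   intensityMatrix(simulateSpaceTime(st, fld, cfg)))
  cfg2 <- lineScanConfig(nLines = 128L, seed = 100L)
  expect_false(identical(intensityMatrix(simulateSpaceTime(st, fld, cfg)),
                         intensityMatrix(simulateSpaceTime(st, fld, cfg2))))
})

test_that("flat-field photon noise has variance ~ mean x gain", {
  st <- phantomState(0, 0)
  empty <- generateBeadField(c(0, 1, -1, 0.1), 0, 0, seed = 1)
  cfg <- lineScanConfig(nLines = 256L, backgroundLevel = 50, readNoiseSd = 0,
                        photonGain = 2, seed = 5L)
  img <- intensityMatrix(simulateSpaceTime(st, empty, cfg))
  expect_equal(stats::var(as.vector(img)) / (mean(img) * 2), 1,
               tolerance = 0.1)
})

test_that("streak count grows linearly with bead density", {
  cfg <- lineScanConfig()
  st <- phantomState(3.82, 30)
  L <- scanAngleToLateral(cfg@fovDeg, st@optics)
  duration <- cfg@nLines / cfg@lineRateHz
  countStreaks <- function(density, seed) {
    fld <- generateBeadField(lineScanFieldArea(st, cfg), density, 0,
                             seed = seed)
    b <- beadTable(fld)
    hits <- vapply(seq_len(nrow(b)), function(i) {
      p <- predictStreak(b$x_mm[i], b$y_mm[i], b$radius_um[i], st, cfg)
      mid <- (p@entryTimeS + p@exitTimeS) / 2
      xmid <- b$x_mm[i] + p@slopeMmS * mid
      mid >= 0 && mid <= duration && xmid >= 0 && xmid <= L
    }, logical(1))
    sum(hits)
  }
  dens <- c(100, 300, 580)
  counts <- vapply(dens, function(d)
    mean(vapply(1:3, function(s) countStreaks(d, s), numeric(1))), numeric(1))
  fit <- linearFit(dens, counts)
  expect_gt(coef(fit)[["slope"]], 0)
  expect_gt(fit@rSquared, 0.9)
})

test_that("raster frames advance the field and respect Poisson density", {
  st <- phantomState(0, 0)
  cfg <- cleanLineScanConfig(nLines = 64L, pixelsPerLine = 128L)
  fld <- generateBeadField(c(0, 0.6, 0, 0.6), 580, 40, seed = 13)
  vid <- simulateRasterFrames(st, fld, cfg, nFrames = 3)
  fr <- videoFrames(vid)
  expect_identical(fr[1, , ], fr[3, , ])  # v = 0: frames identical

  # sub-pixel inter-frame motion stays below one pixel
  stSlow <- phantomState(0.02, 0)
  vid2 <- simulateRasterFrames(stSlow, manualBeadField(0.2, 0.2), cfg,
                               nFrames = 2, frameRateHz = 27)
  stepPx <- 0.02 / 27 / (pixelScale(vid2) / 1000)
  expect_lt(stepPx, 1)

  # bead count in the FOV matches density x area at 4 sigma
  L <- scanAngleToLateral(cfg@fovDeg, st@optics)
  b <- beadTable(fld)
  inFov <- sum(b$x_mm <= L & b$y_mm <= L)
  expect_lt(abs(inFov - 580 * L^2), 4 * sqrt(580 * L^2))
})
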