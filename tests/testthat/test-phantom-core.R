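test_that("voltage-velocity map reproduces the calibration endpoints", {
  cal <- motorCalibration()
  expect_equal(voltageToBeltVelocity(11, cal), 7.0, tolerance = 1e-12)
  expect_equal(voltageToBeltVelocity(1.5, cal), 0.5, tolerance = 1e-12)
  expect_identical(voltageToBeltVelocity(0.3, cal), 0)
  expect_equal(voltageToBeltVelocity(-11, cal), -7.0, tolerance = 1e-12)
  expect_error(voltageToBeltVelocity(12.5, cal), "operational range")
})

test_that("voltage map is odd, monotone, and flat inside the dead zone", {
  cal <- motorCalibration()
  v <- seq(0, 12, by = 0.05)
  fwd <- voltageToBeltVelocity(v, cal)
  expect_equal(voltageToBeltVelocity(-v, cal), -fwd)
  expect_true(all(diff(fwd) >= 0))
  dz <- seq(-cal@deadZoneV, cal@deadZoneV, by = 0.05)
  expect_true(all(voltageToBeltVelocity(dz, cal) == 0))
})

test_that("two-point line through the printed endpoints recovers the defaults", {
  cal <- motorCalibration()
  fit <- linearFit(c(1.5, 11), c(0.5, 7))
  expect_equal(coef(fit)[["slope"]], cal@gain, tolerance = 1e-12)
  expect_equal(coef(fit)[["intercept"]], cal@offset, tolerance = 1e-12)
})

test_that("pulley kinematics follow arc-length arithmetic", {
  expect_equal(angularToLinear(60, pulleyGeometry(6)), 60 * pi / 180 * 6)
  expect_equal(angularToLinear(60, pulleyGeometry(6)), 6.2832, tolerance = 1e-4)
  expect_identical(angularToLinear(0), 0)
  expect_equal(angularToLinear(-60, pulleyGeometry(6)),
               -angularToLinear(60, pulleyGeometry(6)))
})

test_that("paraxial scan-angle mapping is f * theta and linear", {
  expect_equal(scanAngleToLateral(1.5, opticsConfig(20)), 20 * 1.5 * pi / 180)
  expect_equal(scanAngleToLateral(1.5, opticsConfig(20)), 0.5236,
               tolerance = 1e-4)
  expect_identical(scanAngleToLateral(0), 0)
  expect_equal(scanAngleToLateral(1.5, opticsConfig(30)), 0.7854,
               tolerance = 1e-4)
  th <- c(0.2, 0.7, 1.9)
  expect_equal(scanAngleToLateral(2 * th), 2 * scanAngleToLateral(th))
  expect_equal(scanAngleToLateral(1, opticsConfig(40)),
               2 * scanAngleToLateral(1, opticsConfig(20)))
  expect_error(scanAngleToLateral(15), "paraxial")
})

test_that("bead fields are Poisson-consistent and reproducible", {
  fld <- generateBeadField(c(0, 1, 0, 1), 580, 40, seed = 7)
  n <- nrow(beadTable(fld))
  expect_lt(abs(n - 580), 4 * sqrt(580))
  b <- beadTable(fld)
  expect_true(all(b$x_mm >= 0 & b$x_mm <= 1 & b$y_mm >= 0 & b$y_mm <= 1))

  # reproducibility and zero-density edge case
  fld2 <- generateBeadField(c(0, 1, 0, 1), 580, 40, seed = 7)
  expect_identical(beadTable(fld), beadTable(fld2))
  expect_identical(nrow(beadTable(generateBeadField(c(0, 1, 0, 1), 0, 0,
                                                    seed = 1))), 0L)
  expect_error(generateBeadField(c(0, 1, 0, 1), -1, 0, seed = 1),
               "non-negative")
  expect_error(generateBeadField(c(0, 1, 0, 1), 10, 20, seed = 1),
               "exceed")
})

test_that("fluorescent flagging matches the density ratio (binomial, 4 sigma)", {
  fld <- generateBeadField(c(0, 5, 0, 2), 580, 40, seed = 3)
  b <- beadTable(fld)
  n <- nrow(b)
  p <- 40 / 580
  k <- sum(b$is_fluorescent)
  expect_lt(abs(k - n * p), 4 * sqrt(n * p * (1 - p)))
})

test_that("bead counts over many seeds have Poisson dispersion", {
  mu <- 580 * 0.25
  counts <- vapply(1:200, function(s)
    nrow(beadTable(generateBeadField(c(0, 0.5, 0, 0.5), 580, 40, seed = s))),
    integer(1))
  # index of dispersion test: sum (n_i - nbar)^2 / nbar ~ chisq(n - 1)
  stat <- sum((counts - mean(counts))^2) / mean(counts)
  p <- stats::pchisq(stat, df = length(counts) - 1)
  expect_gt(min(p, 1 - p), 0.005)
  expect_lt(abs(mean(counts) - mu), 4 * sqrt(mu / 200))
})

test_that("minimum-separation mode packs hard disks at the nominal density", {
  fld <- generateBeadField(c(0, 1, 0, 1), 580, 40, seed = 11,
                           minSeparationUm = 10)
  b <- beadTable(fld)
  d <- as.matrix(stats::dist(b[, c("x_mm", "y_mm")]))
  diag(d) <- Inf
  expect_gte(min(d), 0.010)
  expect_lt(abs(nrow(b) - 580), 4 * sqrt(580))
})

test_that("belt velocity series reflects jitter configuration", {
  calm <- motorCalibration()
  expect_identical(beltVelocitySeries(6, calm, n = 5, seed = 1),
                   rep(voltageToBeltVelocity(6, calm), 5))
  calj <- motorCalibration(jitterFraction = 0.03)
  v <- beltVelocitySeries(6, calj, n = 500, seed = 1)
  expect_gt(stats::sd(v), 0)
  expect_lt(repeatabilityPercentSD(v), 4.8)
})
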