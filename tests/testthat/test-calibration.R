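test_that("linearFit matches closed-form least squares", {
  # exact line
  f <- linearFit(1:5, 2 * (1:5))
  expect_equal(coef(f)[["slope"]], 2)
  expect_identical(f@rSquared, 1)
  expect_equal(f@residualSd, 0)

  # non-trivial case checked against the normal equations
  x <- c(0, 1, 2); y <- c(0, 1, 0)
  f2 <- linearFit(x, y)
  o <- olsOracle(x, y)
  expect_equal(coef(f2)[["slope"]], o[["slope"]], tolerance = 1e-12)
  expect_equal(coef(f2)[["intercept"]], o[["intercept"]], tolerance = 1e-12)

  # two printed calibration endpoints
  expect_equal(coef(linearFit(c(1.5, 11), c(0.5, 7)))[["slope"]], 0.68421,
               tolerance = 1e-5)
  expect_error(linearFit(c(2, 2, 2), 1:3), "degenerate")
})

test_that("linearFit agrees with the normal-equations oracle on random data", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    f <- linearFit(x, y)
    o <- olsOracle(x, y)
    expect_equal(coef(f)[["slope"]], o[["slope"]], tolerance = 1e-10)
    expect_equal(coef(f)[["intercept"]], o[["intercept"]], tolerance = 1e-10)
  }
})

test_that("repeatability percent SD follows its definition", {
  expect_identical(repeatabilityPercentSD(c(4, 4, 4)), 0)
  expect_equal(repeatabilityPercentSD(c(3.8, 4.0, 4.2)), 5.0)
  v <- c(2.2, 2.5, 2.4)
  expect_equal(repeatabilityPercentSD(v * 17), repeatabilityPercentSD(v))
  expect_error(repeatabilityPercentSD(c(-1, 1)), "zero mean")
})

test_that("cubic angle model fitting round-trips and degenerates sanely", {
  m <- referenceAngleModel()
  expect_identical(unname(evaluateAngleModel(m, 0)), 1.9)
  angles <- seq(0, 90, by = 5)
  fit <- fitAngleModel(angles, evaluateAngleModel(m, angles))
  expect_equal(unname(coef(fit)), unname(coef(m)), tolerance = 1e-9)
  expect_equal(fit@rSquared, 1)

  const <- fitAngleModel(angles, rep(2.5, length(angles)))
  expect_equal(unname(coef(const)), c(0, 0, 0, 2.5), tolerance = 1e-9)
  expect_error(fitAngleModel(c(0, 10, 20, 30), 1:4), "5 distinct")
})

test_that("angle correction factor rescales the model to the reference", {
  m <- referenceAngleModel()
  f45 <- angleCorrectionFactor(m, 45, vReference = 3.82)
  expect_equal(f45, 3.82 / evaluateAngleModel(m, 45))
  # model(alpha) * factor(alpha) == vReference at the fitted angles
  aa <- seq(40, 90, by = 5)
  expect_equal(evaluateAngleModel(m, aa) * angleCorrectionFactor(m, aa),
               rep(3.82, length(aa)))
  # where the model increases, the factor decreases
  y <- evaluateAngleModel(m, aa)
  f <- angleCorrectionFactor(m, aa)
  expect_true(all(sign(diff(f)) == -sign(diff(y))))
  expect_error(angleCorrectionFactor(m, 30), "40")
})

test_that("sweeps are reproducible and structured", {
  cfgFast <- lineScanConfig(nLines = 1024L)
  sw1 <- runVelocitySweep("linescan", velocities = c(2, 5), nReps = 2,
                          baseSeed = 3, lineScanCfg = cfgFast)
  sw2 <- runVelocitySweep("linescan", velocities = c(2, 5), nReps = 2,
                          baseSeed = 3, lineScanCfg = cfgFast)
  expect_identical(sweepTable(sw1), sweepTable(sw2))
  expect_identical(nrow(sweepTable(sw1)), 4L)
  expect_true(all(abs(sweepTable(sw1)$measured_v -
                      sweepTable(sw1)$true_v) /
                  sweepTable(sw1)$true_v < 0.05))
  expect_s4_class(sw1@fit, "LinearFit")
})

test_that("angle sweep flags the 90-degree breakdown and tracks error growth", {
  sw <- runAngleSweep(angles = c(0, 30, 90), nReps = 1, baseSeed = 2,
                      lineScanCfg = lineScanConfig(nLines = 2048L))
  tab <- sweepTable(sw)
  expect_true(tab$failed[tab$alpha_deg == 90])
  ok <- tab[tab$alpha_deg < 45, ]
  expect_true(all(ok$abs_percent_error <= 5))
})
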