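#' @include streaks.R tracking.R frame-sim.R
NULL

#' Ordinary least-squares line fit
#'
#' Wraps [stats::lm()] and reports slope, intercept, r^2 (against the
#' regression mean, not through the origin), and the residual SD
#' sqrt(SSE / (n - 2)).
#'
#' @param x,y numeric vectors of equal length (n >= 2); `x` must have
#'   non-zero variance.
#' @return a [LinearFit-class].
#' @examples
#' linearFit(c(1.5, 11), c(0.5, 7))  # slope 6.5 / 9.5
#' @export
linearFit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::var(x) == 0) stop("degenerate x: zero variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  n <- length(x)
  new("LinearFit",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = if (n >= 3 && sst > 0) 1 - sse / sst else NA_real_,
      residualSd = if (n > 2) sqrt(sse / (n - 2)) else NA_real_,
      n = as.integer(n))
}

#' Repeatability as percent standard deviation
#'
#' 100 * SD / |mean| of repeated measurements (sample SD); invariant to
#' uniform rescaling.
#'
#' @param values numeric vector, length >= 2, non-zero mean.
#' @return percent SD (numeric scalar).
#' @examples
#' repeatabilityPercentSD(c(3.8, 4.0, 4.2))  # 5
#' @export
repeatabilityPercentSD <- function(values) {
  stopifnot(length(values) >= 2)
  mu <- mean(values)
  if (mu == 0) stop("zero mean: percent SD undefined")
  100 * stats::sd(values) / abs(mu)
}

## Deterministic per-replicate seed derivation, kept within 32-bit range.
.deriveSeed <- function(baseSeed, k) {
  as.integer((as.numeric(baseSeed) * 10007 + 7919 * k) %% .Machine$integer.max)
}

#' Simulate-and-estimate velocity sweep
#'
#' For each true velocity and seeded replicate, simulates an acquisition
#' (line-scan space-time image or ICGA-style frame video), runs the
#' matching estimator, and regresses the measured means against truth --
#' the synthetic analog of validating the phantom against an instrument
#' over its velocity range.
#'
#' @param modality `"linescan"` (streak velocimetry at vessel angle
#'   `alphaDeg`) or `"frames"` (LAP particle tracking).
#' @param velocities true belt velocities in mm/s; a warning is issued
#'   outside the calibrated 0.5-7 mm/s range. Defaults: 0.5-7 mm/s for
#'   line-scan, 0.8-5.8 mm/s for frames.
#' @param alphaDeg vessel angle for the line-scan modality (degrees).
#' @param nReps seeded replicates per velocity (default 3, as in
#'   triplicate acquisition practice).
#' @param baseSeed integer; all per-replicate seeds derive from it.
#' @param lineScanCfg a [LineScanConfig-class] template (line-scan).
#' @param sloCfg an [SLOVideoConfig-class] template (frames).
#' @param optics an [OpticsConfig-class].
#' @param totalDensity,fluorescentDensity bead densities per mm^2.
#' @param maxSpotsPerFrame frames modality: track only the N brightest
#'   spots per frame, keeping the spot spacing above the per-frame
#'   displacement as in sparse-labeling EMA practice.
#' @param ... extra arguments to the estimator ([detectStreakSlopes()] or
#'   [trackVideo()]).
#' @return a [SweepResult-class]; `@table` has columns `true_v`, `rep`,
#'   `seed`, `measured_v`, `sd`, `n`, and `@fit` the [LinearFit-class] of
#'   per-velocity measured means against truth.
#' @examples
#' \donttest{
#' sw <- runVelocitySweep("linescan", velocities = c(2, 5), nReps = 1,
#'                        baseSeed = 1,
#'                        lineScanCfg = lineScanConfig(nLines = 1024L))
#' sw
#' }
#' @export
runVelocitySweep <- function(modality = c("linescan", "frames"),
                             velocities = NULL, alphaDeg = 30, nReps = 3,
                             baseSeed = 1,
                             lineScanCfg = lineScanConfig(),
                             sloCfg = sloVideoConfig(),
                             optics = opticsConfig(),
                             totalDensity = 580, fluorescentDensity = 40,
                             maxSpotsPerFrame = 25, ...) {
  modality <- match.arg(modality)
  if (is.null(velocities))
    velocities <- if (modality == "linescan") c(0.5, 2, 3.82, 5.5, 7)
                  else c(0.8, 2, 3, 4.5, 5.8)
  if (any(velocities < 0.5 | velocities > 7))
    warning("velocities outside the calibrated 0.5-7 mm/s range")
  rows <- list()
  k <- 0L
  for (v in velocities) {
    for (r in seq_len(nReps)) {
      k <- k + 1L
      sd_ <- .deriveSeed(baseSeed, k)
      row <- data.frame(true_v = v, rep = r, seed = sd_,
                        measured_v = NA_real_, sd = NA_real_, n = NA_integer_)
      est <- tryCatch({
        if (modality == "linescan") {
          st <- phantomState(v, alphaDeg, optics)
          cfg <- methods::initialize(lineScanCfg, seed = sd_)
          fld <- generateBeadField(lineScanFieldArea(st, cfg), totalDensity,
                                   fluorescentDensity, seed = sd_)
          e <- estimateVelocity(simulateSpaceTime(st, fld, cfg), ...)
          c(e@velocityMmS, e@sdMmS, e@nStreaks)
        } else {
          st <- phantomState(v, 0, optics)
          cfg <- methods::initialize(sloCfg, seed = sd_)
          fld <- generateBeadField(icgaFieldArea(st, cfg), totalDensity,
                                   fluorescentDensity, seed = sd_)
          tr <- trackVideo(simulateIcgaVideo(st, fld, cfg),
                           maxSpotsPerFrame = maxSpotsPerFrame, ...)
          c(tr@meanVelocityMmS, tr@sdMmS, tr@nTracksUsed)
        }
      }, error = function(e) {
        warning("estimation failed at v = ", v, " (rep ", r, "): ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(est)) {
        row$measured_v <- est[1]; row$sd <- est[2]; row$n <- est[3]
      }
      rows[[k]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  means <- stats::aggregate(measured_v ~ true_v, tab, mean, na.rm = TRUE)
  fit <- if (nrow(means) >= 2) linearFit(means$true_v, means$measured_v)
         else NULL
  new("SweepResult", table = tab, fit = fit, sweepType = "velocity",
      modality = modality, baseSeed = as.integer(baseSeed),
      config = list(velocities = velocities, alphaDeg = alphaDeg,
                    nReps = nReps,
                    cfg = if (modality == "linescan") lineScanCfg else sloCfg))
}

#' Vessel-angle sweep at fixed belt velocity
#'
#' Simulates and estimates line-scan acquisitions over a grid of vessel
#' angles at a constant belt velocity (default 3.82 mm/s, angles 0-90 deg
#' in 10 deg steps), applying only the sec(alpha) correction. At 90 deg
#' the correction is undefined and the row is recorded as a flagged
#' failure rather than an estimate.
#'
#' @param vMmS true belt velocity (mm/s).
#' @param angles vessel angles in degrees, within [0, 90].
#' @param nReps seeded replicates per angle.
#' @param baseSeed integer seed root.
#' @param lineScanCfg a [LineScanConfig-class] template.
#' @param optics an [OpticsConfig-class]; the angle experiment on the
#'   physical phantom used the 30 mm achromat.
#' @param totalDensity,fluorescentDensity bead densities per mm^2.
#' @param alphaMaxDeg angles at or above this are flagged as failures
#'   (sec correction breakdown).
#' @param ... extra arguments to [detectStreakSlopes()].
#' @return a [SweepResult-class]; `@table` has columns `alpha_deg`, `rep`,
#'   `seed`, `measured_v`, `percent_error` (signed,
#'   100 (measured - true) / true), `abs_percent_error`, `n`, `failed`.
#' @export
runAngleSweep <- function(vMmS = 3.82, angles = seq(0, 90, by = 10),
                          nReps = 3, baseSeed = 1,
                          lineScanCfg = lineScanConfig(),
                          optics = opticsConfig(30),
                          totalDensity = 580, fluorescentDensity = 40,
                          alphaMaxDeg = 89, ...) {
  stopifnot(all(angles >= 0 & angles <= 90))
  rows <- list()
  k <- 0L
  for (a in angles) {
    for (r in seq_len(nReps)) {
      k <- k + 1L
      sd_ <- .deriveSeed(baseSeed, 100000 + k)
      row <- data.frame(alpha_deg = a, rep = r, seed = sd_,
                        measured_v = NA_real_, percent_error = NA_real_,
                        abs_percent_error = NA_real_, n = NA_integer_,
                        failed = FALSE)
      if (a >= alphaMaxDeg) {
        row$failed <- TRUE
      } else {
        est <- tryCatch({
          st <- phantomState(vMmS, a, optics)
          cfg <- methods::initialize(lineScanCfg, seed = sd_)
          fld <- generateBeadField(lineScanFieldArea(st, cfg), totalDensity,
                                   fluorescentDensity, seed = sd_)
          estimateVelocity(simulateSpaceTime(st, fld, cfg), ...)
        }, error = function(e) NULL)
        if (is.null(est) || est@nStreaks == 0L) {
          row$failed <- TRUE
        } else {
          row$measured_v <- est@velocityMmS
          row$percent_error <- 100 * (est@velocityMmS - vMmS) / vMmS
          row$abs_percent_error <- abs(row$percent_error)
          row$n <- est@nStreaks
        }
      }
      rows[[k]] <- row
    }
  }
  new("SweepResult", table = do.call(rbind, rows), fit = NULL,
      sweepType = "angle", modality = "linescan",
      baseSeed = as.integer(baseSeed),
      config = list(vMmS = vMmS, angles = angles, nReps = nReps,
                    cfg = lineScanCfg))
}

#' Fit a cubic vessel-angle response model
#'
#' Least-squares cubic of measured velocity (mm/s) against vessel angle
#' (degrees): y = c3 x^3 + c2 x^2 + c1 x + c0.
#'
#' @param angles vessel angles in degrees; at least 5 distinct values.
#' @param measuredVelocities measured velocities (mm/s), same length.
#' @return an [AngleModel-class].
#' @examples
#' m <- referenceAngleModel()
#' fitAngleModel(0:90, evaluateAngleModel(m, 0:90))
#' @export
fitAngleModel <- function(angles, measuredVelocities) {
  stopifnot(length(angles) == length(measuredVelocities))
  if (length(unique(angles)) < 5)
    stop("need at least 5 distinct angles for a cubic fit")
  fit <- stats::lm(measuredVelocities ~ angles + I(angles^2) + I(angles^3))
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  sst <- sum((measuredVelocities - mean(measuredVelocities))^2)
  new("AngleModel",
      coefficients = c(c3 = unname(co[4]), c2 = unname(co[3]),
                       c1 = unname(co[2]), c0 = unname(co[1])),
      rSquared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_)
}

#' Reference cubic vessel-angle model
#'
#' The cubic vessel-angle response reported for an AO-SLO line-scan
#' instrument calibrated with the physical phantom at 3.82 mm/s:
#' y = 8.44e-5 x^3 - 0.007 x^2 + 0.223 x + 1.9 (x in degrees, y in mm/s).
#' Instrument-specific; provided as the reference input for the
#' angle-correction workflow.
#'
#' @return an [AngleModel-class].
#' @examples
#' evaluateAngleModel(referenceAngleModel(), 0)  # 1.9
#' @export
referenceAngleModel <- function() {
  new("AngleModel",
      coefficients = c(c3 = 8.44e-5, c2 = -0.007, c1 = 0.223, c0 = 1.9),
      rSquared = NA_real_)
}

#' Evaluate an angle model
#'
#' @param model an [AngleModel-class].
#' @param angleDeg vessel angle(s) in degrees, within [0, 90].
#' @return predicted measured velocity (mm/s).
#' @export
evaluateAngleModel <- function(model, angleDeg) {
  if (any(angleDeg < 0 | angleDeg > 90))
    stop("angle model is defined on [0, 90] degrees")
  co <- model@coefficients
  co["c3"] * angleDeg^3 + co["c2"] * angleDeg^2 + co["c1"] * angleDeg +
    co["c0"]
}

#' Vessel-angle correction factor
#'
#' Derives the multiplicative correction factor v_ref / model(alpha) from
#' a fitted cubic angle model: applied to a measurement taken at vessel
#' angle alpha, it rescales the model's systematic angle response back to
#' the reference velocity. Proposed for steep angles (40-90 deg) where the
#' plain secant correction breaks down; the model is only validated at
#' the velocity it was fitted at.
#'
#' @param model an [AngleModel-class] fitted at `vReference`.
#' @param alphaDeg vessel angle(s) in degrees, within [40, 90].
#' @param vReference reference (true) velocity the model was fitted at
#'   (mm/s); default 3.82.
#' @return dimensionless correction factor(s).
#' @examples
#' angleCorrectionFactor(referenceAngleModel(), 45)
#' @export
angleCorrectionFactor <- function(model, alphaDeg, vReference = 3.82) {
  if (any(alphaDeg < 40 | alphaDeg > 90))
    stop("the angle correction is proposed for alpha in [40, 90] degrees")
  y <- evaluateAngleModel(model, alphaDeg)
  if (any(y <= 0)) stop("model evaluates to a non-positive velocity")
  vReference / y
}
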