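#' @include RcppExports.R
NULL

## ---------------------------------------------------------------------------
## Phantom hardware model
## ---------------------------------------------------------------------------

#' Motor voltage-to-velocity calibration
#'
#' Parameters of the affine DC-motor calibration mapping drive voltage to
#' belt linear velocity. The motor needs a minimum voltage before the belt
#' starts to move (a dead zone), and the usable voltage range is bounded by
#' the motor rating. Defaults reproduce the two printed calibration
#' endpoints of the physical phantom (1.5 V -> 0.5 mm/s, 11 V -> 7 mm/s).
#'
#' @slot gain numeric(1), mm/s per volt (> 0).
#' @slot offset numeric(1), mm/s.
#' @slot deadZoneV numeric(1), volts; belt does not move for |V| below this.
#' @slot vMinVolts,vMaxVolts numeric(1), operational voltage bounds (volts).
#' @slot jitterFraction numeric(1), optional relative SD of the
#'   instantaneous belt velocity (multiplicative Gaussian jitter); 0 = off.
#' @seealso [motorCalibration()], [voltageToBeltVelocity()]
#' @exportClass MotorCalibration
setClass("MotorCalibration",
  representation(
    gain = "numeric",
    offset = "numeric",
    deadZoneV = "numeric",
    vMinVolts = "numeric",
    vMaxVolts = "numeric",
    jitterFraction = "numeric"
  )
)

setValidity("MotorCalibration", function(object) {
  msg <- character()
  if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain <= 0)
    msg <- c(msg, "'gain' must be a single positive finite number")
  if (length(object@offset) != 1L || !is.finite(object@offset))
    msg <- c(msg, "'offset' must be a single finite number")
  if (object@deadZoneV < 0)
    msg <- c(msg, "'deadZoneV' must be >= 0")
  if (abs(object@vMinVolts) > 12 || object@vMaxVolts > 12)
    msg <- c(msg, "voltage bounds exceed the 12 V motor rating")
  if (object@vMinVolts >= object@vMaxVolts)
    msg <- c(msg, "'vMinVolts' must be below 'vMaxVolts'")
  if (object@jitterFraction < 0)
    msg <- c(msg, "'jitterFraction' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Timing-pulley geometry
#'
#' Radius of the synchronous timing pulley that converts motor shaft
#' rotation into belt translation. The default 6 mm radius corresponds to
#' the 12 mm diameter GT2 pulley of the physical phantom.
#'
#' @slot radiusMm numeric(1), effective pulley radius in mm (> 0).
#' @seealso [pulleyGeometry()], [angularToLinear()]
#' @exportClass PulleyGeometry
setClass("PulleyGeometry", representation(radiusMm = "numeric"))

setValidity("PulleyGeometry", function(object) {
  if (length(object@radiusMm) != 1L || !is.finite(object@radiusMm) ||
      object@radiusMm <= 0)
    "'radiusMm' must be a single positive number"
  else TRUE
})

#' Focusing-optics configuration
#'
#' The achromat lens in front of the belt focuses the scan onto the bead
#' monolayer; under the paraxial approximation a scan angle theta maps to a
#' lateral distance f * theta (radians) at the focal plane. The phantom is
#' used in air (refractive index 1).
#'
#' @slot focalLengthMm numeric(1), lens focal length in mm (20 or 30 for
#'   the physical phantom).
#' @slot refractiveIndex numeric(1), medium refractive index (>= 1).
#' @seealso [opticsConfig()], [scanAngleToLateral()]
#' @exportClass OpticsConfig
setClass("OpticsConfig",
  representation(focalLengthMm = "numeric", refractiveIndex = "numeric")
)

setValidity("OpticsConfig", function(object) {
  msg <- character()
  if (length(object@focalLengthMm) != 1L || !is.finite(object@focalLengthMm) ||
      object@focalLengthMm <= 0)
    msg <- c(msg, "'focalLengthMm' must be a single positive number")
  if (object@refractiveIndex < 1)
    msg <- c(msg, "'refractiveIndex' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Ground-truth state of the phantom
#'
#' The belt velocity and vessel angle against which all velocity estimates
#' are judged. The vessel angle alpha is the angle between the belt (flow)
#' direction and the fast-scan line, mimicking retinal vessel orientation.
#'
#' @slot beltVelocityMmS numeric(1), signed belt velocity in mm/s.
#' @slot vesselAngleDeg numeric(1), alpha in degrees, in [0, 90].
#' @slot optics an [OpticsConfig-class] object.
#' @seealso [phantomState()]
#' @exportClass PhantomState
setClass("PhantomState",
  representation(
    beltVelocityMmS = "numeric",
    vesselAngleDeg = "numeric",
    optics = "OpticsConfig"
  )
)

setValidity("PhantomState", function(object) {
  msg <- character()
  if (length(object@beltVelocityMmS) != 1L || !is.finite(object@beltVelocityMmS))
    msg <- c(msg, "'beltVelocityMmS' must be a single finite number")
  if (length(object@vesselAngleDeg) != 1L ||
      object@vesselAngleDeg < 0 || object@vesselAngleDeg > 90)
    msg <- c(msg, "'vesselAngleDeg' must be in [0, 90]")
  if (length(msg)) msg else TRUE
})

#' Stochastic bead monolayer
#'
#' A homogeneous spatial Poisson process of polystyrene microspheres (10 um
#' nominal diameter) on a rectangular patch of the slide, with a sparse
#' subset flagged fluorescent, emulating the drop-cast monolayer affixed to
#' the phantom belt. Fig.-2-style reference densities are ~580 total and
#' ~40 fluorescent particles/mm^2.
#'
#' @slot beads data.frame with columns `x_mm`, `y_mm`, `radius_um`,
#'   `is_fluorescent`.
#' @slot area numeric(4), named `xmin`, `xmax`, `ymin`, `ymax` in mm.
#' @slot totalDensity numeric(1), beads per mm^2.
#' @slot fluorescentDensity numeric(1), fluorescent beads per mm^2.
#' @slot seed integer(1), RNG seed used for generation.
#' @seealso [generateBeadField()], [beadTable()]
#' @exportClass BeadField
setClass("BeadField",
  representation(
    beads = "data.frame",
    area = "numeric",
    totalDensity = "numeric",
    fluorescentDensity = "numeric",
    seed = "integer"
  )
)

setValidity("BeadField", function(object) {
  msg <- character()
  need <- c("x_mm", "y_mm", "radius_um", "is_fluorescent")
  if (!all(need %in% names(object@beads)))
    msg <- c(msg, paste("'beads' must have columns", paste(need, collapse = ", ")))
  if (length(object@area) != 4L ||
      !all(c("xmin", "xmax", "ymin", "ymax") %in% names(object@area)))
    msg <- c(msg, "'area' must be named numeric(4): xmin, xmax, ymin, ymax")
  else if (object@area["xmin"] >= object@area["xmax"] ||
           object@area["ymin"] >= object@area["ymax"])
    msg <- c(msg, "'area' must have positive extent")
  else if (nrow(object@beads) &&
           (any(object@beads$x_mm < object@area["xmin"]) ||
            any(object@beads$x_mm > object@area["xmax"]) ||
            any(object@beads$y_mm < object@area["ymin"]) ||
            any(object@beads$y_mm > object@area["ymax"])))
    msg <- c(msg, "bead centers must lie inside 'area'")
  if (object@totalDensity < 0 || object@fluorescentDensity < 0 ||
      object@fluorescentDensity > object@totalDensity)
    msg <- c(msg, "need 0 <= fluorescentDensity <= totalDensity")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Acquisition configurations and data products
## ---------------------------------------------------------------------------

#' AO-SLO line-scan acquisition configuration
#'
#' Defaults follow the AO-SLO line-scan channel used to evaluate the
#' physical phantom: resonant scanner at 13.6 kHz (one line per resonant
#' period), 1.5 degree fast-scan field of view. Pixels per line and lines
#' per acquisition are engineering choices.
#'
#' @slot lineRateHz numeric(1), lines per second.
#' @slot pixelsPerLine integer(1), >= 16.
#' @slot fovDeg numeric(1), fast-scan field of view in degrees.
#' @slot nLines integer(1), lines per space-time acquisition (>= 2).
#' @slot psfSigmaUm numeric(1), Gaussian PSF sigma in um.
#' @slot backgroundLevel numeric(1), mean background photon level.
#' @slot photonScale numeric(1), photons at a bead-profile peak.
#' @slot photonGain numeric(1), output units per detected photon.
#' @slot readNoiseSd numeric(1), Gaussian read-noise SD (output units).
#' @slot shotNoise logical(1), apply Poisson shot noise?
#' @slot seed integer(1), RNG seed for the noise realization.
#' @seealso [lineScanConfig()], [simulateSpaceTime()]
#' @exportClass LineScanConfig
setClass("LineScanConfig",
  representation(
    lineRateHz = "numeric",
    pixelsPerLine = "integer",
    fovDeg = "numeric",
    nLines = "integer",
    psfSigmaUm = "numeric",
    backgroundLevel = "numeric",
    photonScale = "numeric",
    photonGain = "numeric",
    readNoiseSd = "numeric",
    shotNoise = "logical",
    seed = "integer"
  )
)

setValidity("LineScanConfig", function(object) {
  msg <- character()
  if (object@lineRateHz <= 0) msg <- c(msg, "'lineRateHz' must be > 0")
  if (object@pixelsPerLine < 16L) msg <- c(msg, "'pixelsPerLine' must be >= 16")
  if (object@fovDeg <= 0) msg <- c(msg, "'fovDeg' must be > 0")
  if (object@nLines < 2L) msg <- c(msg, "'nLines' must be >= 2")
  if (object@psfSigmaUm <= 0) msg <- c(msg, "'psfSigmaUm' must be > 0")
  if (object@backgroundLevel < 0 || object@photonScale < 0 ||
      object@readNoiseSd < 0 || object@photonGain <= 0)
    msg <- c(msg, "intensity-model parameters must be non-negative (gain > 0)")
  if (length(msg)) msg else TRUE
})

#' Space-time (kymograph) image
#'
#' The line-scan data product: a 2D intensity array with one temporal axis
#' (line index, rows) and one spatial axis (pixel along the scan line,
#' columns). A bead crossing the stationary scan line traces a streak whose
#' slope Dx/Dt is its along-line velocity component v * cos(alpha).
#'
#' @slot intensity numeric matrix `[line, pixel]`, non-negative.
#' @slot linePeriodS numeric(1), seconds between successive lines.
#' @slot pixelPitchMm numeric(1), lateral mm per pixel at the focal plane.
#' @slot vesselAngleDeg numeric(1), alpha copied from the generating
#'   [PhantomState-class] (NA when unknown, e.g. external data).
#' @slot provenance list; generating configuration and seed.
#' @seealso [simulateSpaceTime()], [detectStreakSlopes()]
#' @exportClass SpaceTimeImage
setClass("SpaceTimeImage",
  representation(
    intensity = "matrix",
    linePeriodS = "numeric",
    pixelPitchMm = "numeric",
    vesselAngleDeg = "numeric",
    provenance = "list"
  )
)

setValidity("SpaceTimeImage", function(object) {
  msg <- character()
  if (!is.numeric(object@intensity) || any(object@intensity < 0))
    msg <- c(msg, "'intensity' must be a non-negative numeric matrix")
  if (object@linePeriodS <= 0) msg <- c(msg, "'linePeriodS' must be > 0")
  if (object@pixelPitchMm <= 0) msg <- c(msg, "'pixelPitchMm' must be > 0")
  if (length(msg)) msg else TRUE
})

#' Clinical-SLO video acquisition configuration
#'
#' Defaults follow the clinical confocal SLO operated in ICGA mode for
#' erythrocyte-mediated-angiography-style imaging: 15 degree field of view
#' sampled at 15.4 fps for 5 s. The lateral scale is derived from the
#' phantom optics in air unless set explicitly.
#'
#' @slot fps numeric(1), frames per second.
#' @slot fovDeg numeric(1), field of view in degrees.
#' @slot pixels integer(2), frame size (rows, cols).
#' @slot durationS numeric(1), video duration in seconds.
#' @slot umPerPixel numeric(1), lateral scale; `NA` = derive from optics.
#' @slot psfSigmaUm numeric(1), Gaussian PSF sigma in um.
#' @slot backgroundLevel,photonScale,photonGain,readNoiseSd,shotNoise
#'   intensity model, as in [LineScanConfig-class].
#' @slot brightnessSdLog numeric(1), log-SD of the lognormal per-bead
#'   fluorescence amplitude distribution (0 = uniform brightness);
#'   dye-loaded microspheres vary widely in emission, and the tracked
#'   "well-resolved" subset is the bright tail.
#' @slot seed integer(1), RNG seed for the noise realization.
#' @seealso [sloVideoConfig()], [simulateIcgaVideo()]
#' @exportClass SLOVideoConfig
setClass("SLOVideoConfig",
  representation(
    fps = "numeric",
    fovDeg = "numeric",
    pixels = "integer",
    durationS = "numeric",
    umPerPixel = "numeric",
    psfSigmaUm = "numeric",
    backgroundLevel = "numeric",
    photonScale = "numeric",
    photonGain = "numeric",
    readNoiseSd = "numeric",
    shotNoise = "logical",
    brightnessSdLog = "numeric",
    seed = "integer"
  )
)

setValidity("SLOVideoConfig", function(object) {
  msg <- character()
  if (object@fps <= 0) msg <- c(msg, "'fps' must be > 0")
  if (object@fovDeg <= 0) msg <- c(msg, "'fovDeg' must be > 0")
  if (length(object@pixels) != 2L || any(object@pixels < 16L))
    msg <- c(msg, "'pixels' must be integer(2) >= 16")
  if (object@durationS * object@fps < 2)
    msg <- c(msg, "'durationS' must cover at least 2 frames")
  if (!is.na(object@umPerPixel) && object@umPerPixel <= 0)
    msg <- c(msg, "'umPerPixel' must be > 0 (or NA to derive from optics)")
  if (object@psfSigmaUm <= 0) msg <- c(msg, "'psfSigmaUm' must be > 0")
  if (object@brightnessSdLog < 0)
    msg <- c(msg, "'brightnessSdLog' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Frame video
#'
#' A stack of 2D frames with frame rate and lateral scale; the data product
#' of clinical-SLO style acquisition (and of raster-mode AO-SLO imaging).
#'
#' @slot frames numeric 3D array `[frame, row, col]`, non-negative.
#' @slot fps numeric(1), frames per second.
#' @slot umPerPixel numeric(1), lateral scale in um per pixel.
#' @slot provenance list; generating configuration and seed.
#' @seealso [simulateIcgaVideo()], [maxIntensityProjection()], [trackVideo()]
#' @exportClass FrameVideo
setClass("FrameVideo",
  representation(
    frames = "array",
    fps = "numeric",
    umPerPixel = "numeric",
    provenance = "list"
  )
)

setValidity("FrameVideo", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "'frames' must be a 3D array [frame, row, col]")
  else if (dim(object@frames)[1] < 1L)
    msg <- c(msg, "'frames' must contain at least one frame")
  if (any(object@frames < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@fps <= 0) msg <- c(msg, "'fps' must be > 0")
  if (object@umPerPixel <= 0) msg <- c(msg, "'umPerPixel' must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Analysis results
## ---------------------------------------------------------------------------

#' Analytic streak prediction
#'
#' Closed-form geometry of the streak a single bead traces on a space-time
#' image: the along-line slope v * cos(alpha), the dwell time the bead
#' spends on the scan line, and the line-crossing coordinates. Serves as
#' the independent oracle for the streak velocimetry.
#'
#' @slot slopeMmS numeric(1), true Dx/Dt in mm/s (= v cos alpha).
#' @slot dwellS numeric(1), streak duration in seconds.
#' @slot entryTimeS,exitTimeS numeric(1), first/last time on the line (s).
#' @slot entryXMm numeric(1), along-line position at entry (mm).
#' @seealso [predictStreak()]
#' @exportClass StreakPrediction
setClass("StreakPrediction",
  representation(
    slopeMmS = "numeric",
    dwellS = "numeric",
    entryTimeS = "numeric",
    exitTimeS = "numeric",
    entryXMm = "numeric"
  )
)

#' Per-acquisition velocity estimate
#'
#' Summary of per-streak corrected velocities from one space-time
#' acquisition: mean velocity, dispersion and streak count. An empty
#' estimate (`nStreaks == 0`) is the explicit no-estimate result.
#'
#' @slot velocityMmS numeric(1), mean corrected velocity (NA if no streaks).
#' @slot alphaDeg numeric(1), vessel angle used for the sec correction.
#' @slot nStreaks integer(1), number of streak measurements used.
#' @slot sdMmS numeric(1), SD of per-streak velocities.
#' @slot relativeSdPercent numeric(1), 100 * sd / |mean|.
#' @slot measurements data.frame of per-streak measurements (see
#'   [detectStreakSlopes()]).
#' @seealso [summarizeAcquisition()], [estimateVelocity()]
#' @exportClass VelocityEstimate
setClass("VelocityEstimate",
  representation(
    velocityMmS = "numeric",
    alphaDeg = "numeric",
    nStreaks = "integer",
    sdMmS = "numeric",
    relativeSdPercent = "numeric",
    measurements = "data.frame"
  )
)

setValidity("VelocityEstimate", function(object) {
  if (object@nStreaks > 0 && !is.finite(object@velocityMmS))
    "'velocityMmS' must be finite when streaks are present"
  else TRUE
})

#' Ordinary least-squares line fit
#'
#' @slot slope,intercept numeric(1), fitted coefficients.
#' @slot rSquared numeric(1), coefficient of determination in [0, 1]
#'   (NA for n < 3).
#' @slot residualSd numeric(1), sqrt(SSE / (n - 2)) for n > 2.
#' @slot n integer(1), number of points.
#' @seealso [linearFit()]
#' @exportClass LinearFit
setClass("LinearFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    residualSd = "numeric",
    n = "integer"
  )
)

setValidity("LinearFit", function(object) {
  msg <- character()
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    msg <- c(msg, "'rSquared' must be in [0, 1]")
  if (!is.na(object@residualSd) && object@residualSd < 0)
    msg <- c(msg, "'residualSd' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Cubic vessel-angle response model
#'
#' Cubic polynomial mapping vessel angle x (degrees) to measured line-scan
#' velocity y (mm/s), used to characterize the non-linear growth of the
#' uncorrected measurement error above ~45 degrees and to derive an
#' opt-in angle-correction factor.
#'
#' @slot coefficients numeric(4), named `c3`, `c2`, `c1`, `c0` so that
#'   y = c3 x^3 + c2 x^2 + c1 x + c0.
#' @slot rSquared numeric(1), fit r^2 (NA for an externally supplied model).
#' @seealso [fitAngleModel()], [referenceAngleModel()],
#'   [angleCorrectionFactor()]
#' @exportClass AngleModel
setClass("AngleModel",
  representation(coefficients = "numeric", rSquared = "numeric")
)

setValidity("AngleModel", function(object) {
  if (length(object@coefficients) != 4L || any(!is.finite(object@coefficients)))
    "'coefficients' must be 4 finite numbers (c3, c2, c1, c0)"
  else TRUE
})

#' Simulation sweep result
#'
#' Rows of (true velocity or angle) x replicate estimates from a seeded
#' simulate-then-estimate sweep, with the derived linear fit (velocity
#' sweeps) and full provenance for bit-exact reproduction.
#'
#' @slot table data.frame of per-replicate results.
#' @slot fit a [LinearFit-class] (velocity sweeps) or NULL.
#' @slot sweepType character(1), "velocity" or "angle".
#' @slot modality character(1), "linescan" or "frames".
#' @slot baseSeed integer(1).
#' @slot config list, configuration snapshot.
#' @seealso [runVelocitySweep()], [runAngleSweep()]
#' @exportClass SweepResult
setClass("SweepResult",
  representation(
    table = "data.frame",
    fit = "ANY",
    sweepType = "character",
    modality = "character",
    baseSeed = "integer",
    config = "list"
  )
)

#' Particle-tracking result
#'
#' Tracks linked across frames with per-track mean speeds and the
#' per-video mean velocity, computed from at least `minTracks` qualifying
#' traces (default 20) as in erythrocyte-mediated angiography practice.
#'
#' @slot spots data.frame of all detected spots (frame, x, y, response).
#' @slot tracks data.frame with columns `track_id`, `frame`, `x`, `y`
#'   (pixels).
#' @slot trackStats data.frame of per-track statistics (length, mean
#'   step speed, net speed, in mm/s).
#' @slot meanVelocityMmS numeric(1), mean over qualifying tracks (NA when
#'   none qualify).
#' @slot sdMmS numeric(1), SD over qualifying tracks.
#' @slot nTracksUsed integer(1), number of qualifying tracks.
#' @slot lowConfidence logical(1), TRUE when fewer than `minTracks`
#'   qualifying tracks were available.
#' @seealso [trackVideo()], [computeVelocities()]
#' @exportClass TrackingResult
setClass("TrackingResult",
  representation(
    spots = "data.frame",
    tracks = "data.frame",
    trackStats = "data.frame",
    meanVelocityMmS = "numeric",
    sdMmS = "numeric",
    nTracksUsed = "integer",
    lowConfidence = "logical"
  )
)
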