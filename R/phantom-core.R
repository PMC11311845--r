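#' @include AllGenerics.R
NULL

## Default calibration line through the two printed endpoints
## (1.5 V, 0.5 mm/s) and (11 V, 7 mm/s).
.DEFAULT_GAIN <- 6.5 / 9.5
.DEFAULT_OFFSET <- 0.5 - .DEFAULT_GAIN * 1.5

#' Construct a motor calibration
#'
#' The voltage-to-velocity map is affine in |V| outside a dead zone:
#' v(V) = sign(V) * max(0, gain * |V| + offset) for |V| > deadZoneV, and 0
#' inside the dead zone. Defaults are the two-point line through
#' (1.5 V, 0.5 mm/s) and (11 V, 7 mm/s), with a 0.5 V dead zone, matching
#' the physical phantom's calibration endpoints.
#'
#' @param gain mm/s per volt.
#' @param offset mm/s.
#' @param deadZoneV dead-zone half width in volts.
#' @param vMinVolts,vMaxVolts operational voltage bounds (|.| <= 12).
#' @param jitterFraction relative SD of instantaneous velocity (0 = off).
#' @return a [MotorCalibration-class] object.
#' @examples
#' cal <- motorCalibration()
#' voltageToBeltVelocity(c(0.3, 1.5, 11), cal)
#' @export
motorCalibration <- function(gain = .DEFAULT_GAIN, offset = .DEFAULT_OFFSET,
                             deadZoneV = 0.5, vMinVolts = -12,
                             vMaxVolts = 12, jitterFraction = 0) {
  new("MotorCalibration", gain = gain, offset = offset, deadZoneV = deadZoneV,
      vMinVolts = vMinVolts, vMaxVolts = vMaxVolts,
      jitterFraction = jitterFraction)
}

#' Construct a pulley geometry
#'
#' @param radiusMm effective pulley radius in mm (default 6, i.e. a 12 mm
#'   diameter timing pulley).
#' @return a [PulleyGeometry-class] object.
#' @export
pulleyGeometry <- function(radiusMm = 6.0) {
  new("PulleyGeometry", radiusMm = radiusMm)
}

#' Construct an optics configuration
#'
#' @param focalLengthMm lens focal length in mm (20 or 30 on the physical
#'   phantom).
#' @param refractiveIndex medium refractive index (1 = air).
#' @return an [OpticsConfig-class] object.
#' @export
opticsConfig <- function(focalLengthMm = 20, refractiveIndex = 1.0) {
  new("OpticsConfig", focalLengthMm = focalLengthMm,
      refractiveIndex = refractiveIndex)
}

#' Construct a phantom ground-truth state
#'
#' @param beltVelocityMmS signed belt velocity in mm/s (physiological range
#'   0.5-7 mm/s).
#' @param vesselAngleDeg vessel angle alpha in degrees, in [0, 90]: the
#'   angle between belt motion and the fast-scan line.
#' @param optics an [OpticsConfig-class].
#' @return a [PhantomState-class] object.
#' @examples
#' phantomState(3.82, vesselAngleDeg = 30)
#' @export
phantomState <- function(beltVelocityMmS, vesselAngleDeg = 0,
                         optics = opticsConfig()) {
  new("PhantomState", beltVelocityMmS = beltVelocityMmS,
      vesselAngleDeg = vesselAngleDeg, optics = optics)
}

#' Motor voltage to belt velocity
#'
#' Applies the affine calibration with dead zone. The map is odd in
#' voltage, zero on `[-deadZoneV, deadZoneV]`, and clipped at zero from
#' below outside the dead zone.
#'
#' @param voltage drive voltage(s) in volts; must satisfy
#'   `vMinVolts <= voltage <= vMaxVolts`.
#' @param cal a [MotorCalibration-class].
#' @return belt velocity in mm/s, signed, same length as `voltage`.
#' @examples
#' voltageToBeltVelocity(11, motorCalibration())   # 7 mm/s
#' voltageToBeltVelocity(-11, motorCalibration())  # -7 mm/s
#' @export
voltageToBeltVelocity <- function(voltage, cal = motorCalibration()) {
  stopifnot(is.numeric(voltage))
  if (any(voltage < cal@vMinVolts | voltage > cal@vMaxVolts))
    stop("voltage outside the motor's operational range [",
         cal@vMinVolts, ", ", cal@vMaxVolts, "] V")
  av <- abs(voltage)
  v <- pmax(0, cal@gain * av + cal@offset)
  v[av <= cal@deadZoneV] <- 0
  sign(voltage) * v
}

#' Pulley angular velocity to belt linear velocity
#'
#' v = omega * (pi / 180) * radius, for omega in degrees/s.
#'
#' @param omegaDegS angular velocity of the pulley in degrees per second.
#' @param pulley a [PulleyGeometry-class].
#' @return linear belt velocity in mm/s.
#' @examples
#' angularToLinear(60, pulleyGeometry(6))  # 6.2832 mm/s
#' @export
angularToLinear <- function(omegaDegS, pulley = pulleyGeometry()) {
  omegaDegS * (pi / 180) * pulley@radiusMm
}

#' Scan angle to lateral distance at the focal plane
#'
#' Paraxial mapping: lateral = f * theta(radians). A guard rejects angles
#' where the small-angle approximation is no longer meaningful.
#'
#' @param thetaDeg scan angle(s) in degrees; |theta| must be below
#'   `maxAngleDeg`.
#' @param optics an [OpticsConfig-class].
#' @param maxAngleDeg paraxial validity guard (degrees).
#' @return lateral distance in mm.
#' @examples
#' scanAngleToLateral(1.5, opticsConfig(20))  # 0.5236 mm
#' @export
scanAngleToLateral <- function(thetaDeg, optics = opticsConfig(),
                               maxAngleDeg = 10) {
  if (any(abs(thetaDeg) >= maxAngleDeg))
    stop("scan angle beyond the paraxial guard (|theta| < ",
         maxAngleDeg, " deg)")
  optics@focalLengthMm * thetaDeg * pi / 180
}

#' Sampled instantaneous belt-velocity series
#'
#' Emulates a repeatability measurement: the nominal calibrated velocity
#' with optional multiplicative Gaussian jitter (relative SD
#' `jitterFraction`) on each sample.
#'
#' @param voltage drive voltage in volts.
#' @param cal a [MotorCalibration-class].
#' @param n number of samples.
#' @param seed RNG seed.
#' @return numeric vector of n instantaneous velocities (mm/s).
#' @seealso [repeatabilityPercentSD()]
#' @export
beltVelocitySeries <- function(voltage, cal = motorCalibration(), n = 100,
                               seed = 1) {
  v0 <- voltageToBeltVelocity(voltage, cal)
  if (cal@jitterFraction == 0) return(rep(v0, n))
  withr::with_seed(as.integer(seed),
    v0 * (1 + stats::rnorm(n, sd = cal@jitterFraction)))
}

#' Generate a stochastic bead monolayer
#'
#' Bead centers form a homogeneous spatial Poisson process on the given
#' rectangle: the count is Poisson(density x area) and positions are
#' i.i.d. uniform. Each bead is independently flagged fluorescent with
#' probability `fluorescentDensity / totalDensity`. An optional
#' minimum-separation (dart-throwing) mode is available but off by
#' default: at the reference densities (~580/mm^2 of 10 um beads, ~4.6%
#' area fraction) collisions are rare.
#'
#' @param areaMm rectangle `c(xmin, xmax, ymin, ymax)` in mm.
#' @param totalDensity total bead density per mm^2 (reference ~580).
#' @param fluorescentDensity fluorescent bead density per mm^2
#'   (reference ~40); must not exceed `totalDensity`.
#' @param beadRadiusUm bead radius in um (default 5, i.e. 10 um nominal
#'   diameter polystyrene microspheres).
#' @param seed RNG seed; generation is reproducible given the seed.
#' @param minSeparationUm minimum center-to-center separation in um
#'   (0 = pure Poisson process, the default). With a positive separation
#'   the bead count is still Poisson(density x area) but positions are
#'   placed by random sequential adsorption (hard-disk packing), as on a
#'   physical drop-cast monolayer where beads cannot overlap.
#' @return a [BeadField-class] object.
#' @examples
#' fld <- generateBeadField(c(0, 1, 0, 1), 580, 40, seed = 7)
#' fld
#' @export
generateBeadField <- function(areaMm, totalDensity = 580,
                              fluorescentDensity = 40, beadRadiusUm = 5,
                              seed = 1, minSeparationUm = 0) {
  if (length(areaMm) != 4L) stop("'areaMm' must be c(xmin, xmax, ymin, ymax)")
  areaMm <- stats::setNames(as.numeric(areaMm),
                            c("xmin", "xmax", "ymin", "ymax"))
  if (totalDensity < 0 || fluorescentDensity < 0)
    stop("densities must be non-negative")
  if (fluorescentDensity > totalDensity)
    stop("'fluorescentDensity' must not exceed 'totalDensity'")
  w <- areaMm["xmax"] - areaMm["xmin"]
  h <- areaMm["ymax"] - areaMm["ymin"]
  if (w <= 0 || h <= 0) stop("'areaMm' must have positive extent")
  seed <- as.integer(seed)

  beads <- withr::with_seed(seed, {
    n <- stats::rpois(1, totalDensity * w * h)
    if (n == 0L) {
      data.frame(x_mm = numeric(0), y_mm = numeric(0),
                 radius_um = numeric(0), is_fluorescent = logical(0))
    } else {
      if (minSeparationUm > 0) {
        xy <- .sequentialAdsorption(n, areaMm, minSeparationUm / 1000)
        x <- xy$x; y <- xy$y; n <- length(x)
      } else {
        x <- stats::runif(n, areaMm["xmin"], areaMm["xmax"])
        y <- stats::runif(n, areaMm["ymin"], areaMm["ymax"])
      }
      pFluor <- if (totalDensity > 0) fluorescentDensity / totalDensity else 0
      data.frame(x_mm = x, y_mm = y,
                 radius_um = rep(beadRadiusUm, n),
                 is_fluorescent = stats::runif(n) < pFluor)
    }
  })
  new("BeadField", beads = beads, area = areaMm,
      totalDensity = totalDensity, fluorescentDensity = fluorescentDensity,
      seed = seed)
}

## Random sequential adsorption: place n points uniformly, one at a time,
## rejecting proposals closer than minSepMm to any accepted point.
## Feasible far below the hard-disk jamming fraction (the reference
## densities are ~5% area fraction); errors out if packing stalls.
.sequentialAdsorption <- function(n, areaMm, minSepMm, maxTries = 200L) {
  x <- numeric(n); y <- numeric(n)
  placed <- 0L
  d2 <- minSepMm^2
  while (placed < n) {
    tries <- 0L
    repeat {
      px <- stats::runif(1, areaMm["xmin"], areaMm["xmax"])
      py <- stats::runif(1, areaMm["ymin"], areaMm["ymax"])
      if (placed == 0L ||
          min((x[seq_len(placed)] - px)^2 + (y[seq_len(placed)] - py)^2) >= d2)
        break
      tries <- tries + 1L
      if (tries >= maxTries)
        stop("cannot place ", n, " beads at the requested separation")
    }
    placed <- placed + 1L
    x[placed] <- px; y[placed] <- py
  }
  list(x = x, y = y)
}

## Translate all bead centers by (dx, dy) mm, keeping metadata.
.shiftBeadField <- function(field, dxMm, dyMm) {
  b <- field@beads
  b$x_mm <- b$x_mm + dxMm
  b$y_mm <- b$y_mm + dyMm
  a <- field@area
  a["xmin"] <- a["xmin"] + dxMm; a["xmax"] <- a["xmax"] + dxMm
  a["ymin"] <- a["ymin"] + dyMm; a["ymax"] <- a["ymax"] + dyMm
  methods::initialize(field, beads = b, area = a)
}
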