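#' @include render.R
NULL

#' Construct a line-scan acquisition configuration
#'
#' @param lineRateHz line rate in Hz (default 13600, one line per resonant
#'   period).
#' @param pixelsPerLine pixels along the fast-scan line.
#' @param fovDeg fast-scan field of view in degrees.
#' @param nLines lines per space-time acquisition; the default 4096 lines
#'   (~0.3 s at 13.6 kHz) makes a 3.82 mm/s bead at alpha = 30 deg leave a
#'   streak tens of pixels long.
#' @param psfSigmaUm Gaussian PSF sigma (um); the confocal pinhole is
#'   folded into this single blur parameter.
#' @param backgroundLevel,photonScale,photonGain,readNoiseSd,shotNoise
#'   intensity/noise model; see [LineScanConfig-class].
#' @param seed RNG seed for the noise realization.
#' @return a [LineScanConfig-class] object.
#' @export
lineScanConfig <- function(lineRateHz = 13600, pixelsPerLine = 512L,
                           fovDeg = 1.5, nLines = 4096L, psfSigmaUm = 3,
                           backgroundLevel = 10, photonScale = 50,
                           photonGain = 1, readNoiseSd = 2,
                           shotNoise = TRUE, seed = 1L) {
  new("LineScanConfig", lineRateHz = lineRateHz,
      pixelsPerLine = as.integer(pixelsPerLine), fovDeg = fovDeg,
      nLines = as.integer(nLines), psfSigmaUm = psfSigmaUm,
      backgroundLevel = backgroundLevel, photonScale = photonScale,
      photonGain = photonGain, readNoiseSd = readNoiseSd,
      shotNoise = shotNoise, seed = as.integer(seed))
}

## Lateral scan-line length (mm) and pixel pitch (mm) for a configuration.
.lineLengthMm <- function(state, cfg) {
  scanAngleToLateral(cfg@fovDeg, state@optics)
}
.pixelPitchMm <- function(state, cfg) {
  .lineLengthMm(state, cfg) / cfg@pixelsPerLine
}

#' Analytic streak geometry for a single bead
#'
#' Closed-form prediction of the streak a bead traces on a space-time
#' image: slope Dx/Dt = v cos(alpha); dwell time 2 r_eff / (|v| sin alpha)
#' for alpha > 0 (the line-crossing time is set by the velocity component
#' perpendicular to the scan line), the along-line field-of-view transit
#' time for alpha = 0, and the full acquisition duration for v = 0. The
#' effective radius r_eff = bead radius + 2 psf_sigma accounts for the
#' PSF-broadened profile.
#'
#' @param xMm,yMm bead center at time 0, in mm. The scan line lies along
#'   y = 0, x in `[0, L]`; the belt moves at angle alpha to +x.
#' @param radiusUm bead radius in um.
#' @param state a [PhantomState-class].
#' @param cfg a [LineScanConfig-class].
#' @return a [StreakPrediction-class] object.
#' @examples
#' st <- phantomState(3.82, 30)
#' predictStreak(0.1, -0.1, 5, st, lineScanConfig())
#' @export
predictStreak <- function(xMm, yMm, radiusUm = 5, state, cfg = lineScanConfig()) {
  alpha <- state@vesselAngleDeg
  if (alpha < 0 || alpha > 90) stop("vessel angle must be in [0, 90]")
  v <- state@beltVelocityMmS
  a <- alpha * pi / 180
  slope <- v * cos(a)
  rEffMm <- (radiusUm + 2 * cfg@psfSigmaUm) / 1000
  duration <- cfg@nLines / cfg@lineRateHz
  if (v == 0) {
    dwell <- duration
    entryT <- 0
  } else if (alpha > 0) {
    dwell <- 2 * rEffMm / (abs(v) * sin(a))
    tc <- -yMm / (v * sin(a))  # time the center crosses the scan line
    entryT <- tc - dwell / 2
  } else {
    dwell <- .lineLengthMm(state, cfg) / abs(v)
    entryT <- if (v > 0) (0 - xMm) / v else (.lineLengthMm(state, cfg) - xMm) / v
  }
  new("StreakPrediction", slopeMmS = slope, dwellS = dwell,
      entryTimeS = entryT, exitTimeS = entryT + dwell,
      entryXMm = xMm + v * cos(a) * entryT)
}

#' Simulate a space-time (kymograph) acquisition
#'
#' The slow scanner is held stationary so the same line is sampled at the
#' line rate. For each line time t, bead centers are advanced by v * t
#' along the belt direction (at angle alpha to the scan line); the line
#' samples the Gaussian-blurred bead profiles where they intersect y = 0.
#' Poisson shot noise and Gaussian read noise are applied under the
#' configuration seed; output is bit-identical for identical seeds.
#'
#' @param state a [PhantomState-class] (belt velocity, vessel angle,
#'   optics).
#' @param field a [BeadField-class]; bead positions are taken at time 0.
#' @param cfg a [LineScanConfig-class].
#' @return a [SpaceTimeImage-class] with rows = line index (time) and
#'   columns = pixel along the scan line.
#' @seealso [predictStreak()] for the analytic oracle,
#'   [lineScanFieldArea()] for a field rectangle covering the acquisition.
#' @examples
#' st <- phantomState(3.82, 30)
#' cfg <- lineScanConfig(nLines = 256L)
#' fld <- generateBeadField(lineScanFieldArea(st, cfg), 580, 40, seed = 3)
#' img <- simulateSpaceTime(st, fld, cfg)
#' img
#' @export
simulateSpaceTime <- function(state, field, cfg = lineScanConfig()) {
  v <- state@beltVelocityMmS
  a <- state@vesselAngleDeg * pi / 180
  vx <- v * cos(a)
  vy <- v * sin(a)
  P <- cfg@pixelsPerLine
  L <- cfg@nLines
  pitch <- .pixelPitchMm(state, cfg)
  dt <- 1 / cfg@lineRateHz
  tvec <- (seq_len(L) - 1L) * dt
  xc <- (seq_len(P) - 0.5) * pitch

  b <- beadTable(field)
  sig <- matrix(0, L, P)
  if (nrow(b)) {
    sigMm <- .beadSigmaUm(b$radius_um, cfg@psfSigmaUm) / 1000
    for (k in seq_len(nrow(b))) {
      s <- sigMm[k]
      w <- 4 * s
      ## lines where the bead profile intersects the scan line (y = 0)
      if (vy == 0) {
        if (abs(b$y_mm[k]) > w) next
        li <- 1L; hi <- L
      } else {
        tt <- sort(c((-w - b$y_mm[k]) / vy, (w - b$y_mm[k]) / vy))
        li <- max(1L, ceiling(tt[1] / dt) + 1L)
        hi <- min(L, floor(tt[2] / dt) + 1L)
        if (li > hi) next
      }
      tl <- tvec[li:hi]
      xt <- b$x_mm[k] + vx * tl
      yt <- b$y_mm[k] + vy * tl
      c0 <- max(1L, ceiling((min(xt) - w) / pitch))
      c1 <- min(P, floor((max(xt) + w) / pitch) + 1L)
      if (c0 > c1) next
      ay <- exp(-yt^2 / (2 * s^2))
      dx <- outer(xt, xc[c0:c1], "-")
      sig[li:hi, c0:c1] <- sig[li:hi, c0:c1] +
        ay * exp(-dx^2 / (2 * s^2))
    }
  }
  img <- .applyNoise(sig, cfg@backgroundLevel, cfg@photonScale,
                     cfg@photonGain, cfg@readNoiseSd, cfg@shotNoise,
                     cfg@seed)
  new("SpaceTimeImage", intensity = img, linePeriodS = dt,
      pixelPitchMm = pitch, vesselAngleDeg = state@vesselAngleDeg,
      provenance = list(state = state, config = cfg, seed = cfg@seed))
}

#' Field rectangle covering a line-scan acquisition
#'
#' Returns the slide rectangle (mm) containing every bead that can
#' intersect the scan line during the acquisition, with a margin, so a
#' [BeadField-class] generated on it yields a stationary streak density.
#'
#' @param state a [PhantomState-class].
#' @param cfg a [LineScanConfig-class].
#' @param marginMm extra margin on all sides (mm).
#' @return numeric(4): `c(xmin, xmax, ymin, ymax)` in mm.
#' @export
lineScanFieldArea <- function(state, cfg = lineScanConfig(),
                              marginMm = 0.05) {
  v <- state@beltVelocityMmS
  a <- state@vesselAngleDeg * pi / 180
  L <- .lineLengthMm(state, cfg)
  duration <- cfg@nLines / cfg@lineRateHz
  dx <- v * cos(a) * duration
  dy <- v * sin(a) * duration
  c(min(0, -dx) - marginMm, L + max(0, -dx) + marginMm,
    min(0, -dy) - marginMm, max(0, -dy) + marginMm)
}

#' Simulate raster-mode frames
#'
#' Standard 2D rendering of the bead field over the square field of view,
#' with the field advanced by v / frameRate between frames (the line-scan
#' instrument interleaves raster frames with space-time acquisitions).
#'
#' @param state a [PhantomState-class].
#' @param field a [BeadField-class].
#' @param cfg a [LineScanConfig-class]; pixels per line and FOV define the
#'   raster geometry.
#' @param nFrames number of frames (default 100).
#' @param frameRateHz frame rate (default 27).
#' @return a [FrameVideo-class].
#' @export
simulateRasterFrames <- function(state, field, cfg = lineScanConfig(),
                                 nFrames = 100, frameRateHz = 27) {
  v <- state@beltVelocityMmS
  a <- state@vesselAngleDeg * pi / 180
  P <- cfg@pixelsPerLine
  pitch <- .pixelPitchMm(state, cfg)
  b <- beadTable(field)
  sigMm <- .beadSigmaUm(b$radius_um, cfg@psfSigmaUm) / 1000
  frames <- array(0, c(nFrames, P, P))
  for (k in seq_len(nFrames)) {
    tk <- (k - 1) / frameRateHz
    sig <- .renderSpots(b$x_mm + v * cos(a) * tk,
                        b$y_mm + v * sin(a) * tk,
                        sigMm, P, P, pitch)
    frames[k, , ] <- .applyNoise(sig, cfg@backgroundLevel, cfg@photonScale,
                                 cfg@photonGain, cfg@readNoiseSd,
                                 cfg@shotNoise, cfg@seed + k)
  }
  new("FrameVideo", frames = frames, fps = frameRateHz,
      umPerPixel = pitch * 1000,
      provenance = list(state = state, config = cfg, seed = cfg@seed))
}

#' Centroid-regression streak slope (geometry oracle)
#'
#' Independent slope measurement for noise-free, single-streak space-time
#' images: on each line with signal, the intensity-weighted centroid gives
#' the streak position; an ordinary least-squares regression of centroid
#' position against time gives the slope. Used to verify the simulator
#' geometry and to cross-check the Radon-style estimator.
#'
#' @param img a [SpaceTimeImage-class].
#' @param minLineEnergyFrac lines whose total intensity (above the image
#'   minimum) is below this fraction of the maximum line energy are
#'   ignored.
#' @return list with `slopeMmS`, `slopePxPerLine` and `nLines` (lines
#'   used).
#' @export
streakCentroidSlope <- function(img, minLineEnergyFrac = 0.2) {
  m <- sweep(intensityMatrix(img), 1, 0)  # copy
  m <- m - min(m)
  e <- rowSums(m)
  use <- which(e > minLineEnergyFrac * max(e))
  if (length(use) < 2L) stop("not enough signal lines for a centroid fit")
  cent <- as.vector(m[use, , drop = FALSE] %*% seq_len(ncol(m))) / e[use]
  fit <- stats::lm.fit(cbind(1, use), cent)
  slopePx <- fit$coefficients[2]  # px per line
  list(slopeMmS = unname(slopePx * img@pixelPitchMm / img@linePeriodS),
       slopePxPerLine = unname(slopePx), nLines = length(use))
}
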