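#' @include render.R
NULL

#' Construct a clinical-SLO video configuration
#'
#' Defaults follow ICGA-mode acquisition for erythrocyte-mediated
#' angiography-style imaging: a 15 degree field of view at 15.4 fps for
#' 5 s. The lateral scale defaults to the true phantom-in-air scaling
#' (focal length x FOV angle across the frame); pass `umPerPixel` to
#' emulate an instrument-assumed (e.g. human-eye) scale instead and so
#' reproduce the scaling-mismatch underestimation mechanism.
#'
#' @param fps frames per second.
#' @param fovDeg field of view in degrees.
#' @param pixels frame size, `c(rows, cols)` or a scalar for square
#'   frames.
#' @param durationS video duration (s).
#' @param umPerPixel lateral scale; `NA` derives it from the phantom
#'   optics at simulation time.
#' @param psfSigmaUm Gaussian PSF sigma (um); clinical-SLO beads are a few
#'   pixels wide.
#' @param backgroundLevel,photonScale,photonGain,readNoiseSd,shotNoise
#'   intensity/noise model; see [SLOVideoConfig-class].
#' @param brightnessSdLog log-SD of the lognormal per-bead fluorescence
#'   amplitude (median 1); 0 renders all beads equally bright.
#' @param seed RNG seed for the noise realization.
#' @return an [SLOVideoConfig-class] object.
#' @export
sloVideoConfig <- function(fps = 15.4, fovDeg = 15, pixels = c(768L, 768L),
                           durationS = 5, umPerPixel = NA_real_,
                           psfSigmaUm = 10, backgroundLevel = 5,
                           photonScale = 80, photonGain = 1,
                           readNoiseSd = 2, shotNoise = TRUE,
                           brightnessSdLog = 1, seed = 1L) {
  if (length(pixels) == 1L) pixels <- c(pixels, pixels)
  new("SLOVideoConfig", fps = fps, fovDeg = fovDeg,
      pixels = as.integer(pixels), durationS = durationS,
      umPerPixel = umPerPixel, psfSigmaUm = psfSigmaUm,
      backgroundLevel = backgroundLevel, photonScale = photonScale,
      photonGain = photonGain, readNoiseSd = readNoiseSd,
      shotNoise = shotNoise, brightnessSdLog = brightnessSdLog,
      seed = as.integer(seed))
}

.sloUmPerPixel <- function(state, cfg) {
  if (!is.na(cfg@umPerPixel)) return(cfg@umPerPixel)
  1000 * scanAngleToLateral(cfg@fovDeg, state@optics, maxAngleDeg = 30) /
    cfg@pixels[2]
}

#' Field rectangle covering an ICGA video acquisition
#'
#' Returns the slide rectangle containing every bead that can enter the
#' field of view during the video: the FOV extended upstream by the total
#' belt displacement. Generating the [BeadField-class] on this rectangle
#' keeps the in-FOV bead density stationary as beads leave downstream and
#' fresh beads enter upstream.
#'
#' @param state a [PhantomState-class].
#' @param cfg an [SLOVideoConfig-class].
#' @param marginMm extra margin on all sides (mm).
#' @return numeric(4): `c(xmin, xmax, ymin, ymax)` in mm.
#' @export
icgaFieldArea <- function(state, cfg = sloVideoConfig(), marginMm = 0.05) {
  umpp <- .sloUmPerPixel(state, cfg)
  wMm <- cfg@pixels[2] * umpp / 1000
  hMm <- cfg@pixels[1] * umpp / 1000
  v <- state@beltVelocityMmS
  a <- state@vesselAngleDeg * pi / 180
  dx <- v * cos(a) * cfg@durationS
  dy <- v * sin(a) * cfg@durationS
  c(min(0, -dx) - marginMm, wMm + max(0, -dx) + marginMm,
    min(0, -dy) - marginMm, hMm + max(0, -dy) + marginMm)
}

#' Simulate an ICGA-mode frame video
#'
#' Renders only the fluorescent beads (the near-IR channel sees the sparse
#' fluorescent subset, as in erythrocyte-mediated angiography). For frame
#' k, bead positions are advanced by v * k / fps along the belt direction;
#' each frame gets Gaussian PSF rendering plus Poisson and Gaussian noise
#' under the configuration seed.
#'
#' @param state a [PhantomState-class].
#' @param field a [BeadField-class]; use [icgaFieldArea()] to generate a
#'   field whose in-FOV density stays stationary over the video.
#' @param cfg an [SLOVideoConfig-class].
#' @return a [FrameVideo-class].
#' @examples
#' st <- phantomState(3.82)
#' cfg <- sloVideoConfig(pixels = 128L, durationS = 1)
#' fld <- generateBeadField(icgaFieldArea(st, cfg), 580, 40, seed = 4)
#' vid <- simulateIcgaVideo(st, fld, cfg)
#' vid
#' @export
simulateIcgaVideo <- function(state, field, cfg = sloVideoConfig()) {
  b <- beadTable(field)
  b <- b[b$is_fluorescent, , drop = FALSE]
  if (nrow(b) == 0L)
    warning("bead field has no fluorescent beads; video is background only")
  umpp <- .sloUmPerPixel(state, cfg)
  pitch <- umpp / 1000
  v <- state@beltVelocityMmS
  a <- state@vesselAngleDeg * pi / 180
  nFrames <- max(2L, round(cfg@durationS * cfg@fps))
  sigMm <- .beadSigmaUm(b$radius_um, cfg@psfSigmaUm) / 1000
  ## per-bead fluorescence amplitude, constant across the video
  amp <- if (cfg@brightnessSdLog > 0 && nrow(b)) {
    withr::with_seed(cfg@seed, stats::rlnorm(nrow(b), 0, cfg@brightnessSdLog))
  } else rep(1, nrow(b))
  frames <- array(0, c(nFrames, cfg@pixels[1], cfg@pixels[2]))
  for (k in seq_len(nFrames)) {
    tk <- (k - 1) / cfg@fps
    sig <- .renderSpots(b$x_mm + v * cos(a) * tk,
                        b$y_mm + v * sin(a) * tk,
                        sigMm, cfg@pixels[1], cfg@pixels[2], pitch,
                        amplitude = amp)
    frames[k, , ] <- .applyNoise(sig, cfg@backgroundLevel, cfg@photonScale,
                                 cfg@photonGain, cfg@readNoiseSd,
                                 cfg@shotNoise, cfg@seed + k)
  }
  new("FrameVideo", frames = frames, fps = cfg@fps, umPerPixel = umpp,
      provenance = list(state = state, config = cfg, seed = cfg@seed))
}

#' Maximum intensity projection
#'
#' Pixelwise maximum over all frames of a video, producing a single
#' composite image in which a moving bead appears as a motion trace.
#' Idempotent and invariant to frame order.
#'
#' @param video a [FrameVideo-class] (or a 3D array `[frame, row, col]`).
#' @return numeric matrix `[row, col]`.
#' @examples
#' st <- phantomState(3.82)
#' cfg <- sloVideoConfig(pixels = 96L, durationS = 1, shotNoise = FALSE,
#'                       readNoiseSd = 0)
#' fld <- generateBeadField(icgaFieldArea(st, cfg), 580, 40, seed = 5)
#' mip <- maxIntensityProjection(simulateIcgaVideo(st, fld, cfg))
#' @export
maxIntensityProjection <- function(video) {
  fr <- if (methods::is(video, "FrameVideo")) videoFrames(video) else video
  if (length(dim(fr)) != 3L) stop("need a 3D array [frame, row, col]")
  n <- dim(fr)[1]
  if (n < 1L) stop("video has no frames")
  out <- fr[1, , ]
  if (n > 1L) for (k in 2:n) out <- pmax(out, fr[k, , ])
  out
}
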