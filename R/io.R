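#' @include calibration.R
NULL

.sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a space-time image as TIFF + JSON sidecar
#'
#' The intensity matrix is stored as a 16-bit grayscale TIFF (normalized
#' to its maximum) and the physical scales (line period, pixel pitch,
#' vessel angle, seed, intensity scale) in a JSON sidecar named
#' `<path>.json`, so the pair round-trips losslessly up to 16-bit
#' quantization.
#'
#' @param img a [SpaceTimeImage-class].
#' @param path output TIFF path.
#' @return `writeSpaceTimeImage()` returns `path` invisibly;
#'   `readSpaceTimeImage()` returns a [SpaceTimeImage-class].
#' @export
writeSpaceTimeImage <- function(img, path) {
  m <- intensityMatrix(img)
  mx <- max(m, 1e-12)
  tiff::writeTIFF(m / mx, path, bits.per.sample = 16)
  meta <- list(type = "space_time_image",
               line_period_s = img@linePeriodS,
               pixel_pitch_mm = img@pixelPitchMm,
               alpha_deg = img@vesselAngleDeg,
               seed = img@provenance$seed,
               max_intensity = mx)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSpaceTimeImage
#' @export
readSpaceTimeImage <- function(path) {
  m <- tiff::readTIFF(path)
  if (!file.exists(.sidecarPath(path)))
    stop("missing JSON sidecar: ", .sidecarPath(path))
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  new("SpaceTimeImage", intensity = m * meta$max_intensity,
      linePeriodS = meta$line_period_s, pixelPitchMm = meta$pixel_pitch_mm,
      vesselAngleDeg = if (is.null(meta$alpha_deg)) NA_real_ else meta$alpha_deg,
      provenance = list(seed = meta$seed, source = path))
}

#' Write / read a frame video as multi-page TIFF + JSON sidecar
#'
#' Frames are stored as 16-bit grayscale TIFF pages (normalized to the
#' video maximum); frame rate, lateral scale and intensity scale go to a
#' JSON sidecar `<path>.json`.
#'
#' @param video a [FrameVideo-class].
#' @param path output TIFF path.
#' @return `writeFrameVideo()` returns `path` invisibly;
#'   `readFrameVideo()` returns a [FrameVideo-class].
#' @export
writeFrameVideo <- function(video, path) {
  fr <- videoFrames(video)
  mx <- max(fr, 1e-12)
  pages <- lapply(seq_len(dim(fr)[1]), function(k) fr[k, , ] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(type = "frame_video", fps = frameRate(video),
               um_per_pixel = pixelScale(video),
               seed = video@provenance$seed, max_intensity = mx)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeFrameVideo
#' @export
readFrameVideo <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!file.exists(.sidecarPath(path)))
    stop("missing JSON sidecar: ", .sidecarPath(path))
  meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  fr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) fr[k, , ] <- pages[[k]] * meta$max_intensity
  new("FrameVideo", frames = fr, fps = meta$fps,
      umPerPixel = meta$um_per_pixel,
      provenance = list(seed = meta$seed, source = path))
}

#' Export / import a bead table as CSV
#'
#' Columns `x_mm`, `y_mm`, `radius_um`, `is_fluorescent`. On import the
#' field area defaults to the bead bounding box and the recorded densities
#' to count / area.
#'
#' @param field a [BeadField-class].
#' @param path CSV path.
#' @param areaMm optional `c(xmin, xmax, ymin, ymax)` when reading.
#' @return `writeBeadFieldCSV()` returns `path` invisibly;
#'   `readBeadFieldCSV()` a [BeadField-class].
#' @export
writeBeadFieldCSV <- function(field, path) {
  utils::write.csv(beadTable(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBeadFieldCSV
#' @export
readBeadFieldCSV <- function(path, areaMm = NULL) {
  b <- utils::read.csv(path)
  b$is_fluorescent <- as.logical(b$is_fluorescent)
  if (is.null(areaMm)) {
    areaMm <- c(min(b$x_mm), max(b$x_mm), min(b$y_mm), max(b$y_mm))
  }
  areaMm <- stats::setNames(as.numeric(areaMm),
                            c("xmin", "xmax", "ymin", "ymax"))
  A <- (areaMm["xmax"] - areaMm["xmin"]) * (areaMm["ymax"] - areaMm["ymin"])
  new("BeadField", beads = b, area = areaMm,
      totalDensity = unname(nrow(b) / A),
      fluorescentDensity = unname(sum(b$is_fluorescent) / A),
      seed = NA_integer_)
}

#' Export streak measurements as CSV
#'
#' One row per streak: ROI origin, orientation, slope, corrected velocity
#' and quality score.
#'
#' @param estimate a [VelocityEstimate-class] (from
#'   [summarizeAcquisition()] / [estimateVelocity()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeStreakCSV <- function(estimate, path) {
  utils::write.csv(measurements(estimate), path, row.names = FALSE)
  invisible(path)
}

#' Export tracks in TrackMate-compatible CSV form
#'
#' Columns `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`, positions in
#' micrometers (FRAME is 0-based as in TrackMate exports).
#'
#' @param result a [TrackingResult-class].
#' @param path CSV path.
#' @param umPerPixel lateral scale used to convert pixel positions to um.
#' @return `path`, invisibly.
#' @export
writeTrackCSV <- function(result, path, umPerPixel) {
  tr <- trackTable(result)
  out <- data.frame(TRACK_ID = tr$track_id, FRAME = tr$frame - 1L,
                    POSITION_X = tr$x * umPerPixel,
                    POSITION_Y = tr$y * umPerPixel)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-acquisition summary as JSON
#'
#' @param x a [VelocityEstimate-class], [TrackingResult-class] or
#'   [SweepResult-class].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeSummaryJSON <- function(x, path) {
  s <- if (methods::is(x, "VelocityEstimate")) {
    list(type = "velocity_estimate", velocity_mm_s = x@velocityMmS,
         alpha_deg = x@alphaDeg, n_streaks = x@nStreaks, sd_mm_s = x@sdMmS,
         relative_sd_percent = x@relativeSdPercent)
  } else if (methods::is(x, "TrackingResult")) {
    list(type = "tracking_result", velocity_mm_s = x@meanVelocityMmS,
         sd_mm_s = x@sdMmS, n_tracks_used = x@nTracksUsed,
         low_confidence = x@lowConfidence)
  } else if (methods::is(x, "SweepResult")) {
    list(type = paste0(x@sweepType, "_sweep"), modality = x@modality,
         base_seed = x@baseSeed, table = x@table,
         fit = if (!is.null(x@fit))
           list(slope = x@fit@slope, intercept = x@fit@intercept,
                r_squared = x@fit@rSquared,
                residual_sd = x@fit@residualSd, n = x@fit@n))
  } else stop("unsupported object")
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Write / read phantom configuration JSON
#'
#' Serializes the phantom configuration objects (motor calibration,
#' optics, state, acquisition configs) to a single JSON document and back.
#'
#' @param config named list whose elements are any of
#'   [MotorCalibration-class], [PulleyGeometry-class],
#'   [OpticsConfig-class], [PhantomState-class], [LineScanConfig-class],
#'   [SLOVideoConfig-class].
#' @param path JSON path.
#' @return `writeConfigJSON()` returns `path` invisibly;
#'   `readConfigJSON()` the reconstructed named list of objects.
#' @export
writeConfigJSON <- function(config, path) {
  ser <- lapply(config, function(obj) {
    sl <- lapply(methods::slotNames(obj), function(s) {
      v <- methods::slot(obj, s)
      if (isVirtualClass(class(v)) || methods::isVirtualClass(class(v)))
        v else v
    })
    names(sl) <- methods::slotNames(obj)
    ## nested S4 (optics inside state)
    sl <- lapply(sl, function(v)
      if (methods::is(v, "OpticsConfig"))
        list(.class = "OpticsConfig", focalLengthMm = v@focalLengthMm,
             refractiveIndex = v@refractiveIndex)
      else v)
    c(list(.class = class(obj)), sl)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeConfigJSON
#' @export
readConfigJSON <- function(path) {
  allowed <- c("MotorCalibration", "PulleyGeometry", "OpticsConfig",
               "PhantomState", "LineScanConfig", "SLOVideoConfig")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    cls <- x$.class
    if (is.null(cls) || !cls %in% allowed)
      stop("unknown or missing class in config JSON")
    x$.class <- NULL
    x <- lapply(x, function(v) {
      if (is.list(v) && identical(v$.class, "OpticsConfig"))
        new("OpticsConfig", focalLengthMm = v$focalLengthMm,
            refractiveIndex = v$refractiveIndex)
      else v
    })
    proto <- methods::new(cls)
    for (s in names(x)) {
      target <- class(methods::slot(proto, s))
      v <- x[[s]]
      if (target == "integer" && !methods::is(v, "OpticsConfig"))
        v <- as.integer(v)
      methods::slot(proto, s) <- v
    }
    methods::validObject(proto)
    proto
  }
  lapply(raw, rebuild)
}
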