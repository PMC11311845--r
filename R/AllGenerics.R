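#' @include AllClasses.R
NULL

#' Accessors for flowPhantom objects
#'
#' Small accessor generics for the package's S4 containers, so user code
#' does not touch slots directly.
#'
#' @param x an object.
#' @return `beadTable()` the bead data.frame; `intensityMatrix()` the
#'   space-time intensity matrix `[line, pixel]`; `videoFrames()` the 3D
#'   frame array `[frame, row, col]`; `frameRate()` frames per second;
#'   `pixelScale()` um per pixel; `meanVelocity()` the mean velocity
#'   estimate in mm/s; `measurements()` the per-streak measurement table;
#'   `trackTable()` the linked-track table; `sweepTable()` the
#'   per-replicate sweep table.
#' @name accessors
#' @examples
#' fld <- generateBeadField(c(0, 1, 0, 1), totalDensity = 50,
#'                          fluorescentDensity = 10, seed = 1)
#' head(beadTable(fld))
NULL

#' @rdname accessors
#' @export
setGeneric("beadTable", function(x) standardGeneric("beadTable"))
#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setGeneric("videoFrames", function(x) standardGeneric("videoFrames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))
#' @rdname accessors
#' @export
setGeneric("meanVelocity", function(x) standardGeneric("meanVelocity"))
#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setGeneric("trackTable", function(x) standardGeneric("trackTable"))
#' @rdname accessors
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname accessors
setMethod("beadTable", "BeadField", function(x) x@beads)
#' @rdname accessors
setMethod("intensityMatrix", "SpaceTimeImage", function(x) x@intensity)
#' @rdname accessors
setMethod("videoFrames", "FrameVideo", function(x) x@frames)
#' @rdname accessors
setMethod("frameRate", "FrameVideo", function(x) x@fps)
#' @rdname accessors
setMethod("pixelScale", "FrameVideo", function(x) x@umPerPixel)
#' @rdname accessors
setMethod("meanVelocity", "VelocityEstimate", function(x) x@velocityMmS)
#' @rdname accessors
setMethod("meanVelocity", "TrackingResult", function(x) x@meanVelocityMmS)
#' @rdname accessors
setMethod("measurements", "VelocityEstimate", function(x) x@measurements)
#' @rdname accessors
setMethod("trackTable", "TrackingResult", function(x) x@tracks)
#' @rdname accessors
setMethod("sweepTable", "SweepResult", function(x) x@table)

#' @describeIn LinearFit-class fitted slope and intercept.
#' @param object a [LinearFit-class] or [AngleModel-class].
#' @param ... ignored.
#' @export
setMethod("coef", "LinearFit", function(object, ...)
  c(slope = object@slope, intercept = object@intercept))

#' @describeIn AngleModel-class cubic coefficients (c3, c2, c1, c0).
#' @param object an [AngleModel-class].
#' @param ... ignored.
#' @export
setMethod("coef", "AngleModel", function(object, ...) object@coefficients)

## show methods -------------------------------------------------------------

setMethod("show", "MotorCalibration", function(object) {
  cat("MotorCalibration: v[mm/s] = sign(V) * (",
      format(object@gain, digits = 5), " * |V| + ",
      format(object@offset, digits = 5), "), dead zone +/-",
      object@deadZoneV, "V\n", sep = "")
})

setMethod("show", "PhantomState", function(object) {
  cat("PhantomState: belt ", object@beltVelocityMmS, " mm/s, vessel angle ",
      object@vesselAngleDeg, " deg, f = ", object@optics@focalLengthMm,
      " mm\n", sep = "")
})

setMethod("show", "BeadField", function(object) {
  a <- object@area
  cat("BeadField: ", nrow(object@beads), " beads (",
      sum(object@beads$is_fluorescent), " fluorescent) on [",
      a["xmin"], ",", a["xmax"], "] x [", a["ymin"], ",", a["ymax"],
      "] mm\n  target densities: ", object@totalDensity, " total, ",
      object@fluorescentDensity, " fluorescent per mm^2 (seed ",
      object@seed, ")\n", sep = "")
})

setMethod("show", "SpaceTimeImage", function(object) {
  d <- dim(object@intensity)
  cat("SpaceTimeImage: ", d[1], " lines x ", d[2], " pixels, ",
      format(1 / object@linePeriodS, digits = 5), " lines/s, ",
      format(object@pixelPitchMm * 1000, digits = 4), " um/px, alpha = ",
      object@vesselAngleDeg, " deg\n", sep = "")
})

setMethod("show", "FrameVideo", function(object) {
  d <- dim(object@frames)
  cat("FrameVideo: ", d[1], " frames of ", d[2], " x ", d[3], " px at ",
      object@fps, " fps, ", format(object@umPerPixel, digits = 4),
      " um/px\n", sep = "")
})

setMethod("show", "StreakPrediction", function(object) {
  cat("StreakPrediction: slope ", format(object@slopeMmS, digits = 5),
      " mm/s, dwell ", format(object@dwellS * 1000, digits = 4),
      " ms, on line [", format(object@entryTimeS, digits = 4), ", ",
      format(object@exitTimeS, digits = 4), "] s\n", sep = "")
})

setMethod("show", "VelocityEstimate", function(object) {
  if (object@nStreaks == 0L) {
    cat("VelocityEstimate: no estimate (0 streaks)\n")
  } else {
    cat("VelocityEstimate: ", format(object@velocityMmS, digits = 5),
        " mm/s (sd ", format(object@sdMmS, digits = 3), ", rel sd ",
        format(object@relativeSdPercent, digits = 3), "%) from ",
        object@nStreaks, " streaks at alpha = ", object@alphaDeg,
        " deg\n", sep = "")
  }
})

setMethod("show", "LinearFit", function(object) {
  cat("LinearFit: y = ", format(object@slope, digits = 6), " x + ",
      format(object@intercept, digits = 6), ", r^2 = ",
      format(object@rSquared, digits = 5), ", residual sd = ",
      format(object@residualSd, digits = 4), " (n = ", object@n, ")\n",
      sep = "")
})

setMethod("show", "AngleModel", function(object) {
  co <- object@coefficients
  cat("AngleModel: y = ", format(co["c3"], digits = 4), " x^3 + ",
      format(co["c2"], digits = 4), " x^2 + ", format(co["c1"], digits = 4),
      " x + ", format(co["c0"], digits = 4),
      if (is.na(object@rSquared)) "" else
        paste0("  (r^2 = ", format(object@rSquared, digits = 5), ")"),
      "\n", sep = "")
})

setMethod("show", "SweepResult", function(object) {
  cat("SweepResult (", object@sweepType, ", ", object@modality, "): ",
      nrow(object@table), " rows, base seed ", object@baseSeed, "\n",
      sep = "")
  if (!is.null(object@fit)) show(object@fit)
})

setMethod("show", "TrackingResult", function(object) {
  cat("TrackingResult: ", length(unique(object@tracks$track_id)),
      " tracks, ", object@nTracksUsed, " used; mean velocity ",
      format(object@meanVelocityMmS, digits = 5), " mm/s (sd ",
      format(object@sdMmS, digits = 3), ")",
      if (object@lowConfidence) "  [low confidence]" else "", "\n",
      sep = "")
})
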