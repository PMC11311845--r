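#' @include linescan-sim.R
NULL

## Column-median background subtraction, clipped at zero. Removes the
## static per-pixel background (slide reflection, fixed pattern) while
## leaving moving-streak energy, since a streak occupies any one spatial
## pixel only briefly.
.subtractColumnMedian <- function(m) {
  pmax(sweep(m, 2, apply(m, 2, stats::median)), 0)
}

#' Preprocess a space-time image
#'
#' Subtracts the per-spatial-pixel (column) median background, clips at
#' zero and contrast-normalizes to `[0, 1]`. Scale metadata are
#' preserved. A constant image yields all zeros with a warning.
#'
#' @param img a [SpaceTimeImage-class].
#' @return a [SpaceTimeImage-class] with intensity in `[0, 1]`.
#' @export
preprocessSpaceTime <- function(img) {
  m <- .subtractColumnMedian(intensityMatrix(img))
  mx <- max(m)
  if (mx == 0) {
    warning("image is constant per column after background subtraction")
  } else {
    m <- m / mx
  }
  methods::initialize(img, intensity = m)
}

## 8-connected components of a logical mask, returned as the foreground
## linear indices plus a component label per index.
.connectedComponents <- function(mask) {
  Tn <- nrow(mask)
  idx <- which(mask)
  if (!length(idx)) return(list(idx = integer(0), comp = integer(0)))
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% Tn) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nb <- idx + off[1] + off[2] * Tn
    ok <- r + off[1] >= 1L & r + off[1] <= Tn &
          nb >= 1L & nb <= length(mask)
    ok[ok] <- mask[nb[ok]]
    if (any(ok))
      edges[[length(edges) + 1L]] <- cbind(pos[idx[ok]], pos[nb[ok]])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  list(idx = idx, comp = igraph::components(g)$membership)
}

## Intensity-weighted principal-axis orientation of a pixel set, measured
## from the time axis toward the spatial axis (so tan(angle) = px/line).
## Seeds the Radon search: for a merged clump of parallel streaks the
## energy-weighted major axis still points along the common direction.
.momentOrientationDeg <- function(t, x, w) {
  sw <- sum(w)
  mt <- sum(w * t) / sw
  mx <- sum(w * x) / sw
  ctt <- sum(w * (t - mt)^2) / sw
  cxx <- sum(w * (x - mx)^2) / sw
  cxt <- sum(w * (t - mt) * (x - mx)) / sw
  0.5 * atan2(2 * cxt, ctt - cxx) * 180 / pi
}

## Radon-style orientation estimate on one set of foreground pixels
## (t in lines, x in pixels, weights w).
##
## For each candidate image angle theta (tan(theta) = pixels per line),
## the pixels are projected onto the line-intercept axis
## b = x - tan(theta) * t and binned; the projection's concentration
## (sum of squared bin masses, corrected for the sheared support width)
## is maximal when the projection direction matches the streak direction.
## Coarse grid then local fine grid, with parabolic peak interpolation.
## Ties are broken toward the smaller |slope|.
.radonOrientation <- function(t, x, w, W, Tn, maxAngleDeg = 88,
                              coarseStepDeg = 2, fineStepDeg = 0.25,
                              centerDeg = NULL, windowDeg = 15) {
  sumw <- sum(w)
  metricAt <- function(angles) {
    vapply(angles, function(th) {
      m <- tan(th * pi / 180)
      b <- x - m * t
      b0 <- floor(b)
      fr <- b - b0
      ## bilinear (fractional) binning to suppress quantization noise
      g <- c(b0, b0 + 1) - min(b0) + 1L
      p <- rowsum(c(w * (1 - fr), w * fr), g, reorder = FALSE)
      nb <- W + abs(m) * Tn
      sum(p^2) - sumw^2 / nb
    }, numeric(1))
  }

  coarse <- if (is.null(centerDeg)) {
    seq(-maxAngleDeg, maxAngleDeg, by = coarseStepDeg)
  } else {
    seq(max(-maxAngleDeg, centerDeg - windowDeg),
        min(maxAngleDeg, centerDeg + windowDeg), by = coarseStepDeg)
  }
  mc <- metricAt(coarse)
  best <- which(mc >= max(mc) - 1e-12)
  b0 <- coarse[best[which.min(abs(coarse[best]))]]

  fine <- seq(max(-maxAngleDeg, b0 - coarseStepDeg),
              min(maxAngleDeg, b0 + coarseStepDeg), by = fineStepDeg)
  mf <- metricAt(fine)
  bestF <- which(mf >= max(mf) - 1e-12)
  j <- bestF[which.min(abs(fine[bestF]))]
  theta <- fine[j]
  ## parabolic interpolation of the peak
  if (j > 1L && j < length(mf)) {
    den <- mf[j - 1L] - 2 * mf[j] + mf[j + 1L]
    if (den < 0) {
      delta <- 0.5 * (mf[j - 1L] - mf[j + 1L]) / den
      if (abs(delta) <= 1) theta <- theta + delta * fineStepDeg
    }
  }
  medc <- stats::median(mc)
  spread <- stats::mad(mc) + 1e-12 * max(abs(mc), 1)
  list(angleDeg = theta, quality = (max(mf) - medc) / spread)
}

#' Detect streak slopes in a space-time image
#'
#' Slides a region of interest over the (preprocessed) space-time image;
#' in each ROI whose foreground energy exceeds the gate, the streak
#' orientation is estimated as the angle maximizing the concentration of
#' the Radon-style projection profile, then converted to a physical slope
#' via `slope = tan(orientation) * pixelPitch / linePeriod`. ROI slopes
#' beyond 3 MAD of the ROI-slope distribution are discarded as outliers.
#'
#' @param img a [SpaceTimeImage-class] (raw; preprocessing is applied
#'   internally).
#' @param roiPixels,roiLines ROI size (spatial pixels x lines).
#' @param overlap fractional ROI overlap in both directions.
#' @param maxAngleDeg orientation search limit (image angle, degrees).
#' @param coarseStepDeg,fineStepDeg orientation grid steps.
#' @param energyGate foreground gate: an ROI is analyzed when its 99th
#'   percentile (background-subtracted) intensity exceeds
#'   `energyGate` x the image's background MAD.
#' @param minQuality minimum orientation-peak quality score to keep a
#'   measurement.
#' @param fgThresh foreground threshold as a fraction of the ROI maximum.
#' @param minStreakPixels minimum foreground pixels per streak component.
#' @param minStreakLines minimum temporal extent (lines) of a streak
#'   component; short fragments carry too little orientation information.
#' @param maxStreaksPerRoi at most this many brightest streak components
#'   are measured per ROI.
#' @return data.frame with one row per measured streak component:
#'   `roi_x`, `roi_t` (0-based ROI origin), `orientation_deg`,
#'   `slope_mm_s`, `quality`. Zero rows when no ROI qualifies.
#' @seealso [slopeToVelocity()], [summarizeAcquisition()],
#'   [estimateVelocity()]
#' @export
detectStreakSlopes <- function(img, roiPixels = 128L, roiLines = 256L,
                               overlap = 0.5, maxAngleDeg = 88,
                               coarseStepDeg = 2, fineStepDeg = 0.25,
                               energyGate = 4, minQuality = 0.5,
                               fgThresh = 0.2, minStreakPixels = 60L,
                               minStreakLines = 48L, maxStreaksPerRoi = 3L) {
  m <- .subtractColumnMedian(intensityMatrix(img))
  Tn <- nrow(m); W <- ncol(m)
  roiLines <- min(roiLines, Tn)
  if (W < roiPixels) roiPixels <- W
  noiseMad <- stats::mad(m[m > 0])
  if (!is.finite(noiseMad)) noiseMad <- 0
  gate <- energyGate * max(noiseMad, 1e-12)

  tStarts <- unique(c(seq(1L, Tn - roiLines + 1L,
                          by = max(1L, round(roiLines * (1 - overlap)))),
                      Tn - roiLines + 1L))
  xStarts <- unique(c(seq(1L, W - roiPixels + 1L,
                          by = max(1L, round(roiPixels * (1 - overlap)))),
                      W - roiPixels + 1L))
  out <- list()
  for (t0 in tStarts) {
    for (x0 in xStarts) {
      roi <- m[t0:(t0 + roiLines - 1L), x0:(x0 + roiPixels - 1L)]
      mx <- max(roi)
      if (mx <= gate || stats::quantile(roi, 0.99, names = FALSE) <= gate)
        next
      roi <- roi / mx
      ## one streak at a time: orientation is measured per connected
      ## foreground component, so fragments of distinct parallel streaks
      ## cannot be sheared into spurious alignment
      cc <- .connectedComponents(roi > fgThresh)
      if (!length(cc$idx)) next
      wAll <- roi[cc$idx]
      tAll <- ((cc$idx - 1L) %% roiLines)
      xAll <- ((cc$idx - 1L) %/% roiLines)
      mass <- rowsum(wAll, cc$comp, reorder = TRUE)
      ord <- order(-mass[, 1])
      picked <- 0L
      for (ci in ord) {
        if (picked >= maxStreaksPerRoi) break
        compId <- as.integer(rownames(mass)[ci])
        sel <- cc$comp == compId
        if (sum(sel) < minStreakPixels) next
        tSel <- tAll[sel]
        if (diff(range(tSel)) < minStreakLines) next
        ctr <- .momentOrientationDeg(tSel, xAll[sel], wAll[sel])
        r <- .radonOrientation(tSel - roiLines / 2, xAll[sel], wAll[sel],
                               W = roiPixels, Tn = roiLines,
                               maxAngleDeg = maxAngleDeg,
                               coarseStepDeg = coarseStepDeg,
                               fineStepDeg = fineStepDeg,
                               centerDeg = ctr)
        if (is.null(r) || r$quality < minQuality) next
        picked <- picked + 1L
        slope <- tan(r$angleDeg * pi / 180) * img@pixelPitchMm /
          img@linePeriodS
        out[[length(out) + 1L]] <- data.frame(
          roi_x = x0 - 1L, roi_t = t0 - 1L,
          orientation_deg = r$angleDeg, slope_mm_s = slope,
          quality = r$quality)
      }
    }
  }
  if (!length(out))
    return(data.frame(roi_x = integer(0), roi_t = integer(0),
                      orientation_deg = numeric(0),
                      slope_mm_s = numeric(0), quality = numeric(0)))
  res <- do.call(rbind, out)
  ## discard slope outliers beyond 3 MAD
  if (nrow(res) >= 4L) {
    med <- stats::median(res$slope_mm_s)
    s <- stats::mad(res$slope_mm_s)
    if (s > 0) res <- res[abs(res$slope_mm_s - med) <= 3 * s, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' Vessel-angle (secant) velocity correction
#'
#' The streak slope on a space-time image measures only the along-line
#' velocity component Dx/Dt = v cos(alpha); the true speed is recovered
#' as v = (Dx/Dt) * sec(alpha). The correction diverges as alpha
#' approaches 90 degrees, so angles at or above `alphaMaxDeg` are
#' rejected.
#'
#' @param slopeMmS measured streak slope(s), mm/s.
#' @param alphaDeg vessel angle in degrees; must be below `alphaMaxDeg`.
#' @param alphaMaxDeg rejection threshold (default 89).
#' @return corrected velocity in mm/s, sign preserved.
#' @examples
#' slopeToVelocity(1.91, 60)  # 3.82: sec(60 deg) = 2
#' @export
slopeToVelocity <- function(slopeMmS, alphaDeg, alphaMaxDeg = 89) {
  if (any(abs(alphaDeg) >= alphaMaxDeg))
    stop("vessel angle too steep for the secant correction (alpha >= ",
         alphaMaxDeg, " deg)")
  slopeMmS / cos(alphaDeg * pi / 180)
}

#' Summarize streak measurements into a velocity estimate
#'
#' Applies the sec(alpha) correction to each per-streak slope and reports
#' the mean, SD and relative SD of the corrected velocities. An empty
#' measurement table yields the explicit no-estimate result
#' (`nStreaks = 0`).
#'
#' @param meas data.frame from [detectStreakSlopes()] (needs a
#'   `slope_mm_s` column).
#' @param alphaDeg vessel angle used for the correction (degrees).
#' @return a [VelocityEstimate-class].
#' @export
summarizeAcquisition <- function(meas, alphaDeg) {
  if (!nrow(meas)) {
    return(new("VelocityEstimate", velocityMmS = NA_real_,
               alphaDeg = alphaDeg, nStreaks = 0L, sdMmS = NA_real_,
               relativeSdPercent = NA_real_, measurements = meas))
  }
  v <- slopeToVelocity(meas$slope_mm_s, alphaDeg)
  meas$v_mm_s <- v
  mu <- mean(v)
  s <- if (length(v) > 1L) stats::sd(v) else 0
  new("VelocityEstimate", velocityMmS = mu, alphaDeg = alphaDeg,
      nStreaks = nrow(meas), sdMmS = s,
      relativeSdPercent = if (mu != 0) 100 * s / abs(mu) else NA_real_,
      measurements = meas)
}

#' End-to-end streak velocimetry
#'
#' Convenience pipeline: [detectStreakSlopes()] then
#' [summarizeAcquisition()] at the image's recorded vessel angle (or an
#' explicit one, e.g. for externally loaded data).
#'
#' @param img a [SpaceTimeImage-class].
#' @param alphaDeg vessel angle (degrees); defaults to the angle recorded
#'   in the image metadata.
#' @param ... passed to [detectStreakSlopes()].
#' @return a [VelocityEstimate-class].
#' @examples
#' st <- phantomState(3.82, 30)
#' cfg <- lineScanConfig(nLines = 1024L, seed = 11L)
#' fld <- generateBeadField(lineScanFieldArea(st, cfg), 580, 40, seed = 11)
#' est <- estimateVelocity(simulateSpaceTime(st, fld, cfg))
#' est
#' @export
estimateVelocity <- function(img, alphaDeg = img@vesselAngleDeg, ...) {
  if (is.na(alphaDeg))
    stop("vessel angle unknown; pass 'alphaDeg' explicitly")
  summarizeAcquisition(detectStreakSlopes(img, ...), alphaDeg)
}
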