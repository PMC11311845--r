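#' @include phantom-core.R
NULL

## Shared rendering core: additive Gaussian bead profiles on a pixel grid.
##
## A bead is modeled as a uniform disk convolved with the Gaussian PSF and
## approximated by a Gaussian with moment-matched width
## sigma_eff^2 = psf_sigma^2 + (radius/2)^2 (the disk contributes a
## per-axis variance of r^2/4), peak amplitude 1 per bead.

.beadSigmaUm <- function(radiusUm, psfSigmaUm) {
  sqrt(psfSigmaUm^2 + (radiusUm / 2)^2)
}

## Render beads at positions (xMm, yMm) onto a [nrow x ncol] pixel grid
## whose pixel centers are at xlim[1] + (j - 0.5) * pitch (columns) and
## ylim[1] + (i - 0.5) * pitch (rows). Returns the noise-free signal.
.renderSpots <- function(xMm, yMm, sigmaMm, nrowPx, ncolPx, pitchMm,
                         xOriginMm = 0, yOriginMm = 0, amplitude = 1) {
  sig <- matrix(0, nrowPx, ncolPx)
  if (!length(xMm)) return(sig)
  amplitude <- rep_len(amplitude, length(xMm))
  xc <- xOriginMm + (seq_len(ncolPx) - 0.5) * pitchMm
  yc <- yOriginMm + (seq_len(nrowPx) - 0.5) * pitchMm
  for (k in seq_along(xMm)) {
    s <- sigmaMm[if (length(sigmaMm) > 1L) k else 1L]
    w <- 4 * s
    c0 <- max(1L, ceiling((xMm[k] - w - xOriginMm) / pitchMm))
    c1 <- min(ncolPx, floor((xMm[k] + w - xOriginMm) / pitchMm) + 1L)
    r0 <- max(1L, ceiling((yMm[k] - w - yOriginMm) / pitchMm))
    r1 <- min(nrowPx, floor((yMm[k] + w - yOriginMm) / pitchMm) + 1L)
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-(xc[c0:c1] - xMm[k])^2 / (2 * s^2))
    gy <- exp(-(yc[r0:r1] - yMm[k])^2 / (2 * s^2))
    sig[r0:r1, c0:c1] <- sig[r0:r1, c0:c1] + amplitude[k] * (gy %o% gx)
  }
  sig
}

## Render beads as uniform disks of their physical radius convolved with
## a Gaussian PSF (soft-edged disk: amplitude pnorm((r - d) / sigma)).
## Used for microscopy-style slide images where the bead diameter exceeds
## the PSF width; the Gaussian renderer above is the right model when the
## PSF dominates.
.renderDisks <- function(xMm, yMm, radiusMm, psfSigmaMm, nrowPx, ncolPx,
                         pitchMm, xOriginMm = 0, yOriginMm = 0) {
  sig <- matrix(0, nrowPx, ncolPx)
  if (!length(xMm)) return(sig)
  radiusMm <- rep_len(radiusMm, length(xMm))
  xc <- xOriginMm + (seq_len(ncolPx) - 0.5) * pitchMm
  yc <- yOriginMm + (seq_len(nrowPx) - 0.5) * pitchMm
  for (k in seq_along(xMm)) {
    w <- radiusMm[k] + 4 * psfSigmaMm
    c0 <- max(1L, ceiling((xMm[k] - w - xOriginMm) / pitchMm))
    c1 <- min(ncolPx, floor((xMm[k] + w - xOriginMm) / pitchMm) + 1L)
    r0 <- max(1L, ceiling((yMm[k] - w - yOriginMm) / pitchMm))
    r1 <- min(nrowPx, floor((yMm[k] + w - yOriginMm) / pitchMm) + 1L)
    if (c0 > c1 || r0 > r1) next
    dx2 <- (xc[c0:c1] - xMm[k])^2
    dy2 <- (yc[r0:r1] - yMm[k])^2
    d <- sqrt(outer(dy2, dx2, "+"))
    sig[r0:r1, c0:c1] <- sig[r0:r1, c0:c1] +
      stats::pnorm((radiusMm[k] - d) / psfSigmaMm)
  }
  sig
}

## Photon + read-noise model. Expected photon count per pixel is
## background + photonScale * signal; the output is
## photonGain * Poisson(expected) + N(0, readNoiseSd), clipped at zero.
## With shotNoise = FALSE and readNoiseSd = 0 the output is exactly
## photonGain * expected.
.applyNoise <- function(signal, backgroundLevel, photonScale, photonGain,
                        readNoiseSd, shotNoise, seed) {
  expected <- backgroundLevel + photonScale * signal
  if (!shotNoise && readNoiseSd == 0)
    return(photonGain * expected)
  out <- withr::with_seed(as.integer(seed), {
    x <- if (shotNoise) {
      matrix(stats::rpois(length(expected), expected), nrow(expected))
    } else expected
    x <- photonGain * x
    if (readNoiseSd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = readNoiseSd), nrow(x))
    x
  })
  pmax(out, 0)
}

#' Render a microscopy-style image of a bead-field region
#'
#' Renders an idealized microscope image of a rectangular region of a
#' [BeadField-class]: beads appear as bright soft-edged disks (their
#' physical radius convolved with the microscope PSF) on a dark
#' background. In `"brightfield"` mode all beads are rendered (total
#' density); in `"fluorescence"` mode only fluorescent beads appear, as
#' in the two-channel microscopy used to verify slide densities. Used
#' together with [detectSpots()] for image-based density counting.
#'
#' @param field a [BeadField-class].
#' @param xlimMm,ylimMm region limits in mm, `c(min, max)`.
#' @param umPerPixel pixel pitch of the rendered image (um).
#' @param psfSigmaUm imaging PSF sigma (um); a high-NA objective resolves
#'   the bead disk, so the default is well below the bead radius.
#' @param mode `"brightfield"` (all beads) or `"fluorescence"`
#'   (fluorescent beads only).
#' @param backgroundLevel,photonScale,photonGain,readNoiseSd,shotNoise
#'   intensity/noise model as in [LineScanConfig-class]; the default is
#'   noise-free.
#' @param seed RNG seed for the noise realization.
#' @return numeric matrix `[row, col]`; rows map to y, columns to x.
#' @examples
#' fld <- generateBeadField(c(0, 0.5, 0, 0.5), 580, 40, seed = 2)
#' img <- renderSlideImage(fld, c(0, 0.5), c(0, 0.5))
#' dim(img)
#' @export
renderSlideImage <- function(field, xlimMm, ylimMm, umPerPixel = 1,
                             psfSigmaUm = 1,
                             mode = c("brightfield", "fluorescence"),
                             backgroundLevel = 0, photonScale = 100,
                             photonGain = 1, readNoiseSd = 0,
                             shotNoise = FALSE, seed = 1) {
  mode <- match.arg(mode)
  b <- beadTable(field)
  if (mode == "fluorescence") b <- b[b$is_fluorescent, , drop = FALSE]
  pitch <- umPerPixel / 1000
  ncolPx <- max(1L, round((xlimMm[2] - xlimMm[1]) / pitch))
  nrowPx <- max(1L, round((ylimMm[2] - ylimMm[1]) / pitch))
  keep <- b$x_mm > xlimMm[1] - 0.05 & b$x_mm < xlimMm[2] + 0.05 &
          b$y_mm > ylimMm[1] - 0.05 & b$y_mm < ylimMm[2] + 0.05
  b <- b[keep, , drop = FALSE]
  sig <- .renderDisks(b$x_mm, b$y_mm, b$radius_um / 1000, psfSigmaUm / 1000,
                      nrowPx, ncolPx, pitch,
                      xOriginMm = xlimMm[1], yOriginMm = ylimMm[1])
  .applyNoise(sig, backgroundLevel, photonScale, photonGain, readNoiseSd,
              shotNoise, seed)
}
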