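#' @include lap.R
NULL

## Separable Gaussian smoothing with edge replication.
.gaussSmooth <- function(m, sigma) {
  kr <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-kr:kr, sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(mm) {
    n <- nrow(mm)
    padded <- rbind(mm[rep(1L, kr), , drop = FALSE], mm,
                    mm[rep(n, kr), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    out[(kr + 1L):(kr + n), , drop = FALSE]
  }
  t(smooth1(t(smooth1(m))))
}

## Scale-normalized Laplacian-of-Gaussian blob response (positive for
## bright blobs of radius ~ sigma * sqrt(2)), edge-replicated.
.logResponse <- function(m, sigma) {
  s <- .gaussSmooth(m, sigma)
  n <- nrow(s); p <- ncol(s)
  up <- s[c(1L, seq_len(n - 1L)), ]
  dn <- s[c(seq_len(n - 1L) + 1L, n), ]
  lf <- s[, c(1L, seq_len(p - 1L))]
  rt <- s[, c(seq_len(p - 1L) + 1L, p)]
  -sigma^2 * (up + dn + lf + rt - 4 * s)
}

#' Detect bead spots in a single frame
#'
#' Scale-matched blob detection: the scale-normalized
#' Laplacian-of-Gaussian response at `sigma = diameter / (2 sqrt(2))` is
#' computed, its local maxima above a threshold are taken as candidate
#' spots, non-maximum suppression at 0.75 x diameter removes duplicate
#' responses, and positions are refined to subpixel accuracy by the
#' response-weighted centroid in a 5 x 5 window.
#'
#' @param frame numeric matrix `[row, col]`.
#' @param expectedDiameterPx expected bead image diameter in pixels
#'   (>= 1).
#' @param threshold detection threshold on the blob response; `NULL`
#'   (default) uses a robust automatic threshold,
#'   median(R) + 10 * mad(R).
#' @param borderMarginPx candidates closer than this to the frame border
#'   are discarded (default: half the diameter, rounded up).
#' @param maxSpots keep at most this many spots, strongest responses
#'   first (`Inf` = keep all). Restricting detection to the brightest
#'   spots emulates tracking only the well-resolved bead subset.
#' @return data.frame with columns `x` (column), `y` (row), both subpixel,
#'   and `response`; zero rows when nothing is detected.
#' @examples
#' img <- matrix(0, 64, 64); img[30:32, 40:42] <- 1
#' detectSpots(img, expectedDiameterPx = 3)
#' @export
detectSpots <- function(frame, expectedDiameterPx, threshold = NULL,
                        borderMarginPx = ceiling(expectedDiameterPx / 2),
                        maxSpots = Inf) {
  stopifnot(expectedDiameterPx >= 1)
  sigma <- expectedDiameterPx / (2 * sqrt(2))
  R <- .logResponse(frame, sigma)
  if (is.null(threshold)) {
    threshold <- stats::median(R) + 10 * stats::mad(R)
    if (threshold <= 0) threshold <- 1e-9
  }
  n <- nrow(R); p <- ncol(R)
  ## strict local maxima over the 8-neighborhood
  sh <- function(dr, dc) {
    ri <- pmin(pmax(seq_len(n) + dr, 1L), n)
    ci <- pmin(pmax(seq_len(p) + dc, 1L), p)
    R[ri, ci]
  }
  isMax <- R > threshold
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
                 c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))) {
    isMax <- isMax & (R >= sh(d[1], d[2]))
    if (!any(isMax)) break
  }
  idx <- which(isMax)
  if (!length(idx))
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  ry <- ((idx - 1L) %% n) + 1L
  rx <- ((idx - 1L) %/% n) + 1L
  keep <- ry > borderMarginPx & ry <= n - borderMarginPx &
          rx > borderMarginPx & rx <= p - borderMarginPx
  ry <- ry[keep]; rx <- rx[keep]
  if (!length(ry))
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  resp <- R[cbind(ry, rx)]

  ## non-maximum suppression at 0.75 * diameter, strongest first
  ord <- order(resp, decreasing = TRUE)
  r2 <- (0.75 * expectedDiameterPx)^2
  sel <- logical(length(ord))
  for (i in ord) {
    if (any(sel & ((ry - ry[i])^2 + (rx - rx[i])^2) < r2 &
            seq_along(sel) != i)) next
    sel[i] <- TRUE
  }
  ry <- ry[sel]; rx <- rx[sel]; resp <- resp[sel]

  ## subpixel refinement: response-weighted centroid in a 5x5 window
  xs <- numeric(length(ry)); ys <- numeric(length(ry))
  Rpos <- pmax(R, 0)
  for (i in seq_along(ry)) {
    rr <- max(1L, ry[i] - 2L):min(n, ry[i] + 2L)
    cc <- max(1L, rx[i] - 2L):min(p, rx[i] + 2L)
    w <- Rpos[rr, cc, drop = FALSE]
    tw <- sum(w)
    if (tw > 0) {
      ys[i] <- sum(rowSums(w) * rr) / tw
      xs[i] <- sum(colSums(w) * cc) / tw
    } else {
      ys[i] <- ry[i]; xs[i] <- rx[i]
    }
  }
  out <- data.frame(x = xs, y = ys, response = resp)
  out <- out[order(-out$response), , drop = FALSE]
  if (is.finite(maxSpots) && nrow(out) > maxSpots)
    out <- out[seq_len(maxSpots), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Link per-frame spots into tracks
#'
#' Frame-to-frame linking as a linear assignment problem: for each
#' consecutive frame pair, the globally minimal total squared displacement
#' assignment is found subject to a hard per-link distance gate; unmatched
#' spots close or open tracks (death/birth cost = gate distance squared).
#' Optionally, one-frame gaps can be closed in a second assignment pass
#' over track ends and starts. Deterministic.
#'
#' @param spots data.frame with columns `frame`, `x`, `y` (one row per
#'   detected spot); frames need not be contiguous.
#' @param maxLinkDistPx hard per-link distance gate in pixels.
#' @param maxGap maximum number of missing frames to bridge (0 = off,
#'   1 supported).
#' @return data.frame with columns `track_id`, `frame`, `x`, `y`, sorted
#'   by track then frame; each track has strictly increasing frames.
#' @seealso [computeVelocities()], [trackVideo()]
#' @export
linkTracks <- function(spots, maxLinkDistPx, maxGap = 0) {
  stopifnot(all(c("frame", "x", "y") %in% names(spots)))
  if (!nrow(spots))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0)))
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  byFrame <- split(seq_len(nrow(spots)), spots$frame)

  trackOf <- integer(nrow(spots))
  nextId <- 1L
  first <- byFrame[[as.character(frames[1])]]
  trackOf[first] <- seq_along(first)
  nextId <- length(first) + 1L

  for (fi in seq_len(length(frames) - 1L)) {
    i1 <- byFrame[[as.character(frames[fi])]]
    i2 <- byFrame[[as.character(frames[fi + 1L])]]
    contiguous <- frames[fi + 1L] - frames[fi] == 1L
    if (contiguous && length(i1)) {
      link <- .linkFramePair(cbind(spots$x[i1], spots$y[i1]),
                             cbind(spots$x[i2], spots$y[i2]),
                             maxLinkDistPx)
      for (k in seq_along(i1)) {
        if (!is.na(link[k])) trackOf[i2[link[k]]] <- trackOf[i1[k]]
      }
    }
    newb <- i2[trackOf[i2] == 0L]
    if (length(newb)) {
      trackOf[newb] <- nextId + seq_along(newb) - 1L
      nextId <- nextId + length(newb)
    }
  }

  tracks <- data.frame(track_id = trackOf, frame = spots$frame,
                       x = spots$x, y = spots$y)
  if (maxGap >= 1) tracks <- .closeGaps(tracks, maxLinkDistPx, maxGap)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  tracks
}

## Bridge tracks separated by up to maxGap missing frames with a second
## assignment pass over (track end) x (track start) pairs.
.closeGaps <- function(tracks, maxLinkDistPx, maxGap) {
  repeat {
    ids <- unique(tracks$track_id)
    ends <- do.call(rbind, lapply(ids, function(id) {
      tr <- tracks[tracks$track_id == id, ]
      data.frame(id = id,
                 f0 = tr$frame[1], x0 = tr$x[1], y0 = tr$y[1],
                 f1 = tr$frame[nrow(tr)], x1 = tr$x[nrow(tr)],
                 y1 = tr$y[nrow(tr)])
    }))
    cand <- which(outer(ends$f1, ends$f0, function(a, b) {
      g <- b - a; g >= 2 & g <= maxGap + 1
    }), arr.ind = TRUE)
    if (!nrow(cand)) return(tracks)
    gaps <- ends$f0[cand[, 2]] - ends$f1[cand[, 1]]
    d <- sqrt((ends$x1[cand[, 1]] - ends$x0[cand[, 2]])^2 +
              (ends$y1[cand[, 1]] - ends$y0[cand[, 2]])^2)
    ok <- d <= maxLinkDistPx * gaps
    cand <- cand[ok, , drop = FALSE]; d <- d[ok]
    if (!nrow(cand)) return(tracks)
    ## greedy by distance; each end/start used once
    ord <- order(d)
    usedE <- usedS <- logical(nrow(ends))
    merged <- FALSE
    for (k in ord) {
      e <- cand[k, 1]; s <- cand[k, 2]
      if (usedE[e] || usedS[s] || ends$id[e] == ends$id[s]) next
      tracks$track_id[tracks$track_id == ends$id[s]] <- ends$id[e]
      usedE[e] <- TRUE; usedS[s] <- TRUE
      merged <- TRUE
    }
    if (!merged) return(tracks)
  }
}

#' Per-track and per-video velocity statistics
#'
#' Per-track speed is the mean frame-to-frame displacement (displacement
#' divided by frame gap, averaged over steps) scaled by the pixel size and
#' frame rate; the net speed (straight-line displacement over track
#' duration) is also reported. The video mean velocity averages tracks
#' with at least `minTrackLen` spots; when fewer than `minTracks` tracks
#' qualify the result is flagged low-confidence (with a warning), echoing
#' the >= 20-trace averaging rule of EMA practice.
#'
#' @param tracks data.frame from [linkTracks()].
#' @param umPerPixel lateral scale (um per pixel).
#' @param fps frame rate (frames per second).
#' @param minTrackLen minimum spots per qualifying track (default 5).
#' @param minTracks minimum qualifying tracks for a confident video mean
#'   (default 20).
#' @param maxStepNetRatio straightness gate: tracks whose mean step speed
#'   exceeds this multiple of their net (straight-line) speed are dropped
#'   from the video mean. Under linear flow a clean trace has ratio ~1;
#'   a large ratio marks a zigzag trace that alternated between
#'   neighboring beads. `Inf` disables the gate.
#' @param spots optional data.frame of all detected spots, stored in the
#'   result.
#' @return a [TrackingResult-class].
#' @examples
#' tr <- data.frame(track_id = 1L, frame = 1:6,
#'                  x = seq(0, 5) * 2, y = 0)
#' computeVelocities(tr, umPerPixel = 5, fps = 15.4, minTracks = 1)
#' @export
computeVelocities <- function(tracks, umPerPixel, fps, minTrackLen = 5,
                              minTracks = 20, maxStepNetRatio = 1.2,
                              spots = NULL) {
  ids <- unique(tracks$track_id)
  stats_ <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2L) {
      return(data.frame(track_id = id, n_spots = n,
                        mean_step_mm_s = NA_real_, net_mm_s = NA_real_))
    }
    df <- diff(tr$frame)
    step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2) / df
    net <- sqrt((tr$x[n] - tr$x[1])^2 + (tr$y[n] - tr$y[1])^2) /
      (tr$frame[n] - tr$frame[1])
    data.frame(track_id = id, n_spots = n,
               mean_step_mm_s = mean(step) * umPerPixel * fps / 1000,
               net_mm_s = net * umPerPixel * fps / 1000)
  }))
  if (is.null(stats_))
    stats_ <- data.frame(track_id = integer(0), n_spots = integer(0),
                         mean_step_mm_s = numeric(0), net_mm_s = numeric(0))
  qual <- stats_[!is.na(stats_$mean_step_mm_s) &
                 stats_$n_spots >= minTrackLen, , drop = FALSE]
  if (is.finite(maxStepNetRatio) && nrow(qual)) {
    ok <- qual$mean_step_mm_s == 0 |
      (qual$net_mm_s > 0 &
       qual$mean_step_mm_s <= maxStepNetRatio * qual$net_mm_s)
    qual <- qual[ok, , drop = FALSE]
  }
  nUsed <- nrow(qual)
  low <- nUsed < minTracks
  if (low)
    warning("only ", nUsed, " qualifying tracks (< ", minTracks,
            "); video mean is low-confidence")
  new("TrackingResult",
      spots = if (is.null(spots)) data.frame() else spots,
      tracks = tracks, trackStats = stats_,
      meanVelocityMmS = if (nUsed) mean(qual$mean_step_mm_s) else NA_real_,
      sdMmS = if (nUsed > 1L) stats::sd(qual$mean_step_mm_s) else NA_real_,
      nTracksUsed = as.integer(nUsed), lowConfidence = low)
}

#' Detect, link and summarize a frame video
#'
#' Full tracking pipeline on a [FrameVideo-class]: spot detection in every
#' frame, LAP linking, and per-video velocity statistics.
#'
#' @param video a [FrameVideo-class].
#' @param expectedDiameterPx expected bead image diameter (pixels);
#'   default derives from the video's provenance PSF when available, else
#'   4 px.
#' @param threshold detection threshold (NULL = automatic per frame).
#' @param maxLinkDistPx linking gate; default is twice the per-frame
#'   displacement at a 7 mm/s velocity ceiling (the top of the
#'   physiological calibration range).
#' @param velocityCeilingMmS velocity ceiling used for the default gate.
#' @param maxSpotsPerFrame track at most the N brightest spots per frame
#'   (`Inf` = all); frame-to-frame assignment is only unambiguous while
#'   the spot spacing stays above the per-frame displacement, so dense
#'   videos are tracked through their bright, well-resolved subset.
#' @param ... passed to [computeVelocities()].
#' @return a [TrackingResult-class].
#' @export
trackVideo <- function(video, expectedDiameterPx = NULL, threshold = NULL,
                       maxLinkDistPx = NULL, velocityCeilingMmS = 7,
                       maxSpotsPerFrame = Inf, ...) {
  fr <- videoFrames(video)
  if (is.null(expectedDiameterPx)) {
    psf <- tryCatch(video@provenance$config@psfSigmaUm, error = function(e) NULL)
    expectedDiameterPx <- if (!is.null(psf) && length(psf))
      max(2, 2 * sqrt(2) * psf / pixelScale(video)) else 4
  }
  if (is.null(maxLinkDistPx))
    maxLinkDistPx <- 2 * velocityCeilingMmS * 1000 /
      (frameRate(video) * pixelScale(video))
  spots <- do.call(rbind, lapply(seq_len(dim(fr)[1]), function(k) {
    s <- detectSpots(fr[k, , ], expectedDiameterPx, threshold,
                     maxSpots = maxSpotsPerFrame)
    if (nrow(s)) cbind(frame = k, s) else NULL
  }))
  if (is.null(spots))
    spots <- data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
                        response = numeric(0))
  tracks <- linkTracks(spots, maxLinkDistPx)
  computeVelocities(tracks, pixelScale(video), frameRate(video),
                    spots = spots, ...)
}
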