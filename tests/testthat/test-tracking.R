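# render a frame with Gaussian spots at given subpixel positions
spotFrame <- function(x, y, n = 64, sigma = 1.6, amp = 100) {
  m <- matrix(0, n, n)
  for (k in seq_along(x)) {
    gx <- exp(-((seq_len(n) - x[k])^2) / (2 * sigma^2))
    gy <- exp(-((seq_len(n) - y[k])^2) / (2 * sigma^2))
    m <- m + amp * (gy %o% gx)
  }
  m
}

test_that("spot detection localizes a rendered bead to subpixel accuracy", {
  fr <- spotFrame(23.37, 41.81)
  sp <- detectSpots(fr, expectedDiameterPx = 4)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x - 23.37), 0.5)
  expect_lt(abs(sp$y - 41.81), 0.5)
})

test_that("blank frames and separated pairs behave as expected", {
  expect_identical(nrow(detectSpots(matrix(0, 32, 32), 4)), 0L)
  fr <- spotFrame(c(20, 40), c(20, 44))
  sp <- detectSpots(fr, expectedDiameterPx = 4)
  expect_identical(nrow(sp), 2L)
  expect_identical(nrow(detectSpots(fr, 4, maxSpots = 1)), 1L)
})

test_that("assignment solver matches brute force on crossing paths", {
  xy1 <- cbind(c(10, 20), c(10, 20))
  xy2 <- cbind(c(19.5, 10.5), c(19.5, 10.5))  # beads swapped corners
  expect_equal(packageLinkCost(xy1, xy2, 30),
               bruteForceLinkCost(xy1, xy2, 30))
})

test_that("LAP linking equals exhaustive enumeration on random fixtures", {
  set.seed(42)
  for (i in 1:40) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    if (n1 == 0 && n2 == 0) next
    xy1 <- cbind(stats::runif(n1, 0, 50), stats::runif(n1, 0, 50))
    xy2 <- cbind(stats::runif(n2, 0, 50), stats::runif(n2, 0, 50))
    gate <- stats::runif(1, 5, 40)
    expect_equal(packageLinkCost(xy1, xy2, gate),
                 bruteForceLinkCost(xy1, xy2, gate), tolerance = 1e-9)
  }
})

test_that("steady motion yields one track spanning all frames", {
  spots <- data.frame(frame = 1:10, x = 5 + 2 * (0:9), y = 3)
  tr <- linkTracks(spots, maxLinkDistPx = 5)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 10L)
  expect_true(all(diff(tr$frame) == 1))
})

test_that("displacement beyond the gate breaks the track", {
  spots <- data.frame(frame = 1:4, x = c(5, 7, 30, 32), y = 0)
  tr <- linkTracks(spots, maxLinkDistPx = 5)
  expect_identical(length(unique(tr$track_id)), 2L)
})

test_that("one-frame gap closing bridges a missed detection", {
  spots <- data.frame(frame = c(1, 2, 4, 5), x = c(0, 2, 6, 8), y = 0)
  broken <- linkTracks(spots, maxLinkDistPx = 3, maxGap = 0)
  expect_identical(length(unique(broken$track_id)), 2L)
  closed <- linkTracks(spots, maxLinkDistPx = 3, maxGap = 1)
  expect_identical(length(unique(closed$track_id)), 1L)
})

test_that("track speeds follow displacement x scale x rate arithmetic", {
  # 10 um per frame at 15.4 fps -> 0.154 mm/s (5 um/px, 2 px steps)
  tr <- data.frame(track_id = 1L, frame = 1:6, x = 2 * (0:5), y = 0)
  res <- computeVelocities(tr, umPerPixel = 5, fps = 15.4, minTracks = 1)
  expect_equal(meanVelocity(res), 10 * 15.4 / 1000)
  expect_equal(meanVelocity(res), 0.154)

  still <- data.frame(track_id = 1L, frame = 1:6, x = 1, y = 1)
  res0 <- computeVelocities(still, umPerPixel = 5, fps = 15.4, minTracks = 1)
  expect_identical(meanVelocity(res0), 0)

  expect_warning(
    low <- computeVelocities(tr, umPerPixel = 5, fps = 15.4, minTracks = 20),
    "low-confidence")
  expect_true(low@lowConfidence)
})

test_that("full tracking pipeline recovers the belt velocity", {
  st <- phantomState(3.82)
  cfg <- sloVideoConfig(pixels = 384L, fovDeg = 7.5, durationS = 2.5,
                        seed = 6L)
  fld <- generateBeadField(icgaFieldArea(st, cfg), 580, 40, seed = 6)
  vid <- simulateIcgaVideo(st, fld, cfg)
  tr <- suppressWarnings(trackVideo(vid, maxSpotsPerFrame = 12))
  expect_gte(tr@nTracksUsed, 5)
  expect_lt(abs(meanVelocity(tr) - 3.82) / 3.82, 0.05)

  # invariance to global intensity scaling
  vid2 <- methods::initialize(vid, frames = videoFrames(vid) * 3)
  tr2 <- suppressWarnings(trackVideo(vid2, maxSpotsPerFrame = 12))
  expect_equal(meanVelocity(tr2), meanVelocity(tr), tolerance = 0.02)
})

test_that("velocity statistics are invariant to field translation", {
  spots <- data.frame(frame = rep(1:6, each = 2),
                      x = c(t(outer(3 * (0:5), c(5, 25), "+"))),
                      y = rep(c(10, 30), 6))
  tr1 <- computeVelocities(linkTracks(spots, 10), 5, 15.4, minTracks = 1)
  shifted <- transform(spots, x = x + 7.3, y = y - 2.1)
  tr2 <- computeVelocities(linkTracks(shifted, 10), 5, 15.4, minTracks = 1)
  expect_equal(meanVelocity(tr1), meanVelocity(tr2))
})
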