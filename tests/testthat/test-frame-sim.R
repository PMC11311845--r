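cleanSloConfig <- function(...) {
  sloVideoConfig(shotNoise = FALSE, readNoiseSd = 0, brightnessSdLog = 0, ...)
}

test_that("inter-frame displacement equals v / fps", {
  cfg <- cleanSloConfig(pixels = 256L, fovDeg = 5, durationS = 0.2,
                        backgroundLevel = 0)
  st <- phantomState(3.82)
  vid <- simulateIcgaVideo(st, manualBeadField(0.3, 0.8), cfg)
  fr <- videoFrames(vid)
  centroid <- function(m) {
    w <- m / sum(m)
    c(x = sum(colSums(w) * seq_len(ncol(m))),
      y = sum(rowSums(w) * seq_len(nrow(m))))
  }
  c1 <- centroid(fr[1, , ]); c2 <- centroid(fr[2, , ])
  dUm <- sqrt(sum((c2 - c1)^2)) * pixelScale(vid)
  expect_equal(dUm, 3.82 / 15.4 * 1000, tolerance = 0.005)
  expect_equal(dUm, 248.05, tolerance = 0.01)
})

test_that("stationary phantom gives identical noise-free frames", {
  cfg <- cleanSloConfig(pixels = 96L, durationS = 0.5)
  st <- phantomState(0)
  fld <- generateBeadField(icgaFieldArea(st, cfg), 580, 40, seed = 4)
  fr <- videoFrames(simulateIcgaVideo(st, fld, cfg))
  expect_identical(fr[1, , ], fr[dim(fr)[1], , ])
})

test_that("a field with no fluorescent beads warns and renders background", {
  cfg <- cleanSloConfig(pixels = 64L, durationS = 0.2, backgroundLevel = 3)
  st <- phantomState(2)
  fld <- generateBeadField(c(0, 1, 0, 1), 100, 0, seed = 2)
  expect_warning(vid <- simulateIcgaVideo(st, fld, cfg), "no fluorescent")
  expect_true(all(videoFrames(vid) == 3))
})

test_that("maximum intensity projection is exact, idempotent and order-free", {
  cfg <- cleanSloConfig(pixels = 96L, durationS = 0.5)
  st <- phantomState(0)
  fld <- generateBeadField(icgaFieldArea(st, cfg), 580, 40, seed = 5)
  vid <- simulateIcgaVideo(st, fld, cfg)
  fr <- videoFrames(vid)
  mip <- maxIntensityProjection(vid)
  expect_identical(mip, fr[1, , ])            # stationary, noise-free
  expect_identical(maxIntensityProjection(array(fr[1, , ], c(1, dim(fr)[2:3]))),
                   fr[1, , ])                  # single frame: identity
  perm <- fr[sample(dim(fr)[1]), , ]
  expect_identical(maxIntensityProjection(perm), mip)   # order invariance
  stacked <- array(0, c(2, dim(mip)))
  stacked[1, , ] <- mip; stacked[2, , ] <- mip
  expect_identical(maxIntensityProjection(stacked), mip)  # idempotent
  expect_error(maxIntensityProjection(matrix(0, 2, 2)), "3D")
})

test_that("projected trace length matches v x duration plus the bead image", {
  cfg <- cleanSloConfig(pixels = 256L, fovDeg = 5, durationS = 2,
                        backgroundLevel = 0)
  st <- phantomState(0.6)
  vid <- simulateIcgaVideo(st, manualBeadField(0.12, 0.85), cfg)
  mip <- maxIntensityProjection(vid)
  prof <- colSums(mip)
  lit <- range(which(prof > 0.05 * max(prof)))
  lenPx <- diff(lit)
  vm <- 0.6 * (dim(videoFrames(vid))[1] - 1) / 15.4  # travel of frame centers
  expectedPx <- vm * 1000 / pixelScale(vid)
  # trace = travel + blurred bead footprint (a few sigma wide)
  expect_lt(abs(lenPx - expectedPx), 8 * cfg@psfSigmaUm / pixelScale(vid))
})

test_that("rendering is linear in photon scale", {
  st <- phantomState(0)
  mk <- function(ps) {
    cfg <- cleanSloConfig(pixels = 64L, durationS = 0.2, fovDeg = 2,
                          backgroundLevel = 0, photonScale = ps)
    videoFrames(simulateIcgaVideo(st, manualBeadField(0.1, 0.1), cfg))[1, , ]
  }
  expect_equal(mk(160), 2 * mk(80), tolerance = 1e-12)
})

test_that("bead brightness heterogeneity is seeded and configurable", {
  st <- phantomState(0)
  fld <- manualBeadField(c(0.1, 0.25), c(0.1, 0.25))
  cfgH <- sloVideoConfig(pixels = 64L, durationS = 0.2, fovDeg = 2,
                         shotNoise = FALSE, readNoiseSd = 0,
                         backgroundLevel = 0, brightnessSdLog = 1, seed = 8L)
  f1 <- videoFrames(simulateIcgaVideo(st, fld, cfgH))[1, , ]
  f2 <- videoFrames(simulateIcgaVideo(st, fld, cfgH))[1, , ]
  expect_identical(f1, f2)
  peaks <- sort(c(max(f1[1:32, ]), max(f1[33:64, ])))
  expect_gt(peaks[2] / peaks[1], 1.01)  # unequal amplitudes
})
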