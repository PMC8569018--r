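# shared phantom sinograms for the reconstruction tests
reconPhantom <- local({
  ph <- makeEmbryoPhantom(phantomSpec(targetTortuosity = 1.3, seed = 5))
  channelVolume(ph$volume, 1L)
})

test_that("a centered symmetric object yields zero axis shift", {
  ps <- forwardProject(reconPhantom, nAngles = 32L)
  est <- estimateAxisShift(ps, axisCorrectionParams(nPairs = 8L))
  expect_lt(abs(est$shift), 0.5)
})

test_that("injected axis offsets are recovered through the round trip", {
  for (off in c(-5L, -2L, 3L, 5L)) {
    ps <- forwardProject(reconPhantom, nAngles = 32L, axisOffsetPx = off)
    est <- estimateAxisShift(ps, axisCorrectionParams(nPairs = 8L))
    expect_lt(abs(est$shift - off), 0.5)
    expect_identical(round(est$shift), as.numeric(off))
  }
})

test_that("the median makes the estimate robust to one corrupted pair", {
  ps <- forwardProject(reconPhantom, nAngles = 32L, axisOffsetPx = 3L)
  # corrupt one projection so its pair registers a wild displacement
  bad <- ps@images[, , 4L]
  ps@images[, , 4L] <- bad[, c(17:dim(bad)[2L], 1:16)]
  est <- estimateAxisShift(ps, axisCorrectionParams(nPairs = 16L))
  expect_lt(abs(est$shift - 3), 0.5)
  expect_gt(max(abs(est$pairShifts - 3)), 2)  # the outlier is in there
})

test_that("the shift estimate is invariant to global intensity scaling", {
  ps <- forwardProject(reconPhantom, nAngles = 32L, axisOffsetPx = 2L)
  ps2 <- ps
  ps2@images <- ps@images * 37.5
  e1 <- estimateAxisShift(ps, axisCorrectionParams(nPairs = 8L))
  e2 <- estimateAxisShift(ps2, axisCorrectionParams(nPairs = 8L))
  expect_equal(e1$shift, e2$shift, tolerance = 1e-9)
})

test_that("degenerate projection input is rejected", {
  flat <- ProjectionSet(array(1, c(10L, 12L, 4L)), angles = c(0, 90, 180, 270))
  expect_error(estimateAxisShift(flat, axisCorrectionParams(nPairs = 2L)),
               "no structure")
  one <- ProjectionSet(array(runif(120), c(10L, 12L, 1L)), angles = 0)
  expect_error(estimateAxisShift(one), "at least 2")
})

test_that("axis correction is the identity at zero and inverts itself", {
  ps <- forwardProject(reconPhantom, nAngles = 8L)
  expect_identical(applyAxisCorrection(ps, 0)@images, ps@images)
  fwd <- applyAxisCorrection(ps, 3)
  back <- applyAxisCorrection(fwd, -3)
  w <- dim(ps@images)[2L]
  interior <- 4:(w - 4L)
  expect_equal(back@images[, interior, ], ps@images[, interior, ],
               tolerance = 1e-9)
  expect_error(applyAxisCorrection(ps, w / 2), "quarter")
})

test_that("axis correction improves reconstruction of an off-axis series", {
  truth <- volumeData(reconPhantom)
  ps <- forwardProject(reconPhantom, nAngles = 60L, axisOffsetPx = 3L)
  recRaw <- reconstructFBP(ps)
  est <- estimateAxisShift(ps, axisCorrectionParams(nPairs = 8L))
  recCor <- reconstructFBP(applyAxisCorrection(ps, est$shift))
  corOf <- function(rec) {
    cr <- embryomorph:::.cropCenter(volumeData(rec), dim(truth))
    cor(as.vector(cr), as.vector(truth))
  }
  expect_gt(corOf(recCor), corOf(recRaw))
})

test_that("FBP is linear: zero projections give a zero volume", {
  zero <- ProjectionSet(array(0, c(8L, 16L, 12L)),
                        angles = (0:11) * 30)
  rec <- reconstructFBP(zero)
  expect_lt(max(abs(volumeData(rec))), 1e-9)
})

test_that("FBP recovers a uniform cylinder at the right radius and value", {
  cyl <- digitizedCylinderVolume()
  vol <- EmbryoVolume(cyl, 6.5)
  rec <- reconstructFBP(forwardProject(vol, nAngles = 400L))
  cr <- embryomorph:::.cropCenter(volumeData(rec), dim(cyl))
  expect_gt(cor(as.vector(cr), as.vector(cyl)), 0.95)
  mid <- cr[24L, , ]
  th <- embryomorph:::.otsuThreshold(as.vector(mid))
  radius <- sqrt(sum(mid > th) / pi)
  expect_lt(abs(radius - 20), 1)
  # amplitude approximately preserved
  expect_lt(abs(cr[24L, 48L, 48L] - 100) / 100, 0.05)
  # negative ringing retained, not clipped
  expect_lt(min(cr), 0)
})

test_that("reconstruction fidelity degrades with fewer angles", {
  cyl <- digitizedCylinderVolume(d = c(24L, 64L, 64L), radius = 14,
                                 zSpan = c(5L, 19L))
  vol <- EmbryoVolume(cyl, 6.5)
  corAt <- function(na) {
    rec <- reconstructFBP(forwardProject(vol, nAngles = na))
    cr <- embryomorph:::.cropCenter(volumeData(rec), dim(cyl))
    cor(as.vector(cr), as.vector(cyl))
  }
  c400 <- corAt(400L)
  c20 <- corAt(20L)
  expect_gt(c400, 0.95)
  expect_lt(c20, c400)
})

test_that("non-uniform angles are rejected", {
  img <- array(runif(8 * 16 * 3), c(8L, 16L, 3L))
  expect_error(ProjectionSet(img, angles = c(0, 10, 50)), "uniformly spaced")
})
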