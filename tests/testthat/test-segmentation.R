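test_that("scale-difference images match the per-voxel definition exactly", {
  set.seed(42)
  vol <- array(runif(8^3), c(8L, 8L, 8L))
  p <- segmentationParams(sigma1 = 6.5, sigma2 = 13, sigma3 = 26)
  u <- scaleDifferenceImages(EmbryoVolume(vol, 6.5), p)
  U1 <- gaussianSmooth3d(vol, 1)
  U2 <- gaussianSmooth3d(vol, 2)
  U3 <- gaussianSmooth3d(vol, 4)
  eps <- 1e-6 * max(vol)
  u1b <- array(0, dim(vol))
  u2b <- array(0, dim(vol))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    u1b[i, j, k] <- (U1[i, j, k] - U2[i, j, k]) / max(U2[i, j, k], eps)
    u2b[i, j, k] <- (U2[i, j, k] - U3[i, j, k]) / max(U3[i, j, k], eps)
  }
  expect_identical(u$u1, u1b)
  expect_identical(u$u2, u2b)
})

test_that("a constant volume gives identically zero difference images", {
  u <- scaleDifferenceImages(EmbryoVolume(array(5, c(8L, 8L, 8L)), 6.5),
                             segmentationParams(sigma1 = 6.5, sigma2 = 13,
                                                sigma3 = 26))
  expect_lt(max(abs(u$u1)), 1e-12)
  expect_lt(max(abs(u$u2)), 1e-12)
})

test_that("a blob at the finest scale lights up u1 at its center", {
  d <- c(17L, 17L, 17L)
  g <- voxelGrid(d)
  blob <- exp(-((g$z - 9)^2 + (g$y - 9)^2 + (g$x - 9)^2) / (2 * 2^2))
  u <- scaleDifferenceImages(EmbryoVolume(blob, 6.5),
                             segmentationParams(sigma1 = 13, sigma2 = 39,
                                                sigma3 = 78))
  expect_gt(u$u1[9, 9, 9], 0)
})

test_that("normalized differences are invariant to intensity scaling", {
  set.seed(1)
  vol <- array(runif(10^3, 0.1, 1), c(10L, 10L, 10L))
  p <- segmentationParams(sigma1 = 6.5, sigma2 = 13, sigma3 = 26,
                          epsilon = 1e-12)
  uA <- scaleDifferenceImages(EmbryoVolume(vol, 6.5), p)
  uB <- scaleDifferenceImages(EmbryoVolume(vol * 7, 6.5), p)
  expect_equal(uA$u1, uB$u1, tolerance = 1e-6)
  expect_equal(uA$u2, uB$u2, tolerance = 1e-6)
})

test_that("segmentation equals the voxelwise rule and degenerates at w = 1", {
  set.seed(3)
  ph <- smallPhantom(seed = 3, volumeShape = c(24L, 32L, 48L),
                     radiusProfile = function(s) rep(26, length(s)))
  nuc <- channelVolume(ph$volume, 1L)
  p <- segmentationParams(weight = 0.5, threshold = 0.1, minSize = 1L)
  u <- scaleDifferenceImages(nuc, p)
  binary <- (0.5 * u$u1 + 0.5 * u$u2) > 0.1
  masks <- segmentEmbryos(nuc, p)
  combined <- Reduce(`|`, lapply(masks, maskArray))
  expect_identical(combined, binary)

  p1 <- segmentationParams(weight = 1, threshold = 0.1, minSize = 1L)
  masks1 <- segmentEmbryos(nuc, p1)
  combined1 <- Reduce(`|`, lapply(masks1, maskArray))
  expect_identical(combined1, u$u1 > 0.1)
})

test_that("raising the threshold never grows the binary image", {
  ph <- smallPhantom(seed = 6, volumeShape = c(24L, 32L, 48L),
                     radiusProfile = function(s) rep(26, length(s)))
  nuc <- channelVolume(ph$volume, 1L)
  u <- scaleDifferenceImages(nuc, segmentationParams())
  synth <- 0.8 * u$u1 + 0.2 * u$u2
  prev <- sum(synth > 0.2)
  for (t in c(0.4, 0.6, 0.8, 1.0)) {
    cur <- sum(synth > t)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("the size criterion selects instances and orders them by size", {
  # two tubes of very different calibre in one acquisition
  big <- makeEmbryoPhantom(phantomSpec(seed = 1))
  small <- makeEmbryoPhantom(phantomSpec(
    seed = 2, radiusProfile = function(s) rep(24, length(s))))
  acq <- makeAcquisition(list(big, small))
  nuc <- channelVolume(acq$volume, 1L)

  pAll <- segmentationParams(minSize = 100, maxSize = 1e7)
  masksAll <- segmentEmbryos(nuc, pAll)
  expect_length(masksAll, 2L)
  expect_gt(masksAll[[1L]]@voxelCount, masksAll[[2L]]@voxelCount)
  expect_identical(sapply(masksAll, slot, "instanceId"), 1:2)

  # window straddling the two measured sizes keeps exactly the larger one
  cut <- mean(sapply(masksAll, slot, "voxelCount"))
  p <- segmentationParams(minSize = cut, maxSize = 1e7)
  masks <- segmentEmbryos(nuc, p)
  expect_length(masks, 1L)
  expect_equal(masks[[1L]]@voxelCount, masksAll[[1L]]@voxelCount)

  # upper bound excludes everything
  pNone <- segmentationParams(minSize = 1, maxSize = 50)
  expect_warning(none <- segmentEmbryos(nuc, pNone), "size criterion")
  expect_length(none, 0L)
})

test_that("an empty result warns rather than errors", {
  vol <- EmbryoVolume(array(0, c(12L, 12L, 12L)), 6.5)
  expect_warning(out <- segmentEmbryos(vol, segmentationParams(minSize = 10)),
                 "size criterion")
  expect_length(out, 0L)
})
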