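vs <- 6.5

test_that("landmarks are the channel argmax with deterministic tie-breaks", {
  d <- c(12L, 14L, 16L)
  m <- array(FALSE, d)
  m[4:9, 4:11, 4:13] <- TRUE
  mask <- EmbryoMask(m, vs)
  chA <- array(0, d)
  chA[5, 6, 7] <- 3
  chP <- array(0, d)
  chP[8, 9, 12] <- 2
  lm <- detectLandmarks(chA, chP, mask)
  expect_equal(lm@anterior, c(5, 6, 7))
  expect_equal(lm@posterior, c(8, 9, 12))

  # two equal maxima: lowest linear index wins; brute-force scan agrees
  chT <- array(0, d)
  chT[7, 5, 5] <- 5
  chT[5, 5, 5] <- 5
  lmT <- detectLandmarks(chT, chP, mask)
  best <- NULL
  for (x in seq_len(d[3L])) for (y in seq_len(d[2L])) for (z in seq_len(d[1L]))
    if (is.null(best) && chT[z, y, x] == 5) best <- c(z, y, x)
  # scan order above is z fastest = R linear index order
  expect_equal(lmT@anterior, best)
  expect_equal(best, c(5, 5, 5))

  expect_error(detectLandmarks(array(0, d), chP, mask), "landmark channel empty")
})

test_that("phantom marker landmarks land on the true endpoints", {
  ph <- smallPhantom(seed = 4)
  masks <- segmentEmbryos(channelVolume(ph$volume, 1L))
  lm <- detectLandmarks(channelVolume(ph$volume, 2L),
                        channelVolume(ph$volume, 3L), masks[[1L]])
  expect_lt(sqrt(sum((lm@anterior - ph$truth@anteriorPoint)^2)), 2)
  expect_lt(sqrt(sum((lm@posterior - ph$truth@posteriorPoint)^2)), 2)
})

test_that("skeleton of a straight tube is the axial centerline", {
  ph <- makeEmbryoPhantom(phantomSpec(targetTortuosity = 1, seed = 2))
  sk <- computeSkeleton(truthMaskOf(ph), truthLandmarksOf(ph))
  trueLen <- sum(sqrt(rowSums(diff(ph$truth@centerline)^2))) * vs
  expect_lt(abs(pathLength(sk) - trueLen) / trueLen, 0.05)
  # path stays on the axis
  p <- skeletonPath(sk)
  expect_lt(max(abs(p[, 1L] - ph$truth@centerline[1L, 1L])), 1.5)
})

test_that("skeleton of a curved tube tracks the true centerline", {
  ph <- makeEmbryoPhantom(phantomSpec(targetTortuosity = 1.3, seed = 3))
  sk <- computeSkeleton(truthMaskOf(ph), truthLandmarksOf(ph))
  p <- skeletonPath(sk)
  tc <- ph$truth@centerline
  dmin <- vapply(seq_len(nrow(p)), function(i)
    min(sqrt(colSums((t(tc) - p[i, ])^2))), numeric(1L))
  expect_lte(mean(dmin), 2)
})

test_that("the medial axis of a ball collapses centrally", {
  ball <- digitizedBall()
  sk <- computeSkeleton(EmbryoMask(ball, vs),
                        Landmarks(c(20, 20, 6), c(20, 20, 35)))
  expect_lte(pathLength(sk), 15 * vs)
})

test_that("a flat mask cannot be skeletonized", {
  flat <- array(FALSE, c(8L, 20L, 20L))
  flat[4L, 5:15, 5:15] <- TRUE
  expect_error(computeSkeleton(EmbryoMask(flat, vs),
                               Landmarks(c(4, 5, 5), c(4, 15, 15))),
               "thinner")
})

test_that("principal axis lengths match analytic second moments", {
  ball <- digitizedBall()
  L <- principalAxisLengths(EmbryoMask(ball, vs))
  expect_lt(abs(L["L3"] / L["L1"] - 1), 0.02)

  ell <- digitizedEllipsoid(c(30L, 50L, 90L), c(15, 25, 45), c(10, 20, 40))
  L2 <- principalAxisLengths(EmbryoMask(ell, vs))
  expect_lt(abs(L2["L2"] / L2["L1"] - 0.50), 0.03)
  expect_lt(abs(L2["L3"] / L2["L1"] - 0.25), 0.03)

  # rotating 90 degrees about z permutes nothing but orientation
  L2r <- principalAxisLengths(EmbryoMask(aperm(ell, c(1L, 3L, 2L)), vs))
  expect_lt(max(abs(L2r - L2) / L2), 0.02)

  expect_error(principalAxisLengths(
    EmbryoMask(array(FALSE, c(5L, 5L, 5L)), vs)), "degenerate")
})

test_that("solidity is 1-ish for convex bodies and drops with notches", {
  ell <- digitizedEllipsoid(c(40L, 40L, 40L), c(20, 20, 20), c(9, 15, 18))
  s0 <- maskSolidity(EmbryoMask(ell, vs))
  expect_gte(s0, 0.97)
  notched <- ell
  notched[12:28, 12:28, 1:20] <- FALSE
  s1 <- maskSolidity(EmbryoMask(notched, vs))
  expect_lt(s1, s0)
})

test_that("solidity of an L-shape matches the analytic hull of the extrusion", {
  d <- c(40L, 40L, 40L)
  L <- array(FALSE, d)
  L[5:35, 5:15, 5:15] <- TRUE
  L[5:15, 5:35, 5:15] <- TRUE
  got <- maskSolidity(EmbryoMask(L, vs))
  # the shape is a 2D L extruded along x: hull = 2D hull area x depth,
  # with the 2D hull area from base R chull (independent route)
  co <- which(L[, , 5L], arr.ind = TRUE)
  h <- chull(co)
  poly <- co[h, ]
  n <- nrow(poly)
  area <- abs(sum(poly[, 1L] * poly[c(2:n, 1L), 2L] -
                    poly[c(2:n, 1L), 1L] * poly[, 2L])) / 2
  # lattice points in the closed polygon via Pick's theorem:
  # count = A + B/2 + 1 with B = boundary lattice points (gcd per edge)
  dedge <- abs(poly - poly[c(2:n, 1L), ])
  B <- sum(mapply(function(a, b) {
    while (b != 0) { t <- a %% b; a <- b; b <- t }
    a
  }, dedge[, 1L], dedge[, 2L]))
  hullCount <- (area + B / 2 + 1) * 11
  expect_lt(abs(got - sum(L) / hullCount), 0.02)
})

test_that("tortuosity matches analytic arc/chord ratios", {
  ph <- makeEmbryoPhantom(phantomSpec(targetTortuosity = 1, seed = 2))
  sk <- computeSkeleton(truthMaskOf(ph), truthLandmarksOf(ph))
  expect_lt(abs(tortuosity(sk) - 1), 0.02)

  ph2 <- makeEmbryoPhantom(phantomSpec(
    targetTortuosity = pi / 2, seed = 4,
    radiusProfile = function(s) rep(40, length(s)),
    volumeShape = c(48L, 72L, 96L)))
  sk2 <- computeSkeleton(truthMaskOf(ph2), truthLandmarksOf(ph2))
  expect_lt(abs(tortuosity(sk2) - pi / 2), 0.05)
  expect_gte(tortuosity(sk2), 1)
})

test_that("skeleton-surface distances match the mask radius profile", {
  # constant radius: low variation, mean near the radius
  ph <- makeEmbryoPhantom(phantomSpec(
    targetTortuosity = 1, seed = 2,
    radiusProfile = function(s) rep(65, length(s)),
    volumeShape = c(44L, 48L, 96L)))
  sk <- computeSkeleton(truthMaskOf(ph), truthLandmarksOf(ph))
  st <- skeletonSurfaceStats(truthMaskOf(ph), sk)
  expect_lte(st[["variation"]], 0.05)
  expect_lt(abs(st[["mean"]] - 65) / 65, 0.15)

  # ramped radius 5 -> 15 voxels: per-voxel distances track the ramp
  ph2 <- makeEmbryoPhantom(phantomSpec(
    targetTortuosity = 1, seed = 2,
    radiusProfile = function(s) (5 + 10 * s) * vs,
    volumeShape = c(56L, 64L, 104L)))
  mk2 <- truthMaskOf(ph2)
  sk2 <- computeSkeleton(mk2, truthLandmarksOf(ph2))
  p <- skeletonPath(sk2)
  surf <- embryomorph:::.surfaceVoxels(maskArray(mk2))
  dmap <- embryomorph:::.edt_cpp(surf, dim(surf))
  dists <- dmap[p]
  # expected radius at each path voxel from the generator's radius table
  tc <- ph2$truth@centerline
  sN <- seq(0, 1, length.out = nrow(tc))
  expRad <- vapply(seq_len(nrow(p)), function(i) {
    j <- which.min(sqrt(colSums((t(tc) - p[i, ])^2)))
    5 + 10 * sN[j]
  }, numeric(1L))
  central <- seq_len(nrow(p)) > 0.1 * nrow(p) & seq_len(nrow(p)) < 0.9 * nrow(p)
  expect_lt(max(abs(dists[central] - expRad[central])), 1.5)
  # moments agree with direct computation on the measured distances
  st2 <- skeletonSurfaceStats(mk2, sk2)
  o <- momentOracle(dists)
  expect_equal(st2[["variation"]], o[["variation"]], tolerance = 1e-9)
  expect_equal(st2[["skewness"]], o[["skewness"]], tolerance = 1e-9)
})

test_that("nearest-surface distances agree with exhaustive search", {
  set.seed(8)
  d <- c(14L, 14L, 14L)
  m <- digitizedEllipsoid(d, c(7, 7, 7), c(4, 5, 6))
  surf <- embryomorph:::.surfaceVoxels(m)
  dmap <- embryomorph:::.edt_cpp(surf, d)
  sco <- which(surf, arr.ind = TRUE)
  inside <- which(m, arr.ind = TRUE)
  for (i in sample(nrow(inside), 20L)) {
    p <- inside[i, ]
    brute <- min(sqrt(colSums((t(sco) - p)^2)))
    expect_equal(dmap[p[1L], p[2L], p[3L]], brute, tolerance = 1e-12)
  }
})

test_that("AP index: identical seeds give 1, straight path gives -1", {
  seg <- array(FALSE, c(5L, 5L, 30L))
  seg[3L, 3L, 3:28] <- TRUE
  mk <- EmbryoMask(seg, vs)
  expect_equal(apIndex(mk, Landmarks(c(3, 3, 10), c(3, 3, 10))), 1)
  expect_lt(abs(apIndex(mk, Landmarks(c(3, 3, 3), c(3, 3, 28))) - (-1)), 0.01)
  expect_error(apIndex(mk, Landmarks(c(3, 3, 3), c(1, 1, 40))),
               "outside mask")
})

test_that("geodesic distance maps equal an independent graph oracle", {
  skip_if_not_installed("igraph")
  # bent path graph
  m <- array(FALSE, c(6L, 12L, 12L))
  m[3L, 2:10, 3L] <- TRUE
  m[3L, 10L, 3:9] <- TRUE
  seedPt <- c(3L, 2L, 3L)
  g <- embryomorph:::.geodesic_cpp(m, dim(m),
                                   embryomorph:::.linearIndex0(seedPt, dim(m)))
  got <- g$dist[m]
  want <- geodesicOracle(m, seedPt)
  # both enumerate mask voxels in the same (column-major) order
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("intensity statistics follow the min-subtraction contract", {
  d <- c(4L, 4L, 4L)
  m <- array(FALSE, d)
  m[1L, 1L, 1:3] <- TRUE
  vol <- array(0, d)
  vol[1L, 1L, 1:3] <- c(10, 12, 20)
  st <- intensityStats(vol, EmbryoMask(m, vs))
  expect_equal(st[["mean"]], 4)

  set.seed(2)
  vals <- rnorm(10L, 50, 12)
  m2 <- array(FALSE, c(2L, 5L, 2L))
  m2[1L, , 1L] <- TRUE
  m2[2L, , 2L] <- TRUE
  v2 <- array(0, c(2L, 5L, 2L))
  v2[m2] <- vals
  st2 <- intensityStats(v2, EmbryoMask(m2, vs))
  o <- momentOracle(vals - min(vals))
  expect_equal(st2[["skewness"]], o[["skewness"]], tolerance = 1e-12)
  expect_equal(st2[["kurtosis"]], o[["kurtosis"]], tolerance = 1e-12)
  if (requireNamespace("e1071", quietly = TRUE)) {
    expect_equal(st2[["skewness"]],
                 e1071::skewness(vals - min(vals), type = 1L),
                 tolerance = 1e-12)
  }

  # doubling intensities doubles the mean, fixes the scale-free moments
  st3 <- intensityStats(v2 * 2, EmbryoMask(m2, vs))
  expect_equal(st3[["mean"]], 2 * st2[["mean"]])
  expect_equal(st3[["variation"]], st2[["variation"]], tolerance = 1e-12)
  expect_equal(st3[["kurtosis"]], st2[["kurtosis"]], tolerance = 1e-12)

  # constant in-mask intensity: mean 0, variation designated missing
  v3 <- array(7, d)
  stc <- intensityStats(v3, EmbryoMask(m, vs))
  expect_equal(stc[["mean"]], 0)
  expect_true(is.na(stc[["variation"]]))
})

test_that("descriptor vectors have 26 entries and are motion-invariant", {
  ph <- smallPhantom(seed = 4, volumeShape = c(32L, 40L, 64L))
  mk <- truthMaskOf(ph)
  lm <- truthLandmarksOf(ph)
  dv <- computeDescriptors(ph$volume, mk, lm)
  expect_length(dv, 26L)
  expect_identical(names(dv), descriptorNames())
  expect_gte(dv[["tortuosity"]], 1)
  expect_gte(dv[["solidity"]], 0)
  expect_lte(dv[["solidity"]], 1)
  expect_true(dv[["axis_length_L1_um"]] >= dv[["axis_length_L2_um"]])
  expect_true(dv[["axis_length_L2_um"]] >= dv[["axis_length_L3_um"]])
  expect_gte(dv[["ap_index"]], -1)
  expect_lte(dv[["ap_index"]], 1)

  # translation by whole voxels leaves every shape descriptor unchanged
  sh <- c(3L, 5L, 2L)
  d <- dim(maskArray(mk))
  shift <- function(a) {
    out <- array(0, d)
    out[(1 + sh[1L]):d[1L], (1 + sh[2L]):d[2L], (1 + sh[3L]):d[3L]] <-
      a[1:(d[1L] - sh[1L]), 1:(d[2L] - sh[2L]), 1:(d[3L] - sh[3L])]
    out
  }
  arr <- volumeData(ph$volume)
  arrT <- array(0, dim(arr))
  for (ch in 1:3) arrT[, , , ch] <- shift(arr[, , , ch])
  mkT <- EmbryoMask(shift(maskArray(mk)) > 0, vs)
  lmT <- Landmarks(lm@anterior + sh, lm@posterior + sh)
  dvT <- computeDescriptors(EmbryoVolume(arrT, vs), mkT, lmT)
  expect_equal(unname(dvT), unname(dv), tolerance = 1e-6)

  # 90-degree rotation about z (swap y/x axes)
  arrR <- aperm(arr, c(1L, 3L, 2L, 4L))
  mkR <- EmbryoMask(aperm(maskArray(mk), c(1L, 3L, 2L)), vs)
  lmR <- Landmarks(lm@anterior[c(1L, 3L, 2L)], lm@posterior[c(1L, 3L, 2L)])
  dvR <- computeDescriptors(EmbryoVolume(arrR, vs), mkR, lmR)
  # distribution-shape moments of the near-constant skeleton-surface
  # distance set are resampling-noise dominated: compare them absolutely
  distShape <- c("skel_surf_dist_variation", "skel_surf_dist_skewness",
                 "skel_surf_dist_kurtosis")
  shape <- setdiff(descriptorNames(),
                   c("intensity_mean", "intensity_variation",
                     "intensity_skewness", "intensity_kurtosis", distShape))
  rel <- abs(dvR[shape] - dv[shape]) / pmax(abs(dv[shape]), 1e-9)
  expect_lt(max(rel), 0.02)
  expect_lt(max(abs(dvR[distShape] - dv[distShape])), 0.25)
})
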