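test_that("phantom generation is a pure function of spec and seed", {
  s <- phantomSpec(targetTortuosity = 1.3, seed = 5)
  a <- makeEmbryoPhantom(s)
  b <- makeEmbryoPhantom(s)
  expect_identical(volumeData(a$volume), volumeData(b$volume))
  expect_identical(maskArray(a$truth), maskArray(b$truth))
})

test_that("generated centerline matches the requested tortuosity", {
  for (tt in c(1.1, 1.3)) {
    ph <- makeEmbryoPhantom(phantomSpec(targetTortuosity = tt, seed = 2))
    expect_gte(ph$truth@trueTortuosity, tt - 0.05)
    expect_lte(ph$truth@trueTortuosity, tt + 0.05)
  }
})

test_that("straight constant-radius tube volume matches the analytic value", {
  # the tube body is a union of spheres along the centerline, so a straight
  # tube is a spherocylinder: V = pi r^2 L + 4/3 pi r^3
  # radius chosen off the lattice (7.3 voxels): an integer-voxel radius
  # systematically excludes exact-boundary lattice points and biases the
  # digitized volume low
  vs <- 6.5
  ph <- makeEmbryoPhantom(phantomSpec(
    targetTortuosity = 1, seed = 2,
    radiusProfile = function(s) rep(47.45, length(s)),
    volumeShape = c(36L, 44L, 96L)))
  r <- 47.45 / vs
  L <- sum(sqrt(rowSums(diff(ph$truth@centerline)^2)))
  analytic <- pi * r^2 * L + 4 / 3 * pi * r^3
  expect_lt(abs(ph$truth@trueVolume - analytic) / analytic, 0.05)
})

test_that("a tube exceeding the volume bounds is rejected with context", {
  expect_error(makeEmbryoPhantom(phantomSpec(
    radiusProfile = function(s) rep(150, length(s)))),
    "exits volume bounds")
})

test_that("truth invariants hold: centerline inside mask, tortuosity >= 1", {
  ph <- smallPhantom(tort = 1.25, seed = 12)
  m <- maskArray(ph$truth)
  cl <- round(ph$truth@centerline)
  inside <- vapply(seq_len(nrow(cl)), function(i)
    m[cl[i, 1L], cl[i, 2L], cl[i, 3L]], logical(1L))
  expect_true(all(inside))
  expect_gte(ph$truth@trueTortuosity, 1)
})

test_that("marker channels peak at the centerline endpoints", {
  ph <- smallPhantom(seed = 4)
  for (ch in 2:3) {
    arr <- volumeData(channelVolume(ph$volume, ch))
    peak <- arrayInd(which.max(arr), dim(arr))
    truthPt <- if (ch == 2L) ph$truth@anteriorPoint else
      ph$truth@posteriorPoint
    expect_lt(sqrt(sum((peak - truthPt)^2)), 1.5)
  }
})

test_that("cohorts are reproducible, ordered, and severity-monotone", {
  cs <- cohortSpec(nPerLevel = 2L, seed = 7)
  coh1 <- makeCohort(cs)
  coh2 <- makeCohort(cs)
  expect_length(coh1, 8L)
  expect_identical(sapply(coh1, `[[`, "dose"),
                   rep(cs$doseLevels, each = 2L))
  expect_identical(lapply(coh1, function(e) maskArray(e$truth)),
                   lapply(coh2, function(e) maskArray(e$truth)))
  tor <- sapply(coh1, function(e) e$truth@trueTortuosity)
  byLevel <- tapply(tor, rep(seq_len(4L), each = 2L), mean)
  expect_true(all(diff(byLevel) > 0))
})

test_that("non-monotone severity maps are rejected", {
  expect_error(cohortSpec(doseLevels = c("a", "b"), severityMap = list(
    list(tortuosityMean = 1.3, tortuositySD = 0, thicknessAmplitude = 0,
         axisLengthScale = 1, notchAmplitude = 0),
    list(tortuosityMean = 1.1, tortuositySD = 0, thicknessAmplitude = 0,
         axisLengthScale = 1, notchAmplitude = 0))),
    "monotonically")
})

test_that("forward projection conserves mass and is linear", {
  ph <- smallPhantom(seed = 3, volumeShape = c(24L, 32L, 48L),
                     radiusProfile = function(s) rep(26, length(s)))
  vol <- channelVolume(ph$volume, 1L)
  ps <- forwardProject(vol, nAngles = 16L)
  total <- sum(volumeData(vol))
  sums <- apply(ps@images, 3L, sum)
  expect_lt(max(abs(sums - total)) / total, 0.01)

  zero <- forwardProject(EmbryoVolume(array(0, c(16L, 20L, 20L)), 6.5),
                         nAngles = 8L)
  expect_equal(max(abs(zero@images)), 0)
})

test_that("nuclear gradient stacks encode the decay exactly and are seeded", {
  g0 <- makeNuclearGradientStack(0L)
  expect_equal(nrow(g0$table), 0L)
  expect_equal(max(abs(volumeData(g0$stack))), 0)

  g1 <- makeNuclearGradientStack(30L, seed = 11)
  g2 <- makeNuclearGradientStack(30L, seed = 11)
  expect_identical(volumeData(g1$stack), volumeData(g2$stack))
  expect_equal(g1$table$intensity, exp(-g1$table$margin_distance / 40),
               tolerance = 1e-9)
  # separation >= 2 nuclear diameters
  dd <- as.matrix(dist(as.matrix(g1$table[, c("z", "y", "x")])))
  diag(dd) <- Inf
  expect_gte(min(dd), 2 * 4 * (3 / 2))
})

test_that("impossible nucleus packings raise an error", {
  expect_error(makeNuclearGradientStack(80L, stackShape = c(12L, 20L, 20L),
                                        seed = 1),
               "cannot place")
})
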