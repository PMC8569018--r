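test_that("an empty stack yields zero nuclei without error", {
  labs <- segmentNucleiStack(array(0, c(6L, 20L, 20L)))
  expect_equal(attr(labs, "nNuclei"), 0L)
  rec <- measureNuclei(labs, EmbryoVolume(array(0, c(6L, 20L, 20L)), 2))
  expect_equal(nrow(rec), 0L)
})

test_that("well-separated synthetic nuclei are counted and located", {
  g <- makeNuclearGradientStack(50L, seed = 3L)
  labs <- segmentNucleiStack(g$stack, meanFilterRadius = 5L,
                             minVoxels = 10L, offset = 1e-3)
  expect_lte(abs(attr(labs, "nNuclei") - 50L), 2L)
  rec <- measureNuclei(labs, g$stack)
  err <- vapply(seq_len(nrow(rec)), function(i)
    min(sqrt((g$table$z - rec$z[i])^2 + (g$table$y - rec$y[i])^2 +
               (g$table$x - rec$x[i])^2)), numeric(1L))
  expect_lt(max(err), 0.5)
})

test_that("nucleus counts recover within 4% across seeds", {
  counts <- vapply(1:5, function(s) {
    gs <- makeNuclearGradientStack(50L, seed = s)
    attr(segmentNucleiStack(gs$stack, 5L, 10L, offset = 1e-3), "nNuclei")
  }, integer(1L))
  expect_true(all(abs(counts - 50L) / 50 <= 0.04))
})

test_that("single-voxel specks are removed by morphology and size filters", {
  arr <- array(0, c(6L, 40L, 40L))
  set.seed(4)
  idx <- cbind(sample(6L, 12L, TRUE), sample(40L, 12L, TRUE),
               sample(40L, 12L, TRUE))
  arr[idx] <- 10
  labs <- segmentNucleiStack(arr, meanFilterRadius = 3L, minVoxels = 5L,
                             offset = 1e-3)
  expect_equal(attr(labs, "nNuclei"), 0L)
})

test_that("painted intensities and the exclusion ROI are respected", {
  g <- makeNuclearGradientStack(30L, seed = 6L, decay = function(y) rep(100, length(y)),
                                stackShape = c(30L, 110L, 110L))
  labs <- segmentNucleiStack(g$stack, 5L, 10L, offset = 0.1)
  rec <- measureNuclei(labs, g$stack)
  # mean over the blob is below the center value but within range
  expect_true(all(rec$mean_nuclear > 10 & rec$mean_nuclear <= 100))
  peak <- vapply(seq_len(nrow(rec)), function(i) {
    m <- labs == i
    max(volumeData(g$stack)[m])
  }, numeric(1L))
  expect_lt(max(abs(peak - 100) / 100), 0.12)

  roi <- matrix(FALSE, 110L, 110L)
  roi[, 1:55] <- TRUE
  labs2 <- segmentNucleiStack(g$stack, 5L, 10L, offset = 0.1,
                              exclusionROI = roi)
  rec2 <- measureNuclei(labs2, g$stack)
  # only nuclei whose body lies right of the excluded strip survive intact
  expect_equal(nrow(rec2), sum(g$table$x > 55 + 1))
  expect_true(all(rec2$x > 55))
  expect_error(segmentNucleiStack(g$stack, exclusionROI = matrix(TRUE, 3, 3)),
               "malformed")
})

test_that("margin distances follow the reference plane and clamp at zero", {
  g <- makeNuclearGradientStack(20L, seed = 8L)
  labs <- segmentNucleiStack(g$stack, 5L, 10L, offset = 1e-3)
  rec <- measureNuclei(labs, g$stack,
                       marginReference = list(axis = "y", origin = 1,
                                              direction = 1))
  expect_true(all(rec$margin_distance >= 0))
  expect_equal(rec$margin_distance, pmax(0, (rec$y - 1) * 2),
               tolerance = 1e-9)
  recRev <- measureNuclei(labs, g$stack,
                          marginReference = list(axis = "y", origin = 200,
                                                 direction = 1))
  expect_true(all(recRev$margin_distance == 0))
})

test_that("lowess profiles recover constant and exponential gradients", {
  recs <- lapply(1:3, function(s)
    makeNuclearGradientStack(200L, seed = s,
                             stackShape = c(40L, 60L, 400L))$table)
  names(recs) <- paste0("embryo", 1:3)

  gp <- fitGradientProfile(recs, smoothingFraction = 0.3)
  truth <- exp(-gp@grid / 40)
  rng <- range(gp@grid)
  central <- gp@grid >= rng[1L] + 0.1 * diff(rng) &
    gp@grid <= rng[1L] + 0.9 * diff(rng)
  expect_lt(max(abs(gp@mean[central] - truth[central]) / truth[central]),
            0.05)
  # strictly decreasing input -> non-increasing fit (1% of range slack)
  expect_lte(max(diff(gp@mean)), 0.01 * diff(range(gp@mean)))

  recsC <- lapply(recs, function(r) {
    r$intensity <- 7
    r
  })
  gpc <- fitGradientProfile(recsC)
  expect_lt(max(abs(gpc@mean - 7)), 1e-6)
  expect_lt(max(gpc@sem), 1e-9)

  # scaling all intensities scales the mean curve and SEM linearly
  recsS <- lapply(recs, function(r) {
    r$intensity <- 3 * r$intensity
    r
  })
  gps <- fitGradientProfile(recsS, smoothingFraction = 0.3)
  expect_equal(gps@mean, 3 * gp@mean, tolerance = 1e-9)
  expect_equal(gps@sem, 3 * gp@sem, tolerance = 1e-9)

  few <- recs
  few[[1L]] <- few[[1L]][1:5, ]
  expect_error(fitGradientProfile(few), "fewer than 10")
})

test_that("domain size ratios behave at the extremes and at one half", {
  expect_equal(domainSizeRatio(100, 100), 1)
  expect_equal(domainSizeRatio(0, 100), 0)
  expect_error(domainSizeRatio(101, 100), "registration")

  emb <- matrix(0, 60L, 60L)
  emb[10:50, 10:50] <- 100
  sig <- matrix(0, 60L, 60L)
  sig[10:50, 10:29] <- 80
  da <- domainAreasFromMIP(sig, emb, pixelSize = 1.5)
  expect_equal(da$embryoArea, 41^2 * 1.5^2)
  expect_lt(abs(da$ratio - 20 / 41), 0.02)
  expect_equal(domainAreasFromMIP(emb * 0, emb)$ratio, 0)
})
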