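#' Specify a synthetic embryo phantom
#'
#' A phantom is a curved-tube "embryo body" built as the union of spheres
#' along a smooth centerline (Catmull-Rom interpolation of control points),
#' with Gaussian marker spots at the anterior and posterior centerline
#' endpoints, emulating a 24-hpf zebrafish embryo with nuclear staining and
#' head/tail expression landmarks. When no control points are given, the
#' centerline is a planar circular arc whose arc/chord ratio equals
#' \code{targetTortuosity} exactly.
#'
#' Severity knobs mirror the descriptor groups the pipeline measures:
#' \code{targetTortuosity} (axis bending), \code{thicknessAmplitude}
#' (sinusoidal radius modulation, fraction of the base radius),
#' \code{axisLengthScale} (axis shortening) and \code{notchAmplitude}
#' (a solidity-reducing surface notch, fraction of the local radius).
#'
#' @param centerlineControlPoints optional matrix of control points
#'   (rows = points; z, y, x in micrometers, origin at the first voxel
#'   center); if NULL an arc matching \code{targetTortuosity} is used
#' @param radiusProfile function mapping normalized arclength in [0,1] to
#'   tube radius in micrometers
#' @param targetTortuosity desired centerline arc/chord ratio (>= 1)
#' @param anteriorMarkerSigma,posteriorMarkerSigma marker spot widths (um)
#' @param volumeShape volume dimensions (z, y, x) in voxels
#' @param voxelSize isotropic voxel size (um)
#' @param intensityLevel body and marker peak intensity (arbitrary units)
#' @param noiseSigma additive Gaussian noise SD (arbitrary units)
#' @param thicknessAmplitude radius modulation amplitude (fraction)
#' @param axisLengthScale scale factor on the default axis chord length
#' @param notchAmplitude notch depth (fraction of local radius; 0 = none)
#' @param seed integer seed; the phantom is a pure function of (spec, seed)
#' @return a PhantomSpec (validated list)
#' @examples
#' spec <- phantomSpec(targetTortuosity = 1.2, seed = 7)
#' @export
phantomSpec <- function(centerlineControlPoints = NULL,
                        radiusProfile = function(s) rep(50, length(s)),
                        targetTortuosity = 1.1,
                        anteriorMarkerSigma = 20,
                        posteriorMarkerSigma = 20,
                        volumeShape = c(48L, 64L, 96L),
                        voxelSize = 6.5,
                        intensityLevel = 100,
                        noiseSigma = 0,
                        thicknessAmplitude = 0,
                        axisLengthScale = 1,
                        notchAmplitude = 0,
                        seed = 1L) {
  if (targetTortuosity < 1) stop("targetTortuosity must be >= 1")
  if (voxelSize <= 0) stop("voxelSize must be positive")
  if (length(volumeShape) != 3L || any(volumeShape < 8))
    stop("volumeShape must be 3 positive integers")
  if (thicknessAmplitude < 0 || thicknessAmplitude >= 1)
    stop("thicknessAmplitude must be in [0, 1)")
  if (axisLengthScale <= 0) stop("axisLengthScale must be positive")
  spec <- list(centerlineControlPoints = centerlineControlPoints,
               radiusProfile = radiusProfile,
               targetTortuosity = targetTortuosity,
               anteriorMarkerSigma = anteriorMarkerSigma,
               posteriorMarkerSigma = posteriorMarkerSigma,
               volumeShape = as.integer(volumeShape),
               voxelSize = voxelSize,
               intensityLevel = intensityLevel,
               noiseSigma = noiseSigma,
               thicknessAmplitude = thicknessAmplitude,
               axisLengthScale = axisLengthScale,
               notchAmplitude = notchAmplitude,
               seed = as.integer(seed))
  class(spec) <- "PhantomSpec"
  spec
}

# arc subtending half-angle a has tortuosity a / sin(a); invert numerically
.arcHalfAngle <- function(tort) {
  if (tort <= 1 + 1e-12) return(0)
  uniroot(function(a) a / sin(a) - tort, c(1e-8, pi - 1e-6),
          tol = 1e-12)$root
}

# default centerline: planar arc in the (y, x) plane, micrometer coordinates
.defaultControlPoints <- function(spec) {
  d <- spec$volumeShape
  vs <- spec$voxelSize
  chord <- 0.62 * (d[3L] - 1) * vs * spec$axisLengthScale
  a <- .arcHalfAngle(spec$targetTortuosity)
  # integer voxel-centered axis: an exactly half-voxel-centered straight
  # tube has a two-voxel-thick medial line, degenerate for any thinning
  zc <- round((d[1L] - 1) / 2) * vs
  yc <- round((d[2L] - 1) / 2) * vs
  xc <- (d[3L] - 1) / 2 * vs
  phi <- seq(-a, a, length.out = 9L)
  if (a == 0) {
    x <- xc + seq(-chord / 2, chord / 2, length.out = 9L)
    y <- rep(yc, 9L)
  } else {
    R <- chord / (2 * sin(a))
    x <- xc + R * sin(phi)
    # bulge towards -y so the arc stays centered-ish in the volume
    y <- yc - R * (cos(phi) - cos(a)) + R * (1 - cos(a)) / 2
  }
  cbind(z = rep(zc, 9L), y = y, x = x)
}

# uniform Catmull-Rom spline through control points, then arclength-uniform
# resampling at `spacing` (same units as the points)
.catmullRom <- function(pts, nPerSegment = 40L) {
  n <- nrow(pts)
  if (n == 2L) {
    t <- seq(0, 1, length.out = 2L * nPerSegment)
    return(cbind(pts[1, 1] + t * (pts[2, 1] - pts[1, 1]),
                 pts[1, 2] + t * (pts[2, 2] - pts[1, 2]),
                 pts[1, 3] + t * (pts[2, 3] - pts[1, 3])))
  }
  ext <- rbind(2 * pts[1, ] - pts[2, ], pts, 2 * pts[n, ] - pts[n - 1, ])
  out <- list()
  for (i in seq_len(n - 1L)) {
    p0 <- ext[i, ]; p1 <- ext[i + 1, ]; p2 <- ext[i + 2, ]; p3 <- ext[i + 3, ]
    t <- seq(0, 1, length.out = nPerSegment + 1L)
    if (i < n - 1L) t <- t[-length(t)]
    t2 <- t * t; t3 <- t2 * t
    seg <- sapply(1:3, function(k) {
      0.5 * ((2 * p1[k]) + (-p0[k] + p2[k]) * t +
             (2 * p0[k] - 5 * p1[k] + 4 * p2[k] - p3[k]) * t2 +
             (-p0[k] + 3 * p1[k] - 3 * p2[k] + p3[k]) * t3)
    })
    out[[i]] <- seg
  }
  do.call(rbind, out)
}

.resamplePolyline <- function(pts, spacing) {
  steps <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(steps))
  total <- s[length(s)]
  sNew <- seq(0, total, by = spacing)
  if (sNew[length(sNew)] < total) sNew <- c(sNew, total)
  out <- sapply(1:3, function(k) approx(s, pts[, k], xout = sNew)$y)
  list(points = out, arclength = sNew, total = total)
}

#' Generate a ground-truth embryo phantom
#'
#' Builds the multichannel phantom volume (channel 1: nuclear-like body
#' intensity; channels 2/3: anterior/posterior Gaussian marker spots) and
#' the matching \linkS4class{PhantomTruth}. Identical spec + seed gives
#' bit-identical output.
#'
#' @param spec a \code{\link{phantomSpec}}
#' @return list with elements \code{volume} (\linkS4class{EmbryoVolume},
#'   3 channels) and \code{truth} (\linkS4class{PhantomTruth})
#' @examples
#' ph <- makeEmbryoPhantom(phantomSpec(volumeShape = c(24, 32, 48),
#'   radiusProfile = function(s) rep(26, length(s))))
#' ph$truth@trueTortuosity
#' @export
makeEmbryoPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  d <- spec$volumeShape
  vs <- spec$voxelSize
  ctrl <- spec$centerlineControlPoints %||% .defaultControlPoints(spec)
  dense <- .catmullRom(as.matrix(ctrl))
  rs <- .resamplePolyline(dense, spacing = 0.5 * vs)
  pts <- rs$points                       # micrometers
  sNorm <- rs$arclength / rs$total
  radius <- spec$radiusProfile(sNorm)
  if (length(radius) == 1L) radius <- rep(radius, length(sNorm))
  if (spec$thicknessAmplitude > 0)
    radius <- radius * (1 + spec$thicknessAmplitude * sin(3 * 2 * pi * sNorm))

  # bounds: tube must fit with a >= 2-voxel margin
  vox <- pts / vs + 1                    # 1-based voxel coordinates
  margin <- radius / vs + 2
  for (ax in 1:3) {
    bad <- which(vox[, ax] - margin < 1 | vox[, ax] + margin > d[ax])
    if (length(bad)) {
      # name the nearest control point
      db <- as.matrix(dist(rbind(pts[bad[1L], ], as.matrix(ctrl))))[1L, -1L]
      stop(sprintf(
        "tube exits volume bounds near control point %d (axis %d)",
        which.min(db), ax))
    }
  }

  mask <- array(FALSE, d)
  mask <- .stampSpheres(mask, vox, radius / vs)
  if (spec$notchAmplitude > 0) {
    mid <- which.min(abs(sNorm - 0.5))
    rMid <- radius[mid] / vs
    notchCenter <- vox[mid, ] + c(0, rMid, 0)
    notchRadius <- 1.5 * spec$notchAmplitude * rMid
    mask <- .carveSphere(mask, notchCenter, notchRadius)
  }

  # truth centerline at ~1 voxel spacing
  cl <- .resamplePolyline(dense, spacing = vs)
  clVox <- cl$points / vs + 1
  chord <- sqrt(sum((clVox[nrow(clVox), ] - clVox[1L, ])^2))
  pl <- sum(sqrt(rowSums(diff(clVox)^2)))
  truth <- new("PhantomTruth", mask = mask, centerline = clVox,
               anteriorPoint = clVox[1L, ], posteriorPoint = clVox[nrow(clVox), ],
               trueTortuosity = if (chord > 0) pl / chord else 1,
               trueVolume = sum(mask),
               radiusAtArclength = cbind(arclength = sNorm, radius = radius))

  nuclear <- array(0, d)
  nuclear[mask] <- spec$intensityLevel
  ant <- .stampGaussian(array(0, d), clVox[1L, ],
                        spec$anteriorMarkerSigma / vs, spec$intensityLevel)
  post <- .stampGaussian(array(0, d), clVox[nrow(clVox), ],
                         spec$posteriorMarkerSigma / vs, spec$intensityLevel)
  arr <- array(0, c(d, 3L))
  arr[, , , 1L] <- nuclear
  arr[, , , 2L] <- ant
  arr[, , , 3L] <- post
  if (spec$noiseSigma > 0)
    arr <- arr + array(rnorm(length(arr), 0, spec$noiseSigma), dim(arr))
  vol <- EmbryoVolume(arr, voxelSize = vs,
                      channelLabels = c("nuclear", "anterior", "posterior"))
  list(volume = vol, truth = truth)
}

# union of spheres along centerline samples; centers/radii in voxel units
.stampSpheres <- function(mask, centers, radii) {
  d <- dim(mask)
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]
    r <- radii[i]
    lo <- pmax(1L, floor(c0 - r))
    hi <- pmin(d, ceiling(c0 + r))
    if (any(lo > hi)) next
    zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
    dz2 <- (zi - c0[1L])^2
    dy2 <- (yi - c0[2L])^2
    dx2 <- (xi - c0[3L])^2
    inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= r * r
    mask[zi, yi, xi] <- mask[zi, yi, xi] | inside
  }
  mask
}

.carveSphere <- function(mask, center, r) {
  d <- dim(mask)
  lo <- pmax(1L, floor(center - r))
  hi <- pmin(d, ceiling(center + r))
  if (any(lo > hi)) return(mask)
  zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
  inside <- outer(outer((zi - center[1L])^2, (yi - center[2L])^2, "+"),
                  (xi - center[3L])^2, "+") <= r * r
  mask[zi, yi, xi] <- mask[zi, yi, xi] & !inside
  mask
}

.stampGaussian <- function(arr, center, sigmaVox, amplitude) {
  d <- dim(arr)
  r <- ceiling(4 * sigmaVox)
  lo <- pmax(1L, floor(center - r))
  hi <- pmin(d, ceiling(center + r))
  zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
  g <- amplitude * exp(-outer(outer((zi - center[1L])^2, (yi - center[2L])^2,
                                    "+"), (xi - center[3L])^2, "+") /
                         (2 * sigmaVox^2))
  arr[zi, yi, xi] <- arr[zi, yi, xi] + g
  arr
}

#' Specify a severity-graded phantom cohort
#'
#' Emulates a dose-response experiment: each dose level maps to shape
#' parameters (tortuosity mean/SD, thickness-nonuniformity amplitude, axis
#' length scale, notch amplitude) that change monotonically with the level
#' index, mimicking increasing BMP-inhibition severity.
#'
#' @param doseLevels ordered character labels, mildest first
#' @param nPerLevel phantoms per level
#' @param severityMap list (one entry per level) of lists with fields
#'   \code{tortuosityMean}, \code{tortuositySD}, \code{thicknessAmplitude},
#'   \code{axisLengthScale}, \code{notchAmplitude}
#' @param volumeShape,voxelSize,intensityLevel,noiseSigma passed to each
#'   \code{\link{phantomSpec}}
#' @param seed integer seed
#' @return a CohortSpec (validated list)
#' @export
cohortSpec <- function(doseLevels = c("0nM", "low", "mid", "high"),
                       nPerLevel = 5L,
                       severityMap = NULL,
                       volumeShape = c(48L, 64L, 96L),
                       voxelSize = 6.5,
                       intensityLevel = 100,
                       noiseSigma = 0,
                       seed = 1L) {
  nl <- length(doseLevels)
  if (nPerLevel < 1L) stop("nPerLevel must be >= 1")
  if (is.null(severityMap)) {
    tor <- seq(1.03, 1.45, length.out = nl)
    thick <- seq(0, 0.2, length.out = nl)
    axl <- seq(1, 0.72, length.out = nl)
    notch <- seq(0, 0.7, length.out = nl)
    severityMap <- lapply(seq_len(nl), function(i)
      list(tortuosityMean = tor[i], tortuositySD = 0.02,
           thicknessAmplitude = thick[i], axisLengthScale = axl[i],
           notchAmplitude = notch[i]))
  }
  if (length(severityMap) != nl)
    stop("severityMap needs one entry per dose level")
  getv <- function(f) vapply(severityMap, `[[`, numeric(1), f)
  if (is.unsorted(getv("tortuosityMean")) ||
      is.unsorted(getv("thicknessAmplitude")) ||
      is.unsorted(getv("notchAmplitude")) ||
      is.unsorted(rev(getv("axisLengthScale"))))
    stop("severity parameters must vary monotonically with dose level")
  spec <- list(doseLevels = as.character(doseLevels),
               nPerLevel = as.integer(nPerLevel), severityMap = severityMap,
               volumeShape = as.integer(volumeShape), voxelSize = voxelSize,
               intensityLevel = intensityLevel, noiseSigma = noiseSigma,
               seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  spec
}

#' Generate a severity-graded phantom cohort
#'
#' @param spec a \code{\link{cohortSpec}}
#' @return list of entries, each with \code{volume}, \code{truth},
#'   \code{dose} (level label) and \code{id}, in generation order
#' @examples
#' coh <- makeCohort(cohortSpec(nPerLevel = 1, volumeShape = c(32, 48, 64)))
#' length(coh)
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  out <- list()
  for (i in seq_along(spec$doseLevels)) {
    sv <- spec$severityMap[[i]]
    for (j in seq_len(spec$nPerLevel)) {
      eseed <- spec$seed + 1000L * (i - 1L) + j
      set.seed(eseed)
      tor <- max(1, rnorm(1L, sv$tortuosityMean, sv$tortuositySD))
      rBase <- max(20, rnorm(1L, 50, 2))
      pspec <- phantomSpec(
        radiusProfile = local({
          rb <- rBase
          function(s) rep(rb, length(s))
        }),
        targetTortuosity = tor,
        thicknessAmplitude = sv$thicknessAmplitude,
        axisLengthScale = sv$axisLengthScale,
        notchAmplitude = sv$notchAmplitude,
        volumeShape = spec$volumeShape, voxelSize = spec$voxelSize,
        intensityLevel = spec$intensityLevel, noiseSigma = spec$noiseSigma,
        seed = eseed)
      ph <- makeEmbryoPhantom(pspec)
      out[[length(out) + 1L]] <- list(
        volume = ph$volume, truth = ph$truth, dose = spec$doseLevels[i],
        id = sprintf("L%d_%s_e%02d", i, spec$doseLevels[i], j))
    }
  }
  out
}

#' Combine single-embryo phantoms into one multi-embryo acquisition
#'
#' Places up to five phantom volumes side by side along the y axis (the OPT
#' field of view holds several embryos per acquisition), with background
#' padding between them, and offsets the truths accordingly.
#'
#' @param phantoms list of \code{makeEmbryoPhantom} outputs
#' @param gap gap between embryos in voxels
#' @return list with \code{volume} (multichannel \linkS4class{EmbryoVolume})
#'   and \code{truths} (list of \linkS4class{PhantomTruth} with shifted
#'   coordinates)
#' @export
makeAcquisition <- function(phantoms, gap = 4L) {
  stopifnot(length(phantoms) >= 1L)
  dims <- sapply(phantoms, function(p) dim(maskArray(p$truth)))
  vs <- voxelSize(phantoms[[1L]]$volume)
  nch <- nChannels(phantoms[[1L]]$volume)
  d <- c(max(dims[1L, ]), sum(dims[2L, ]) + gap * (length(phantoms) - 1L),
         max(dims[3L, ]))
  arr <- array(0, c(d, nch))
  truths <- list()
  yOff <- 0L
  for (p in phantoms) {
    dp <- dim(maskArray(p$truth))
    zi <- seq_len(dp[1L]); yi <- yOff + seq_len(dp[2L]); xi <- seq_len(dp[3L])
    arr[zi, yi, xi, ] <- arr[zi, yi, xi, ] + volumeData(p$volume)
    tr <- p$truth
    shifted <- new("PhantomTruth",
                   mask = {
                     m <- array(FALSE, d)
                     m[zi, yi, xi] <- maskArray(tr)
                     m
                   },
                   centerline = sweep(tr@centerline, 2, c(0, yOff, 0), "+"),
                   anteriorPoint = tr@anteriorPoint + c(0, yOff, 0),
                   posteriorPoint = tr@posteriorPoint + c(0, yOff, 0),
                   trueTortuosity = tr@trueTortuosity,
                   trueVolume = tr@trueVolume,
                   radiusAtArclength = tr@radiusAtArclength)
    truths[[length(truths) + 1L]] <- shifted
    yOff <- yOff + dp[2L] + gap
  }
  list(volume = EmbryoVolume(arr, vs, phantoms[[1L]]$volume@channelLabels),
       truths = truths)
}

#' Forward-project a volume to an OPT sinogram
#'
#' Parallel-beam line-integral projections of a single-channel volume at
#' equally spaced angles over 360 degrees, about the z axis. A miscentred
#' rotation axis is simulated by shifting the detector columns by
#' \code{axisOffsetPx} after projection (positive = object appears shifted
#' towards higher column indices). Noiseless, zero-offset projections
#' conserve mass: each angle's projection sum equals the volume's total
#' intensity up to interpolation error.
#'
#' @param volume single-channel \linkS4class{EmbryoVolume} (isotropic)
#' @param nAngles number of projection angles (>= 2); 400 by default, the
#'   standard OPT acquisition
#' @param axisOffsetPx simulated rotation-axis offset in detector pixels
#' @param noiseSigma additive Gaussian detector noise SD
#' @param seed integer seed for the noise
#' @return a \linkS4class{ProjectionSet}
#' @examples
#' ph <- makeEmbryoPhantom(phantomSpec(volumeShape = c(16, 24, 32),
#'   radiusProfile = function(s) rep(20, length(s))))
#' ps <- forwardProject(channelVolume(ph$volume, 1), nAngles = 16)
#' @export
forwardProject <- function(volume, nAngles = 400L, axisOffsetPx = 0,
                           noiseSigma = 0, seed = 1L) {
  if (is(volume, "EmbryoVolume")) {
    if (nChannels(volume) != 1L)
      stop("forwardProject expects a single-channel volume")
    arr <- volumeData(volume)
    vs <- voxelSize(volume)
    lab <- volume@channelLabels[1L]
  } else {
    arr <- as.array(volume)
    vs <- 6.5
    lab <- "channel1"
  }
  if (nAngles < 2L) stop("need at least 2 angles")
  d <- dim(arr)
  ndet <- 2L * ceiling(sqrt(d[2L]^2 + d[3L]^2) / 2) + 1L
  angles <- (seq_len(nAngles) - 1L) * 360 / nAngles
  proj <- .forward_project_cpp(arr, d, angles * pi / 180, as.integer(ndet))
  if (abs(axisOffsetPx) > 0)
    proj <- .shiftColumns(proj, axisOffsetPx)
  if (noiseSigma > 0) {
    set.seed(seed)
    proj <- proj + array(rnorm(length(proj), 0, noiseSigma), dim(proj))
  }
  ProjectionSet(proj, angles, channelLabel = lab, pixelSize = vs)
}

# translate detector columns of a (rows, cols, angles) stack by `by` pixels
# (content moves towards higher columns for positive `by`); linear
# interpolation, edge replication
.shiftColumns <- function(proj, by) {
  d <- dim(proj)
  n <- d[2L]
  pos <- pmin(pmax(seq_len(n) - by, 1), n)
  i0 <- pmin(floor(pos), n - 1L)
  f <- pos - i0
  W <- matrix(0, n, n)
  W[cbind(seq_len(n), i0)] <- 1 - f
  W[cbind(seq_len(n), i0 + 1L)] <- W[cbind(seq_len(n), i0 + 1L)] + f
  .applyAlongAxis2(proj, 2L, W)
}

#' Synthesize a confocal-like nuclear gradient stack
#'
#' Places well-separated Gaussian-blob nuclei in a z-stack; each nucleus'
#' center intensity equals \code{decay(margin distance)}, where the margin
#' is the y = 0 plane (first row) and distances are measured along y in
#' micrometers. Emulates margin-profiling confocal acquisitions of
#' nuclear-stained embryos.
#'
#' @param nNuclei number of nuclei (>= 0)
#' @param decay function of distance-from-margin (um) giving center
#'   intensity
#' @param noiseSigma additive Gaussian noise SD
#' @param seed integer seed
#' @param stackShape stack dimensions (z, y, x) in voxels
#' @param voxelSize isotropic voxel size (um)
#' @param nucleusSigma Gaussian nucleus radius parameter (um)
#' @return list with \code{stack} (\linkS4class{EmbryoVolume}) and
#'   \code{table} (data.frame: id, z, y, x voxel coordinates, intensity,
#'   margin_distance in um)
#' @examples
#' g <- makeNuclearGradientStack(10, seed = 3)
#' nrow(g$table)
#' @export
makeNuclearGradientStack <- function(nNuclei = 50L,
                                     decay = function(y) exp(-y / 40),
                                     noiseSigma = 0, seed = 1L,
                                     stackShape = c(30L, 110L, 110L),
                                     voxelSize = 2,
                                     nucleusSigma = 3) {
  if (nNuclei < 0L) stop("nNuclei must be >= 0")
  set.seed(seed)
  d <- as.integer(stackShape)
  arr <- array(0, d)
  tab <- data.frame(id = integer(0), z = numeric(0), y = numeric(0),
                    x = numeric(0), intensity = numeric(0),
                    margin_distance = numeric(0))
  if (nNuclei == 0L)
    return(list(stack = EmbryoVolume(arr, voxelSize, "nuclear"), table = tab))
  sigVox <- nucleusSigma / voxelSize
  minSep <- 2 * (4 * sigVox)             # two nuclear diameters (voxels)
  marginVox <- ceiling(4 * sigVox) + 1
  if (d[1L] - 2 * marginVox + 1 < 1 || d[3L] - 2 * marginVox + 1 < 1 ||
      d[2L] - marginVox < 1)
    stop(sprintf("cannot place %d nuclei with separation %.1f voxels",
                 nNuclei, minSep))
  centers <- matrix(NA_real_, nNuclei, 3L)
  placed <- 0L
  tries <- 0L
  maxTries <- 1000L * nNuclei
  while (placed < nNuclei) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop(sprintf("cannot place %d nuclei with separation %.1f voxels",
                   nNuclei, minSep))
    cand <- c(runif(1, marginVox, d[1L] - marginVox + 1),
              runif(1, 1, d[2L] - marginVox + 1),
              runif(1, marginVox, d[3L] - marginVox + 1))
    if (placed > 0L) {
      dd <- sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE], 2,
                               cand)^2))
      if (min(dd) < minSep) next
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  marginDist <- pmax(0, (centers[, 2L] - 1) * voxelSize)
  intensity <- decay(marginDist)
  for (i in seq_len(nNuclei))
    arr <- .stampGaussian(arr, centers[i, ], sigVox, intensity[i])
  if (noiseSigma > 0)
    arr <- arr + array(rnorm(length(arr), 0, noiseSigma), d)
  tab <- data.frame(id = seq_len(nNuclei), z = centers[, 1L],
                    y = centers[, 2L], x = centers[, 3L],
                    intensity = intensity, margin_distance = marginDist)
  list(stack = EmbryoVolume(arr, voxelSize, "nuclear"), table = tab)
}
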