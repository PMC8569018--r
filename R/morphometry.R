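#' Detect anterior/posterior landmarks from marker channels
#'
#' Each landmark is the maximum-brightness voxel of its marker channel
#' restricted to a 5-voxel dilation of the embryo mask (head and tail
#' expression markers are bright spots at the body ends). Ties are broken
#' by the lowest linear index of the (z, y, x) array.
#'
#' @param anteriorChannel,posteriorChannel single-channel
#'   \linkS4class{EmbryoVolume} or 3D arrays, co-registered with the mask
#' @param mask \linkS4class{EmbryoMask}
#' @param dilationVoxels search radius around the mask (default 5)
#' @return a \linkS4class{Landmarks}
#' @export
detectLandmarks <- function(anteriorChannel, posteriorChannel, mask,
                            dilationVoxels = 5) {
  m <- maskArray(mask)
  region <- .edt_cpp(m, dim(m)) <= dilationVoxels
  pick <- function(ch, label) {
    arr <- if (is(ch, "EmbryoVolume")) volumeData(ch) else as.array(ch)
    if (!all(dim(arr) == dim(m))) stop("channel not aligned with mask")
    vals <- ifelse(region, arr, -Inf)
    if (max(vals) <= 0) stop(sprintf("landmark channel empty (%s)", label))
    as.numeric(arrayInd(which.max(vals), dim(m)))
  }
  Landmarks(anterior = pick(anteriorChannel, "anterior"),
            posterior = pick(posteriorChannel, "posterior"))
}

#' Compute the pruned centerline skeleton of an embryo mask
#'
#' The mask is thinned to a curve skeleton by distance-ordered homotopic
#' thinning (voxels are deleted in order of increasing distance to the
#' background whenever deletion preserves topology and the voxel is not a
#' curve endpoint). Pruning keeps the geodesic path between the two
#' skeleton voxels nearest the anterior and posterior landmarks; the path
#' is reported anterior first.
#'
#' @param mask \linkS4class{EmbryoMask} (single connected component)
#' @param landmarks \linkS4class{Landmarks}
#' @return an \linkS4class{EmbryoSkeleton}
#' @export
computeSkeleton <- function(mask, landmarks) {
  m <- maskArray(mask)
  d <- dim(m)
  vs <- voxelSize(mask)
  depth <- .edt_cpp(!m, d)              # distance to background
  if (max(depth[m]) <= 1)
    stop("mask thinner than 2 voxels everywhere")
  raw <- .thin3d_cpp(m, depth, d)
  skVox <- .maskCoords(raw)
  if (nrow(skVox) == 0L) stop("thinning produced an empty skeleton")

  nearestSk <- function(p) {
    dd <- (skVox[, 1L] - p[1L])^2 + (skVox[, 2L] - p[2L])^2 +
      (skVox[, 3L] - p[3L])^2
    skVox[which.min(dd), ]
  }
  a <- nearestSk(landmarks@anterior)
  b <- nearestSk(landmarks@posterior)

  g <- .geodesic_cpp(raw, d, as.integer(.linearIndex0(a, d)))
  path <- .tracePath(g$pred, a, b, d)
  if (is.null(path))
    stop("skeleton disconnected between the landmark anchors")
  # measure length on a lightly smoothed polyline: the raw 26-connected
  # voxel chain overestimates curve length by staircase wiggle
  steps <- if (nrow(path) >= 2L)
    sum(sqrt(rowSums(diff(.smoothPolyline(path, 5L))^2))) else 0
  new("EmbryoSkeleton", path = path,
      endpoints = rbind(anterior = path[1L, ], posterior = path[nrow(path), ]),
      pathLength = steps * vs, rawSkeleton = raw, voxelSize = vs)
}

# centered moving average of polyline coordinates; endpoints kept fixed
.smoothPolyline <- function(pts, window = 5L) {
  n <- nrow(pts)
  if (n <= 2L || window <= 1L) return(pts)
  half <- window %/% 2L
  out <- pts
  for (i in 2:(n - 1L)) {
    w <- min(half, i - 1L, n - i)
    out[i, ] <- colMeans(pts[(i - w):(i + w), , drop = FALSE])
  }
  out
}

# walk predecessors from `to` back to the Dijkstra source `from`
.tracePath <- function(pred, from, to, dims) {
  idx <- .linearIndex0(to, dims)
  fromIdx <- .linearIndex0(from, dims)
  rev_path <- idx
  while (idx != fromIdx) {
    p <- pred[idx + 1L]
    if (is.na(p)) return(NULL)
    idx <- p
    rev_path <- c(rev_path, idx)
  }
  coords <- arrayInd(rev(rev_path) + 1L, dims)
  colnames(coords) <- c("z", "y", "x")
  coords
}

#' Principal axis lengths of a mask
#'
#' Eigenvalues lambda1 >= lambda2 >= lambda3 of the covariance of the mask
#' voxel coordinates give the full axis lengths of the intensity-equivalent
#' ellipsoid, L_i = 4 sqrt(lambda_i) x voxel size. Only the ratios
#' L2/L1 etc. are scale-convention-free and enter the morphospace.
#'
#' @param mask \linkS4class{EmbryoMask} with >= 10 voxels
#' @return named numeric (L1, L2, L3) in micrometers
#' @export
principalAxisLengths <- function(mask) {
  m <- maskArray(mask)
  coords <- .maskCoords(m)
  if (nrow(coords) < 10L) stop("degenerate mask: fewer than 10 voxels")
  ev <- eigen(cov(coords), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  L <- 4 * sqrt(ev) * voxelSize(mask)
  c(L1 = L[1L], L2 = L[2L], L3 = L[3L])
}

#' Solidity of a mask
#'
#' Mask voxel count divided by the voxel count of its 3D convex hull;
#' 1 for convex bodies, lower for notched or bent ones (non-homogeneities
#' of the axis).
#'
#' @param mask \linkS4class{EmbryoMask} with >= 10 voxels
#' @return solidity in (0, 1]
#' @export
maskSolidity <- function(mask) {
  m <- maskArray(mask)
  nv <- sum(m)
  if (nv < 10L) stop("degenerate mask: fewer than 10 voxels")
  pts <- .hullCandidates(m)
  h <- .hull3d_cpp(pts)
  min(1, nv / h$count)
}

# extreme-point candidates: per-line min/max voxels in each axis direction
.hullCandidates <- function(m) {
  co <- .maskCoords(m)
  keyYX <- co[, 2L] + 1e5 * co[, 3L]
  keyZX <- co[, 1L] + 1e5 * co[, 3L]
  keyZY <- co[, 1L] + 1e5 * co[, 2L]
  sel <- c(
    vapply(split(seq_len(nrow(co)), keyYX),
           function(i) c(i[which.min(co[i, 1L])], i[which.max(co[i, 1L])]),
           integer(2L)),
    vapply(split(seq_len(nrow(co)), keyZX),
           function(i) c(i[which.min(co[i, 2L])], i[which.max(co[i, 2L])]),
           integer(2L)),
    vapply(split(seq_len(nrow(co)), keyZY),
           function(i) c(i[which.min(co[i, 3L])], i[which.max(co[i, 3L])]),
           integer(2L)))
  unique(co[unique(as.integer(sel)), , drop = FALSE]) * 1.0
}

#' Tortuosity of a skeleton path
#'
#' Centerline path length divided by the Euclidean distance between its
#' endpoints; 1 for a straight body, larger for bent ones.
#'
#' @param skeleton an \linkS4class{EmbryoSkeleton}
#' @return tortuosity >= 1
#' @export
tortuosity <- function(skeleton) {
  stopifnot(is(skeleton, "EmbryoSkeleton"))
  ep <- skeleton@endpoints
  chord <- sqrt(sum((ep[2L, ] - ep[1L, ])^2)) * skeleton@voxelSize
  if (chord <= 0) stop("closed or degenerate path")
  max(1, skeleton@pathLength / chord)
}

#' Skeleton-to-surface distance statistics
#'
#' For every skeleton path voxel, the Euclidean distance to the nearest
#' surface voxel (mask voxels 6-adjacent to background) is computed via a
#' distance transform seeded at the surface; the mean (um), variation
#' (SD/mean), skewness and excess kurtosis of that distance set describe
#' embryo thickness and its non-uniformity.
#'
#' @param mask \linkS4class{EmbryoMask}
#' @param skeleton \linkS4class{EmbryoSkeleton} computed from the mask
#' @return named numeric: mean, variation, skewness, kurtosis
#' @export
skeletonSurfaceStats <- function(mask, skeleton) {
  path <- skeletonPath(skeleton)
  if (nrow(path) < 3L) stop("skeleton path shorter than 3 voxels")
  m <- maskArray(mask)
  surf <- .surfaceVoxels(m)
  sd2 <- .edt_cpp(surf, dim(m))
  dists <- sd2[path]
  st <- sampleMoments(dists)
  st["mean"] <- st["mean"] * voxelSize(mask)
  st
}

#' Anterior/posterior distance-map correlation (AP index)
#'
#' Two geodesic distance maps over the mask (26-neighbor steps weighted by
#' Euclidean step length) are seeded at the anterior and posterior
#' landmarks; the AP index is the Pearson correlation of the two maps over
#' all mask voxels. A straight elongated body gives values near -1
#' (d_A + d_P is constant along the axis); shortened or folded bodies move
#' the index towards 0 and beyond.
#'
#' @param mask \linkS4class{EmbryoMask} (connected)
#' @param landmarks \linkS4class{Landmarks}; landmarks at most 3 voxels
#'   outside the mask are snapped to the nearest mask voxel
#' @return AP index in [-1, 1]
#' @export
apIndex <- function(mask, landmarks) {
  m <- maskArray(mask)
  d <- dim(m)
  snap <- function(p, what) {
    pr <- pmin(pmax(round(p), 1L), d)
    if (m[pr[1L], pr[2L], pr[3L]]) return(pr)
    co <- .maskCoords(m)
    dd <- sqrt((co[, 1L] - p[1L])^2 + (co[, 2L] - p[2L])^2 +
                 (co[, 3L] - p[3L])^2)
    i <- which.min(dd)
    if (dd[i] > 3) stop(sprintf("%s landmark more than 3 voxels outside mask",
                                what))
    co[i, ]
  }
  a <- snap(landmarks@anterior, "anterior")
  b <- snap(landmarks@posterior, "posterior")
  dA <- .geodesic_cpp(m, d, as.integer(.linearIndex0(a, d)))$dist[m]
  dB <- .geodesic_cpp(m, d, as.integer(.linearIndex0(b, d)))$dist[m]
  if (anyNA(dA) || anyNA(dB)) stop("mask disconnected: unreachable voxels")
  if (sd(dA) == 0 || sd(dB) == 0) return(1)
  cor(dA, dB)
}

#' Mask intensity statistics
#'
#' Statistics of the source intensity inside the mask after subtracting the
#' in-mask minimum: mean, variation (SD/mean), skewness, excess kurtosis.
#' For constant in-mask intensity the mean is 0 and the scale-free moments
#' are undefined (NA).
#'
#' @param volume single-channel \linkS4class{EmbryoVolume} or 3D array
#' @param mask \linkS4class{EmbryoMask}
#' @return named numeric: mean, variation, skewness, kurtosis
#' @export
intensityStats <- function(volume, mask) {
  arr <- if (is(volume, "EmbryoVolume")) volumeData(volume) else as.array(volume)
  m <- maskArray(mask)
  if (!all(dim(arr) == dim(m))) stop("volume not aligned with mask")
  vals <- arr[m] - min(arr[m])
  sampleMoments(vals)
}
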