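#' Two-scale segmentation parameters
#'
#' Parameters of the normalized two-scale difference segmentation of the
#' nuclear channel. Three Gaussian smoothings of the intensity volume U at
#' increasing scales sigma1 < sigma2 < sigma3 form two normalized
#' difference images
#' \deqn{u_1 = (U_{\sigma 1} - U_{\sigma 2}) / U_{\sigma 2}}
#' \deqn{u_2 = (U_{\sigma 2} - U_{\sigma 3}) / U_{\sigma 3}}
#' which are blended with weight w and thresholded at t:
#' \deqn{w u_1 + (1 - w) u_2 > t.}
#' Denominators are guarded below by \code{epsilon} (the source intensity
#' is zero in true background). Defaults correspond to about 2, 6 and 18
#' voxels at 6.5 um/voxel and are meant to be held constant across the
#' samples of a study.
#'
#' @param sigma1,sigma2,sigma3 Gaussian scales in micrometers, increasing
#' @param weight blending weight w in [0, 1]
#' @param threshold binarization threshold t (dimensionless)
#' @param minSize,maxSize size criterion for embryo instances (voxels)
#' @param epsilon denominator guard; NULL = 1e-6 x the volume maximum
#' @return a SegmentationParams list
#' @export
segmentationParams <- function(sigma1 = 13, sigma2 = 39, sigma3 = 117,
                               weight = 0.8, threshold = 0.8,
                               minSize = 1000, maxSize = 1e7,
                               epsilon = NULL) {
  if (!(sigma1 < sigma2 && sigma2 < sigma3))
    stop("need sigma1 < sigma2 < sigma3")
  if (weight < 0 || weight > 1) stop("weight must be in [0, 1]")
  if (minSize > maxSize) stop("minSize must be <= maxSize")
  if (!is.null(epsilon) && epsilon <= 0) stop("epsilon must be positive")
  structure(list(sigma1 = sigma1, sigma2 = sigma2, sigma3 = sigma3,
                 weight = weight, threshold = threshold,
                 minSize = minSize, maxSize = maxSize, epsilon = epsilon),
            class = "SegmentationParams")
}

#' Normalized two-scale difference images
#'
#' Computes the two scale-sensitive difference images u1 and u2 (see
#' \code{\link{segmentationParams}}) from a nonnegative single-channel
#' volume. The normalization makes u1/u2 invariant to global intensity
#' scaling.
#'
#' @param volume single-channel \linkS4class{EmbryoVolume} (isotropic)
#' @param params \code{\link{segmentationParams}}
#' @return list with \code{u1} and \code{u2} (3D arrays) and the
#'   \code{epsilon} actually used
#' @export
scaleDifferenceImages <- function(volume, params = segmentationParams()) {
  arr <- if (is(volume, "EmbryoVolume")) volumeData(volume) else as.array(volume)
  vs <- if (is(volume, "EmbryoVolume")) voxelSize(volume) else 6.5
  if (length(dim(arr)) != 3L)
    stop("expected a single-channel 3D volume")
  if (min(arr) < 0) stop("volume must be nonnegative")
  eps <- params$epsilon %||% (1e-6 * max(arr))
  if (eps <= 0) eps <- 1e-12
  U1 <- gaussianSmooth3d(arr, params$sigma1 / vs)
  U2 <- gaussianSmooth3d(arr, params$sigma2 / vs)
  U3 <- gaussianSmooth3d(arr, params$sigma3 / vs)
  list(u1 = (U1 - U2) / pmax(U2, eps),
       u2 = (U2 - U3) / pmax(U3, eps),
       epsilon = eps)
}

#' Segment embryo bodies from the nuclear channel
#'
#' Thresholds the weighted two-scale image, labels connected components
#' (26-connectivity) and returns the instances passing the size criterion,
#' sorted by descending voxel count (instance ids 1..k). Marker channels
#' are never used for segmentation.
#'
#' @param volume the nuclear-channel \linkS4class{EmbryoVolume}
#' @param params \code{\link{segmentationParams}}
#' @return list of \linkS4class{EmbryoMask}; empty (with a warning) when
#'   no component passes the size criterion
#' @examples
#' ph <- makeEmbryoPhantom(phantomSpec(volumeShape = c(24, 32, 48),
#'   radiusProfile = function(s) rep(26, length(s))))
#' masks <- segmentEmbryos(channelVolume(ph$volume, "nuclear"),
#'                         segmentationParams(minSize = 100))
#' @export
segmentEmbryos <- function(volume, params = segmentationParams()) {
  vs <- if (is(volume, "EmbryoVolume")) voxelSize(volume) else 6.5
  u <- scaleDifferenceImages(volume, params)
  synth <- params$weight * u$u1 + (1 - params$weight) * u$u2
  binary <- synth > params$threshold
  labels <- .label3d_cpp(binary, dim(binary))
  if (max(labels) == 0L) {
    warning("no component passes the size criterion")
    return(list())
  }
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= params$minSize & sizes <= params$maxSize)
  if (length(keep) == 0L) {
    warning("no component passes the size criterion")
    return(list())
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  lapply(seq_along(keep), function(i) {
    EmbryoMask(labels == keep[i], instanceId = i, voxelSize = vs)
  })
}
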