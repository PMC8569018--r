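#' EmbryoVolume: a 3D (optionally multichannel) intensity grid
#'
#' Container for reconstructed or synthetic image volumes with isotropic
#' voxels. The data array is ordered (z, y, x) for a single channel or
#' (z, y, x, channel) for multichannel volumes.
#'
#' @slot data numeric array, 3D or 4D
#' @slot voxelSize isotropic voxel edge length in micrometers
#' @slot channelLabels one label per channel
#' @export
setClass("EmbryoVolume",
  representation(data = "array", voxelSize = "numeric",
                 channelLabels = "character"),
  validity = function(object) {
    nd <- length(dim(object@data))
    if (!nd %in% c(3L, 4L))
      return("data must be a 3D (z,y,x) or 4D (z,y,x,channel) array")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
      return("voxelSize must be a single positive number")
    nch <- if (nd == 4L) dim(object@data)[4L] else 1L
    if (length(object@channelLabels) != nch)
      return("need one channelLabel per channel")
    TRUE
  })

#' Construct an EmbryoVolume
#'
#' @param data 3D (z,y,x) or 4D (z,y,x,channel) numeric array
#' @param voxelSize isotropic voxel size in micrometers
#' @param channelLabels character vector of channel names
#' @return an \linkS4class{EmbryoVolume}
#' @examples
#' v <- EmbryoVolume(array(0, c(4, 5, 6)), voxelSize = 6.5)
#' dim(volumeData(v))
#' @export
EmbryoVolume <- function(data, voxelSize = 6.5, channelLabels = NULL) {
  data <- as.array(data)
  nd <- length(dim(data))
  nch <- if (nd == 4L) dim(data)[4L] else 1L
  if (is.null(channelLabels))
    channelLabels <- if (nch == 1L) "channel1" else paste0("channel", seq_len(nch))
  new("EmbryoVolume", data = data, voxelSize = as.numeric(voxelSize),
      channelLabels = as.character(channelLabels))
}

#' ProjectionSet: an angular series of 2D projection images
#'
#' The sinogram stack for one channel: one detector image per rotation
#' angle, angles equally spaced over 360 degrees. Images are stored as an
#' array (detector row, detector column, angle); detector rows correspond
#' to z, columns to the lateral coordinate perpendicular to the rotation
#' axis.
#'
#' @slot images numeric array (rows, columns, n_angles)
#' @slot angles projection angles in degrees
#' @slot channelLabel channel name
#' @slot pixelSize detector pixel size in micrometers
#' @slot appliedShift total axis-shift correction already applied (px)
#' @export
setClass("ProjectionSet",
  representation(images = "array", angles = "numeric",
                 channelLabel = "character", pixelSize = "numeric",
                 appliedShift = "numeric"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 3L) return("images must be a 3D array (rows, cols, angles)")
    if (d[3L] != length(object@angles))
      return("one image per angle required")
    if (length(object@angles) >= 2L) {
      sp <- diff(object@angles)
      if (any(abs(sp - sp[1L]) > 1e-6))
        return("angles must be uniformly spaced (within 1e-6 degrees)")
    }
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
  })

#' Construct a ProjectionSet
#'
#' @param images array (detector rows, detector columns, n_angles)
#' @param angles projection angles in degrees, equally spaced over 360
#' @param channelLabel channel name
#' @param pixelSize detector pixel size (micrometers)
#' @param appliedShift axis correction already applied, in pixels
#' @return a \linkS4class{ProjectionSet}
#' @export
ProjectionSet <- function(images, angles, channelLabel = "channel1",
                          pixelSize = 6.5, appliedShift = 0) {
  new("ProjectionSet", images = as.array(images), angles = as.numeric(angles),
      channelLabel = channelLabel, pixelSize = as.numeric(pixelSize),
      appliedShift = as.numeric(appliedShift))
}

#' EmbryoMask: one segmented embryo instance
#'
#' @slot mask logical 3D array aligned with the source volume
#' @slot instanceId integer id (1 = largest instance)
#' @slot voxelCount number of mask voxels
#' @slot voxelSize voxel size in micrometers
#' @export
setClass("EmbryoMask",
  representation(mask = "array", instanceId = "integer",
                 voxelCount = "integer", voxelSize = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3L) return("mask must be 3D")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (object@voxelCount != sum(object@mask))
      return("voxelCount does not match mask")
    if (object@voxelSize <= 0) return("voxelSize must be positive")
    TRUE
  })

#' Construct an EmbryoMask
#'
#' @param mask logical 3D array
#' @param instanceId integer instance id
#' @param voxelSize voxel size (micrometers)
#' @return an \linkS4class{EmbryoMask}
#' @export
EmbryoMask <- function(mask, instanceId = 1L, voxelSize = 6.5) {
  mask <- array(as.logical(mask), dim(mask))
  new("EmbryoMask", mask = mask, instanceId = as.integer(instanceId),
      voxelCount = as.integer(sum(mask)), voxelSize = as.numeric(voxelSize))
}

#' EmbryoSkeleton: pruned centerline of an embryo mask
#'
#' @slot path ordered matrix of voxel coordinates (rows = points; z, y, x)
#' @slot endpoints 2 x 3 matrix, anterior then posterior end
#' @slot pathLength centerline length in micrometers
#' @slot rawSkeleton logical 3D array, unpruned skeleton
#' @slot voxelSize voxel size in micrometers
#' @export
setClass("EmbryoSkeleton",
  representation(path = "matrix", endpoints = "matrix", pathLength = "numeric",
                 rawSkeleton = "array", voxelSize = "numeric"),
  validity = function(object) {
    if (ncol(object@path) != 3L) return("path must have 3 columns (z,y,x)")
    if (nrow(object@path) >= 2L) {
      steps <- sqrt(rowSums(diff(object@path)^2))
      if (any(steps > sqrt(3) + 1e-9))
        return("path must be 26-connected (steps within sqrt(3) voxels)")
      chord <- sqrt(sum((object@path[nrow(object@path), ] - object@path[1L, ])^2))
      if (object@pathLength < chord * object@voxelSize - 1e-6)
        return("pathLength cannot be shorter than the endpoint chord")
    }
    TRUE
  })

#' Landmarks: anterior and posterior anchor points
#'
#' @slot anterior voxel coordinate (z, y, x)
#' @slot posterior voxel coordinate (z, y, x)
#' @slot sourceChannels labels of the channels the landmarks came from
#' @export
setClass("Landmarks",
  representation(anterior = "numeric", posterior = "numeric",
                 sourceChannels = "character"),
  validity = function(object) {
    if (length(object@anterior) != 3L || length(object@posterior) != 3L)
      return("landmark coordinates must be length-3 (z,y,x)")
    TRUE
  })

#' Construct Landmarks
#'
#' @param anterior voxel coordinate (z,y,x) of the anterior anchor
#' @param posterior voxel coordinate (z,y,x) of the posterior anchor
#' @param sourceChannels channel labels the anchors were detected in
#' @return a \linkS4class{Landmarks}
#' @export
Landmarks <- function(anterior, posterior,
                      sourceChannels = c("anterior", "posterior")) {
  new("Landmarks", anterior = as.numeric(anterior),
      posterior = as.numeric(posterior),
      sourceChannels = as.character(sourceChannels))
}

#' PhantomTruth: ground truth for a synthetic embryo phantom
#'
#' @slot mask logical 3D array, true embryo body
#' @slot centerline matrix of centerline points (z, y, x voxel coordinates)
#' @slot anteriorPoint,posteriorPoint centerline endpoints (z, y, x)
#' @slot trueTortuosity centerline path length / endpoint chord
#' @slot trueVolume mask voxel count
#' @slot radiusAtArclength two-column matrix: normalized arclength, radius (um)
#' @export
setClass("PhantomTruth",
  representation(mask = "array", centerline = "matrix",
                 anteriorPoint = "numeric", posteriorPoint = "numeric",
                 trueTortuosity = "numeric", trueVolume = "numeric",
                 radiusAtArclength = "matrix"),
  validity = function(object) {
    if (object@trueTortuosity < 1 - 1e-9) return("tortuosity must be >= 1")
    TRUE
  })

#' MorphospaceModel: scaling + PCA model of a descriptor table
#'
#' @slot featureNames descriptor columns entering the model
#' @slot featureMeans,featureScales per-feature centering/scaling constants
#' @slot loadings feature x component rotation matrix (orthonormal columns)
#' @slot varianceExplained percentage of variance per component (sums to 100)
#' @slot scores embryo x component score matrix
#' @slot contributions feature x component variable contributions (percent,
#'   each column sums to 100)
#' @slot scaledData the z-scored feature matrix the model was fitted on
#' @slot embryoIds row identifiers
#' @slot groupLabels group label per embryo (may be NA)
#' @export
setClass("MorphospaceModel",
  representation(featureNames = "character", featureMeans = "numeric",
                 featureScales = "numeric", loadings = "matrix",
                 varianceExplained = "numeric", scores = "matrix",
                 contributions = "matrix", scaledData = "matrix",
                 embryoIds = "character", groupLabels = "character"),
  validity = function(object) {
    if (abs(sum(object@varianceExplained) - 100) > 1e-6)
      return("varianceExplained must sum to 100")
    if (any(diff(object@varianceExplained) > 1e-9))
      return("varianceExplained must be non-increasing")
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(ncol(object@loadings)))) > 1e-8)
      return("loadings columns must be orthonormal")
    TRUE
  })

#' ClusterAssignment: severity clusters of embryos in a morphospace
#'
#' @slot embryoIds embryo identifiers
#' @slot cluster integer cluster id per embryo, 1..k ordered by severity
#'   (ascending mean PC1)
#' @slot method one of hierarchical, kmeans, kmedoids
#' @slot k number of clusters
#' @slot meta linkage / seed metadata
#' @export
setClass("ClusterAssignment",
  representation(embryoIds = "character", cluster = "integer",
                 method = "character", k = "integer", meta = "list"),
  validity = function(object) {
    if (length(object@cluster) != length(object@embryoIds))
      return("one cluster per embryo required")
    if (!all(sort(unique(object@cluster)) == seq_len(max(object@cluster))))
      return("cluster ids must be contiguous 1..k")
    TRUE
  })

#' GradientProfile: fitted intensity-versus-margin-distance curves
#'
#' @slot embryoIds one id per embryo curve
#' @slot grid common margin-distance grid (micrometers, strictly increasing)
#' @slot curves embryo x grid matrix of fitted intensities
#' @slot mean,sem group aggregate per grid point
#' @export
setClass("GradientProfile",
  representation(embryoIds = "character", grid = "numeric",
                 curves = "matrix", mean = "numeric", sem = "numeric"),
  validity = function(object) {
    if (any(diff(object@grid) <= 0)) return("grid must be strictly increasing")
    if (any(object@sem < 0, na.rm = TRUE)) return("SEM must be non-negative")
    TRUE
  })
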