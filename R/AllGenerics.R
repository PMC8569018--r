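#' Accessors for embryomorph classes
#'
#' Small accessor generics: \code{volumeData} returns the raw intensity
#' array, \code{voxelSize} the isotropic voxel size in micrometers,
#' \code{maskArray} the logical mask, \code{skeletonPath} the ordered
#' centerline coordinates, \code{pathLength} its length in micrometers,
#' \code{scores}/\code{loadings}/\code{varianceExplained}/
#' \code{contributions} the PCA model components and
#' \code{clusterLabels} the per-embryo severity clusters.
#'
#' @param object an embryomorph object
#' @return the slot value (see details per class)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("skeletonPath", function(object) standardGeneric("skeletonPath"))
#' @rdname accessors
#' @export
setGeneric("pathLength", function(object) standardGeneric("pathLength"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("modelLoadings", function(object) standardGeneric("modelLoadings"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setGeneric("contributions", function(object) standardGeneric("contributions"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("channelVolume",
           function(object, channel) standardGeneric("channelVolume"))

#' @rdname accessors
#' @export
setMethod("volumeData", "EmbryoVolume", function(object) object@data)
#' @rdname accessors
#' @export
setMethod("voxelSize", "EmbryoVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("voxelSize", "EmbryoMask", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("maskArray", "EmbryoMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskArray", "PhantomTruth", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("skeletonPath", "EmbryoSkeleton", function(object) object@path)
#' @rdname accessors
#' @export
setMethod("pathLength", "EmbryoSkeleton", function(object) object@pathLength)
#' @rdname accessors
#' @export
setMethod("scores", "MorphospaceModel", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("modelLoadings", "MorphospaceModel", function(object) object@loadings)
#' @rdname accessors
#' @export
setMethod("varianceExplained", "MorphospaceModel",
          function(object) object@varianceExplained)
#' @rdname accessors
#' @export
setMethod("contributions", "MorphospaceModel",
          function(object) object@contributions)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(object) {
  setNames(object@cluster, object@embryoIds)
})

#' @rdname accessors
#' @export
setMethod("nChannels", "EmbryoVolume", function(object) {
  d <- dim(object@data)
  if (length(d) == 4L) d[4L] else 1L
})

#' @rdname accessors
#' @param channel channel index or label
#' @export
setMethod("channelVolume", "EmbryoVolume", function(object, channel) {
  d <- dim(object@data)
  if (is.character(channel))
    channel <- match(channel, object@channelLabels)
  if (is.na(channel) || channel < 1L || channel > nChannels(object))
    stop("unknown channel")
  arr <- if (length(d) == 4L) object@data[, , , channel, drop = FALSE] else object@data
  dim(arr) <- d[1:3]
  EmbryoVolume(arr, object@voxelSize, object@channelLabels[channel])
})

setMethod("show", "EmbryoVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("EmbryoVolume: %s voxels (z,y,x), %d channel(s), %.3g um/voxel\n",
              paste(d[1:3], collapse = " x "), nChannels(object),
              object@voxelSize))
})

setMethod("show", "ProjectionSet", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "ProjectionSet '%s': %d x %d detector, %d angles (%.3g deg spacing), %.3g um/px\n",
    object@channelLabel, d[1], d[2], d[3],
    if (d[3] > 1) diff(object@angles)[1] else NA_real_, object@pixelSize))
  if (abs(object@appliedShift) > 0)
    cat(sprintf("  axis correction applied: %.3f px\n", object@appliedShift))
})

setMethod("show", "EmbryoMask", function(object) {
  cat(sprintf("EmbryoMask #%d: %d voxels (%.3g mm^3)\n", object@instanceId,
              object@voxelCount,
              object@voxelCount * (object@voxelSize / 1000)^3))
})

setMethod("show", "EmbryoSkeleton", function(object) {
  cat(sprintf("EmbryoSkeleton: %d path voxels, length %.1f um\n",
              nrow(object@path), object@pathLength))
})

setMethod("show", "MorphospaceModel", function(object) {
  cat(sprintf("MorphospaceModel: %d embryos x %d features\n",
              nrow(object@scores), length(object@featureNames)))
  ve <- object@varianceExplained
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              ve[1], if (length(ve) > 1) ve[2] else NA_real_))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment (%s, k = %d): %s\n", object@method, object@k,
              paste(table(object@cluster), collapse = "/")))
})

setMethod("show", "GradientProfile", function(object) {
  cat(sprintf("GradientProfile: %d embryos, %d grid points over [%.1f, %.1f] um\n",
              nrow(object@curves), length(object@grid), min(object@grid),
              max(object@grid)))
})
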