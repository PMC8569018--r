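#' Write a volume as multi-page TIFF
#'
#' Intensities are stored as 32-bit float pages (one page per z-slice per
#' channel), rescaled to [0, 1]; the scaling factor and voxel size go into
#' a JSON sidecar (same path + ".json") so volumes round-trip losslessly
#' up to float precision.
#'
#' @param volume an \linkS4class{EmbryoVolume}
#' @param path output TIFF path
#' @return invisibly, the path
#' @export
writeVolumeTiff <- function(volume, path) {
  stopifnot(is(volume, "EmbryoVolume"))
  arr <- volumeData(volume)
  d <- dim(arr)
  nch <- nChannels(volume)
  mx <- max(abs(arr), 1e-12)
  pages <- list()
  for (ch in seq_len(nch)) {
    a <- if (nch > 1L) arr[, , , ch] else arr
    for (z in seq_len(d[1L]))
      pages[[length(pages) + 1L]] <- pmax(a[z, , ], 0) / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale = mx, voxelSize = voxelSize(volume),
               dims = d[1:3], nChannels = nch,
               channelLabels = volume@channelLabels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a volume written by \code{writeVolumeTiff}
#'
#' @param path TIFF path (the JSON sidecar must sit next to it)
#' @return an \linkS4class{EmbryoVolume}
#' @export
readVolumeTiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  nch <- as.integer(meta$nChannels)
  arr <- array(0, c(d, nch))
  i <- 0L
  for (ch in seq_len(nch))
    for (z in seq_len(d[1L])) {
      i <- i + 1L
      arr[z, , , ch] <- pages[[i]] * meta$scale
    }
  if (nch == 1L) dim(arr) <- d
  EmbryoVolume(arr, voxelSize = meta$voxelSize,
               channelLabels = meta$channelLabels)
}

#' Write a projection series as multi-page TIFF
#'
#' One page per projection angle, with a JSON sidecar holding the angle
#' list, pixel size, channel label, applied shift and intensity scale.
#'
#' @param projections a \linkS4class{ProjectionSet}
#' @param path output TIFF path
#' @return invisibly, the path
#' @export
writeProjectionsTiff <- function(projections, path) {
  stopifnot(is(projections, "ProjectionSet"))
  img <- projections@images
  mx <- max(abs(img), 1e-12)
  pages <- lapply(seq_len(dim(img)[3L]),
                  function(a) pmax(img[, , a], 0) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(scale = mx, angles = projections@angles,
               pixelSize = projections@pixelSize,
               channelLabel = projections@channelLabel,
               appliedShift = projections@appliedShift,
               dims = dim(img))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a projection series written by \code{writeProjectionsTiff}
#'
#' @param path TIFF path
#' @return a \linkS4class{ProjectionSet}
#' @export
readProjectionsTiff <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  img <- array(0, d)
  for (a in seq_len(d[3L])) img[, , a] <- pages[[a]] * meta$scale
  ProjectionSet(img, angles = meta$angles, channelLabel = meta$channelLabel,
                pixelSize = meta$pixelSize, appliedShift = meta$appliedShift)
}

#' Serialize a morphospace model to JSON
#'
#' Stores feature names, means, scales, loadings, variance explained,
#' contributions and scores; \code{readMorphospaceJson} restores a model
#' usable for projection.
#'
#' @param model a \linkS4class{MorphospaceModel}
#' @param path output JSON path
#' @return invisibly, the path
#' @export
writeMorphospaceJson <- function(model, path) {
  stopifnot(is(model, "MorphospaceModel"))
  obj <- list(featureNames = model@featureNames,
              featureMeans = unname(model@featureMeans),
              featureScales = unname(model@featureScales),
              loadings = unclass(model@loadings),
              varianceExplained = model@varianceExplained,
              scores = unclass(model@scores),
              contributions = unclass(model@contributions),
              scaledData = unclass(model@scaledData),
              embryoIds = model@embryoIds,
              groupLabels = model@groupLabels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a morphospace model from JSON
#'
#' @param path JSON path written by \code{writeMorphospaceJson}
#' @return a \linkS4class{MorphospaceModel}
#' @export
readMorphospaceJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixmat <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- NULL
    m
  }
  gl <- as.character(o$groupLabels)
  new("MorphospaceModel", featureNames = o$featureNames,
      featureMeans = setNames(o$featureMeans, o$featureNames),
      featureScales = setNames(o$featureScales, o$featureNames),
      loadings = fixmat(o$loadings),
      varianceExplained = o$varianceExplained,
      scores = fixmat(o$scores), contributions = fixmat(o$contributions),
      scaledData = fixmat(o$scaledData),
      embryoIds = o$embryoIds, groupLabels = gl)
}

# descriptor CSV: 0-based coordinates convention applies only to
# coordinate columns; descriptor tables have none
.writeCsv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
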