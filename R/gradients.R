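#' Segment nuclei from a confocal z-stack
#'
#' Per-section adaptive thresholding against the local mean (box filter of
#' the given radius, plus an offset), refined by one erosion and one
#' dilation with a 3x3 structuring element, then 3D connected-component
#' labeling across sections; components smaller than \code{minVoxels} are
#' removed. Voxels inside an optional exclusion region (e.g. the yolk
#' syncytial layer) are discarded before labeling.
#'
#' @param stack nuclear-channel \linkS4class{EmbryoVolume} or 3D array
#'   (z, y, x)
#' @param meanFilterRadius box filter radius in pixels
#' @param minVoxels minimum nucleus size in voxels
#' @param offset additive threshold offset above the local mean
#' @param exclusionROI optional logical (y, x) matrix (TRUE = excluded),
#'   applied to every section
#' @return integer 3D label array (0 = background) with attribute
#'   \code{nNuclei}
#' @export
segmentNucleiStack <- function(stack, meanFilterRadius = 5L, minVoxels = 20L,
                               offset = 0, exclusionROI = NULL) {
  arr <- if (is(stack, "EmbryoVolume")) volumeData(stack) else as.array(stack)
  d <- dim(arr)
  if (length(d) != 3L) stop("stack must be a 3D (z,y,x) array")
  if (!is.null(exclusionROI)) {
    if (!is.logical(exclusionROI) || !all(dim(exclusionROI) == d[2:3]))
      stop("malformed exclusion ROI: need a logical (y, x) matrix")
  }
  side <- 2L * as.integer(meanFilterRadius) + 1L
  brush <- matrix(1 / side^2, side, side)
  se <- EBImage::makeBrush(3L, shape = "box")
  binary <- array(FALSE, d)
  for (z in seq_len(d[1L])) {
    sec <- arr[z, , ]
    localMean <- EBImage::filter2(sec, brush, boundary = "replicate")
    b <- sec > localMean + offset
    b <- EBImage::dilate(EBImage::erode(b, se), se)
    binary[z, , ] <- b > 0
  }
  if (!is.null(exclusionROI))
    binary <- binary & !aperm(array(exclusionROI, c(d[2:3], d[1L])),
                              c(3L, 1L, 2L))
  labels <- .label3d_cpp(binary, d)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    keep <- which(sizes >= minVoxels)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  attr(labels, "nNuclei") <- max(labels)
  labels
}

#' Measure segmented nuclei
#'
#' Per nucleus: centroid, voxel count, per-channel mean intensity and the
#' distance of the centroid from the margin reference along the profiling
#' axis (clamped at 0). The margin reference is a plane given by the
#' profiling axis ("z", "y" or "x"), its origin (voxel index) and a
#' direction (+1 = distances increase with the index).
#'
#' @param labels label array from \code{\link{segmentNucleiStack}}
#' @param channels \linkS4class{EmbryoVolume} (single- or multichannel)
#'   aligned with the labels
#' @param marginReference list(axis, origin, direction)
#' @return data.frame: nucleus_id, z, y, x (voxel centroid), voxel_count,
#'   margin_distance (um), one mean-intensity column per channel
#' @export
measureNuclei <- function(labels, channels,
                          marginReference = list(axis = "y", origin = 1,
                                                 direction = 1)) {
  vs <- if (is(channels, "EmbryoVolume")) voxelSize(channels) else 2
  arr <- if (is(channels, "EmbryoVolume")) volumeData(channels) else
    as.array(channels)
  d3 <- dim(labels)
  if (!all(dim(arr)[1:3] == d3)) stop("channel shape mismatch")
  nch <- if (length(dim(arr)) == 4L) dim(arr)[4L] else 1L
  labs <- if (is(channels, "EmbryoVolume")) channels@channelLabels else
    paste0("channel", seq_len(nch))
  n <- max(labels)
  if (n == 0L)
    return(data.frame(nucleus_id = integer(0), z = numeric(0), y = numeric(0),
                      x = numeric(0), voxel_count = integer(0),
                      margin_distance = numeric(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  co <- arrayInd(idx, d3)
  cz <- tapply(co[, 1L], lab, mean)
  cy <- tapply(co[, 2L], lab, mean)
  cx <- tapply(co[, 3L], lab, mean)
  cnt <- as.integer(table(lab))
  out <- data.frame(nucleus_id = seq_len(n), z = as.numeric(cz),
                    y = as.numeric(cy), x = as.numeric(cx),
                    voxel_count = cnt)
  axis <- match(marginReference$axis %||% "y", c("z", "y", "x"))
  if (is.na(axis)) stop("marginReference$axis must be z, y or x")
  centroidAxis <- switch(axis, out$z, out$y, out$x)
  dirn <- marginReference$direction %||% 1
  out$margin_distance <- pmax(0, (centroidAxis - (marginReference$origin %||% 1)) *
                                dirn * vs)
  for (c in seq_len(nch)) {
    ch <- if (nch > 1L) arr[, , , c] else arr
    out[[paste0("mean_", labs[c])]] <- as.numeric(tapply(ch[idx], lab, mean))
  }
  out
}

#' Fit smoothed intensity-versus-margin-distance profiles
#'
#' Per embryo, a locally weighted regression (lowess) of nuclear intensity
#' on margin distance, evaluated on a common distance grid; the group
#' aggregate is the pointwise mean and SEM across embryo curves.
#'
#' @param records named list of per-embryo data.frames (from
#'   \code{\link{measureNuclei}}) or a single data.frame with an
#'   \code{embryo_id} column
#' @param intensityColumn column holding the nuclear signal intensity
#' @param smoothingFraction lowess smoother span (default 0.3)
#' @param gridLength number of grid points (default 50)
#' @return a \linkS4class{GradientProfile}
#' @export
fitGradientProfile <- function(records, intensityColumn = "intensity",
                               smoothingFraction = 0.3, gridLength = 50L) {
  if (is.data.frame(records)) {
    if (!"embryo_id" %in% names(records))
      stop("data.frame input needs an embryo_id column")
    records <- split(records, records$embryo_id)
  }
  if (is.null(names(records)))
    names(records) <- sprintf("embryo%02d", seq_along(records))
  for (id in names(records)) {
    r <- records[[id]]
    if (!intensityColumn %in% names(r))
      stop(sprintf("embryo %s: no column '%s'", id, intensityColumn))
    if (nrow(r) < 10L)
      stop(sprintf("embryo %s has fewer than 10 nuclei", id))
  }
  lo <- max(vapply(records, function(r) min(r$margin_distance), numeric(1L)))
  hi <- min(vapply(records, function(r) max(r$margin_distance), numeric(1L)))
  if (hi <= lo) stop("embryo distance ranges do not overlap")
  grid <- seq(lo, hi, length.out = gridLength)
  curves <- t(vapply(records, function(r) {
    fit <- lowess(r$margin_distance, r[[intensityColumn]],
                  f = smoothingFraction)
    approx(fit$x, fit$y, xout = grid, rule = 2L)$y
  }, numeric(gridLength)))
  rownames(curves) <- names(records)
  mu <- colMeans(curves)
  sem <- apply(curves, 2L, sd) / sqrt(nrow(curves))
  new("GradientProfile", embryoIds = names(records), grid = grid,
      curves = curves, mean = mu, sem = sem)
}

#' Signal-domain size ratio
#'
#' Ratio of a thresholded signal-domain area to the embryo area, both
#' measured on the same maximum-intensity projection (e.g. the size of a
#' phospho-Smad signaling domain relative to the embryo surface).
#'
#' @param signalArea signal domain area (um^2 or px)
#' @param embryoArea embryo area in the same units
#' @return ratio in [0, 1]
#' @export
domainSizeRatio <- function(signalArea, embryoArea) {
  if (embryoArea <= 0) stop("embryo area must be positive")
  if (signalArea < 0) stop("signal area must be nonnegative")
  if (signalArea > embryoArea)
    stop("signal area exceeds embryo area (registration failure)")
  signalArea / embryoArea
}

#' Measure domain areas on maximum-intensity projections
#'
#' Otsu-thresholds the embryo projection to get the embryo region, then
#' Otsu-thresholds the signal projection within that region; returns both
#' areas and their ratio. Replaces manual polygon ROIs with a reproducible
#' rule.
#'
#' @param signalMIP,embryoMIP 2D matrices (maximum-intensity projections)
#' @param pixelSize pixel edge length (um)
#' @return list: signalArea, embryoArea (um^2), ratio
#' @export
domainAreasFromMIP <- function(signalMIP, embryoMIP, pixelSize = 1) {
  stopifnot(all(dim(signalMIP) == dim(embryoMIP)))
  embryo <- embryoMIP > .otsuThreshold(embryoMIP)
  if (!any(embryo)) stop("empty embryo projection")
  insideVals <- signalMIP[embryo]
  signal <- if (diff(range(insideVals)) == 0) embryo & FALSE else
    embryo & (signalMIP > .otsuThreshold(insideVals))
  signalArea <- sum(signal) * pixelSize^2
  embryoArea <- sum(embryo) * pixelSize^2
  list(signalArea = signalArea, embryoArea = embryoArea,
       ratio = domainSizeRatio(signalArea, embryoArea))
}
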