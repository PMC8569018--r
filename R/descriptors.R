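#' Names of the default morphological descriptor set
#'
#' The 26 descriptors computed per embryo: volume (voxels and um^3),
#' surface area, sphericity, extent, solidity, principal axis lengths and
#' ratios, skeleton length, tortuosity, A/P chord and AP index,
#' skeleton-to-surface distance statistics, minimum-subtracted intensity
#' statistics, and centroid depth statistics.
#'
#' @return character vector of descriptor names, in output order
#' @export
descriptorNames <- function() {
  c("volume_voxels", "volume_um3", "surface_area_um2", "sphericity",
    "extent", "solidity",
    "axis_length_L1_um", "axis_length_L2_um", "axis_length_L3_um",
    "axis_ratio_L2_L1", "axis_ratio_L3_L1", "axis_ratio_L3_L2",
    "skeleton_length_um", "tortuosity", "ap_chord_um", "ap_index",
    "skel_surf_dist_mean_um", "skel_surf_dist_variation",
    "skel_surf_dist_skewness", "skel_surf_dist_kurtosis",
    "intensity_mean", "intensity_variation", "intensity_skewness",
    "intensity_kurtosis",
    "centroid_depth_um", "centroid_depth_fraction")
}

#' Compute the per-embryo descriptor vector
#'
#' Assembles the default 26-descriptor morphometric profile of one
#' segmented embryo: shape descriptors from the mask, skeleton descriptors
#' from the pruned centerline, the AP index from landmark-seeded geodesic
#' distance maps, and intensity descriptors from the nuclear channel.
#' Deterministic given its inputs; component errors are propagated with
#' the descriptor name attached.
#'
#' Surface area uses exposed voxel-face counting with the standard 2/3
#' correction factor for digitized smooth surfaces; sphericity is
#' pi^(1/3) (6V)^(2/3) / A. Centroid depth is the distance (um) of the
#' mask centroid to the nearest surface voxel and, as a fraction, relative
#' to the maximum in-mask depth.
#'
#' @param volume multichannel \linkS4class{EmbryoVolume} (channel 1 =
#'   nuclear) or a single-channel volume used for intensity statistics
#' @param mask \linkS4class{EmbryoMask}
#' @param landmarks \linkS4class{Landmarks}
#' @param skeleton optional precomputed \linkS4class{EmbryoSkeleton}
#' @return named numeric vector of length \code{length(descriptorNames())}
#' @examples
#' ph <- makeEmbryoPhantom(phantomSpec(volumeShape = c(24, 32, 48),
#'   radiusProfile = function(s) rep(26, length(s))))
#' mk <- EmbryoMask(maskArray(ph$truth), voxelSize = 6.5)
#' lm <- Landmarks(ph$truth@anteriorPoint, ph$truth@posteriorPoint)
#' dv <- computeDescriptors(ph$volume, mk, lm)
#' length(dv)
#' @export
computeDescriptors <- function(volume, mask, landmarks, skeleton = NULL) {
  vs <- voxelSize(mask)
  m <- maskArray(mask)
  ctx <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
  }

  nuclear <- if (is(volume, "EmbryoVolume") && nChannels(volume) > 1L)
    channelVolume(volume, 1L) else volume

  nv <- sum(m)
  faces <- .exposedFaceCount(m)
  area <- faces * vs^2 * (2 / 3)
  volUm3 <- nv * vs^3
  sphericity <- pi^(1 / 3) * (6 * volUm3)^(2 / 3) / area
  bbox <- apply(.maskCoords(m), 2L, range)
  extent <- nv / prod(bbox[2L, ] - bbox[1L, ] + 1)

  L <- ctx("principal_axes", principalAxisLengths(mask))
  sol <- ctx("solidity", maskSolidity(mask))
  skel <- skeleton %||% ctx("skeleton", computeSkeleton(mask, landmarks))
  tort <- ctx("tortuosity", tortuosity(skel))
  sss <- ctx("skeleton_surface", skeletonSurfaceStats(mask, skel))
  ap <- ctx("ap_index", apIndex(mask, landmarks))
  apChord <- sqrt(sum((landmarks@posterior - landmarks@anterior)^2)) * vs
  ints <- ctx("intensity", intensityStats(nuclear, mask))

  surf <- .surfaceVoxels(m)
  depth <- .edt_cpp(surf, dim(m))
  centroid <- round(colMeans(.maskCoords(m)))
  centroid <- pmin(pmax(centroid, 1), dim(m))
  cDepth <- depth[centroid[1L], centroid[2L], centroid[3L]] * vs
  cFrac <- if (max(depth[m]) > 0) cDepth / (max(depth[m]) * vs) else NA_real_

  out <- c(
    volume_voxels = nv,
    volume_um3 = volUm3,
    surface_area_um2 = area,
    sphericity = sphericity,
    extent = extent,
    solidity = sol,
    axis_length_L1_um = unname(L["L1"]),
    axis_length_L2_um = unname(L["L2"]),
    axis_length_L3_um = unname(L["L3"]),
    axis_ratio_L2_L1 = unname(L["L2"] / L["L1"]),
    axis_ratio_L3_L1 = unname(L["L3"] / L["L1"]),
    axis_ratio_L3_L2 = unname(L["L3"] / L["L2"]),
    skeleton_length_um = pathLength(skel),
    tortuosity = tort,
    ap_chord_um = apChord,
    ap_index = ap,
    skel_surf_dist_mean_um = unname(sss["mean"]),
    skel_surf_dist_variation = unname(sss["variation"]),
    skel_surf_dist_skewness = unname(sss["skewness"]),
    skel_surf_dist_kurtosis = unname(sss["kurtosis"]),
    intensity_mean = unname(ints["mean"]),
    intensity_variation = unname(ints["variation"]),
    intensity_skewness = unname(ints["skewness"]),
    intensity_kurtosis = unname(ints["kurtosis"]),
    centroid_depth_um = cDepth,
    centroid_depth_fraction = cFrac)
  stopifnot(identical(names(out), descriptorNames()))
  out
}

#' Descriptor table for a set of embryos
#'
#' Convenience wrapper building the per-embryo descriptor data.frame the
#' morphospace is fitted on.
#'
#' @param entries list; each element needs \code{volume}, \code{mask},
#'   \code{landmarks}, and optionally \code{id} and \code{group}
#' @return data.frame with embryo_id, group_label and one column per
#'   descriptor
#' @export
descriptorTable <- function(entries) {
  rows <- lapply(seq_along(entries), function(i) {
    e <- entries[[i]]
    dv <- computeDescriptors(e$volume, e$mask, e$landmarks, e$skeleton)
    cbind(data.frame(embryo_id = e$id %||% sprintf("embryo%02d", i),
                     group_label = e$group %||% NA_character_,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(dv)))
  })
  do.call(rbind, rows)
}
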