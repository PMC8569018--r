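#' Default morphospace feature selection
#'
#' The scale-free shape descriptors that carry the severity signal
#' (axis bending and shortening, thickness non-uniformity, body
#' non-convexity): these are the descriptors the morphospace is fitted on
#' by default. Raw sizes and intensity moments are excluded; they mostly
#' reflect acquisition settings rather than morphology.
#'
#' @return character vector of descriptor names
#' @export
morphospaceFeatures <- function() {
  c("sphericity", "extent", "solidity",
    "axis_ratio_L2_L1", "axis_ratio_L3_L1", "axis_ratio_L3_L2",
    "skeleton_length_um", "tortuosity", "ap_chord_um", "ap_index",
    "skel_surf_dist_mean_um", "skel_surf_dist_variation")
}

#' Fit a PCA morphospace to a descriptor table
#'
#' Selected descriptor columns are z-scored (mean 0, SD 1 per feature) and
#' decomposed by PCA (singular value decomposition). The model stores the
#' scaling constants, orthonormal loadings, per-component variance
#' explained (percent, summing to 100), embryo scores and per-variable
#' contributions to each component (squared loading x component variance,
#' normalized to 100 percent per component). Rows containing missing
#' values in the selected features are dropped with a warning. Component
#' signs are fixed so the largest-magnitude loading of each component is
#' positive.
#'
#' @param descriptors data.frame as returned by
#'   \code{\link{descriptorTable}} (columns embryo_id, group_label,
#'   descriptors)
#' @param selectedFeatures feature columns to use; defaults to the
#'   scale-free shape descriptors (\code{\link{morphospaceFeatures}})
#'   present in the table, falling back to all numeric descriptor columns
#' @return a \linkS4class{MorphospaceModel}
#' @export
fitMorphospace <- function(descriptors, selectedFeatures = NULL) {
  df <- as.data.frame(descriptors)
  idCol <- if ("embryo_id" %in% names(df)) df$embryo_id else
    sprintf("embryo%02d", seq_len(nrow(df)))
  grpCol <- if ("group_label" %in% names(df)) as.character(df$group_label) else
    rep(NA_character_, nrow(df))
  if (is.null(selectedFeatures)) {
    selectedFeatures <- intersect(morphospaceFeatures(), names(df))
    if (length(selectedFeatures) < 3L) selectedFeatures <- NULL
  }
  feats <- selectedFeatures %||%
    setdiff(names(df)[vapply(df, is.numeric, logical(1L))],
            c("embryo_id", "group_label"))
  missing <- setdiff(feats, names(df))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(df[, feats, drop = FALSE])
  bad <- !stats::complete.cases(X)
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with missing descriptor values",
                    sum(bad)))
    X <- X[!bad, , drop = FALSE]
    idCol <- idCol[!bad]
    grpCol <- grpCol[!bad]
  }
  if (nrow(X) < 3L) stop("need at least 3 embryos")
  sds <- apply(X, 2L, sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(feats[sds == 0], collapse = ", "))
  pca <- prcomp(X, center = TRUE, scale. = TRUE)
  # deterministic sign: largest |loading| positive per component
  flip <- apply(pca$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pca$rotation, 2L, flip, "*")
  sc <- sweep(pca$x, 2L, flip, "*")
  ev <- pca$sdev^2
  ve <- 100 * ev / sum(ev)
  contrib <- sweep(rot^2, 2L, colSums(rot^2), "/") * 100
  scaled <- scale(X, center = pca$center, scale = pca$scale)
  dimnames(scaled) <- list(idCol, feats)
  rownames(sc) <- idCol
  new("MorphospaceModel", featureNames = feats,
      featureMeans = setNames(pca$center, feats),
      featureScales = setNames(pca$scale, feats),
      loadings = rot, varianceExplained = ve, scores = sc,
      contributions = contrib,
      scaledData = scaled[, , drop = FALSE],
      embryoIds = as.character(idCol), groupLabels = grpCol)
}

#' Project new embryos into a fitted morphospace
#'
#' Applies the stored centering/scaling and loadings to new descriptor
#' rows; re-projecting the training table reproduces the stored scores.
#'
#' @param model a \linkS4class{MorphospaceModel}
#' @param newDescriptors data.frame containing all model features
#' @return score matrix (embryos x components)
#' @export
projectSamples <- function(model, newDescriptors) {
  stopifnot(is(model, "MorphospaceModel"))
  df <- as.data.frame(newDescriptors)
  missing <- setdiff(model@featureNames, names(df))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(df[, model@featureNames, drop = FALSE])
  Xs <- sweep(sweep(X, 2L, model@featureMeans), 2L, model@featureScales, "/")
  Xs %*% model@loadings
}

#' Cluster embryos into severity groups
#'
#' Clusters the scaled descriptor rows (default) or the PC scores with
#' hierarchical clustering (Ward linkage, Euclidean distance), k-means or
#' k-medoids. Cluster labels are renumbered 1..k by ascending mean PC1
#' score so they order along the main severity axis (note the PCA sign
#' convention makes the direction deterministic but not inherently
#' "severe = high").
#'
#' @param model a \linkS4class{MorphospaceModel}
#' @param method one of "hierarchical", "kmeans", "kmedoids"
#' @param k number of clusters (default 4: unperturbed / slightly /
#'   moderately / heavily perturbed)
#' @param seed integer seed (k-means initialization)
#' @param space "features" (scaled descriptors, default) or "scores"
#' @return a \linkS4class{ClusterAssignment}
#' @export
clusterEmbryos <- function(model,
                           method = c("hierarchical", "kmeans", "kmedoids"),
                           k = 4L, seed = 1L,
                           space = c("features", "scores")) {
  stopifnot(is(model, "MorphospaceModel"))
  method <- match.arg(method)
  space <- match.arg(space)
  X <- if (space == "features") model@scaledData else model@scores
  n <- nrow(X)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k cannot exceed the number of embryos")
  cl <- switch(method,
    hierarchical = cutree(hclust(dist(X), method = "ward.D2"), k = k),
    kmeans = {
      set.seed(seed)
      kmeans(X, centers = k, nstart = 10L)$cluster
    },
    kmedoids = cluster::pam(X, k = k, cluster.only = TRUE))
  # relabel by ascending mean PC1
  pc1 <- model@scores[, 1L]
  ord <- order(vapply(seq_len(k), function(g) mean(pc1[cl == g]), numeric(1L)))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  new("ClusterAssignment", embryoIds = model@embryoIds,
      cluster = as.integer(relabel[cl]), method = method, k = as.integer(k),
      meta = list(seed = as.integer(seed), space = space,
                  linkage = if (method == "hierarchical") "ward.D2" else NA))
}
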