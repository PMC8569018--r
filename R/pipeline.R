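#' Build (or read) a run configuration
#'
#' A run configuration bundles the per-stage parameters of the whole
#' sinogram-to-morphospace workflow: the input (a synthetic cohort spec or
#' file paths), the channel-role map, axis-correction, segmentation,
#' morphospace and output settings. Unset sections take package defaults.
#'
#' @param input either list(type = "simulate", cohort = cohortSpec-args)
#'   or list(type = "volumes"/"sinograms", paths = character vector of
#'   TIFF files written by the package writers)
#' @param channels role map: nuclear / anterior / posterior channel index
#' @param reconstruct simulate the OPT leg (forward projection, axis
#'   correction, FBP) before segmentation; if FALSE volumes are used as-is
#' @param nAngles,axisOffsetPx,noiseSigma OPT simulation settings (used
#'   when reconstruct = TRUE on simulated input)
#' @param axisCorrection \code{\link{axisCorrectionParams}} arguments
#' @param segmentation \code{\link{segmentationParams}} arguments
#' @param morphospace list(method, k, seed, space)
#' @param outDir output directory (created if needed); NULL = no files
#' @param seed top-level seed
#' @return a RunConfig list
#' @export
runConfig <- function(input = list(type = "simulate", cohort = list()),
                      channels = list(nuclear = 1L, anterior = 2L,
                                      posterior = 3L),
                      reconstruct = FALSE,
                      nAngles = 400L, axisOffsetPx = 0, noiseSigma = 0,
                      axisCorrection = list(),
                      segmentation = list(minSize = 1000),
                      morphospace = list(method = "hierarchical", k = 4L,
                                         seed = 1L, space = "features"),
                      outDir = NULL, seed = 1L) {
  roles <- c("nuclear", "anterior", "posterior")
  if (!all(roles %in% names(channels)))
    stop("channels must map nuclear, anterior and posterior roles")
  idx <- unlist(channels[roles])
  if (any(duplicated(idx)))
    stop("each channel role must map to a distinct channel index")
  structure(list(input = input, channels = channels,
                 reconstruct = isTRUE(reconstruct), nAngles = nAngles,
                 axisOffsetPx = axisOffsetPx, noiseSigma = noiseSigma,
                 axisCorrection = axisCorrection,
                 segmentation = segmentation, morphospace = morphospace,
                 outDir = outDir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the fields of \code{\link{runConfig}}
#' @return a RunConfig list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, o)
}

#' Run the full pipeline end to end
#'
#' Simulates or loads the acquisitions, optionally runs the OPT leg
#' (forward projection with a miscentred axis, axis-shift estimation and
#' correction, filtered back-projection), segments every embryo instance,
#' detects landmarks, computes the 26-descriptor array, fits the PCA
#' morphospace, clusters embryos into severity groups, and writes
#' descriptor CSV, model JSON, scores+clusters CSV, landmark CSV
#' (0-based voxel coordinates) and a run log recording every effective
#' parameter and the per-pair axis shifts.
#'
#' @param config a \code{\link{runConfig}} (or path to its JSON form)
#' @return invisibly, list(status, descriptors, model, clusters,
#'   artifacts, log)
#' @export
runEndToEnd <- function(config = runConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig"))
  logLines <- c(sprintf("embryomorph run, seed %d", config$seed),
                sprintf("config: %s",
                        jsonlite::toJSON(config[setdiff(names(config),
                                                        "input")],
                                         auto_unbox = TRUE, force = TRUE)))
  entries <- list()

  if (identical(config$input$type, "simulate")) {
    coh <- do.call(cohortSpec, c(config$input$cohort,
                                 list(seed = config$seed)))
    cohort <- makeCohort(coh)
    logLines <- c(logLines, sprintf("simulated cohort: %d phantoms",
                                    length(cohort)))
    for (ph in cohort)
      entries[[length(entries) + 1L]] <-
        list(volume = ph$volume, group = ph$dose, id = ph$id)
  } else if (config$input$type %in% c("volumes", "sinograms")) {
    paths <- config$input$paths
    if (is.null(paths) || !all(file.exists(paths)))
      stop("missing input path(s): ",
           paste(paths[!file.exists(paths)], collapse = ", "))
    if (config$input$type == "volumes") {
      for (i in seq_along(paths))
        entries[[i]] <- list(volume = readVolumeTiff(paths[i]),
                             group = NA_character_,
                             id = sprintf("acq%02d", i))
    } else {
      stop("sinogram file input expects one multichannel volume per ",
           "acquisition; reconstruct each channel with reconstructFBP() ",
           "and pass type = 'volumes'")
    }
  } else stop("unknown input type")

  segParams <- do.call(segmentationParams, config$segmentation)
  axParams <- do.call(axisCorrectionParams, config$axisCorrection)
  ms0 <- config$morphospace
  logLines <- c(logLines,
    sprintf("segmentation: %s",
            jsonlite::toJSON(segParams[!vapply(segParams, is.null,
                                               logical(1L))],
                             auto_unbox = TRUE)),
    sprintf("axis correction: %s",
            jsonlite::toJSON(axParams[!vapply(axParams, is.null,
                                              logical(1L))],
                             auto_unbox = TRUE)),
    sprintf("morphospace: method %s, k %d, seed %d, space %s",
            ms0$method %||% "hierarchical", ms0$k %||% 4L, ms0$seed %||% 1L,
            ms0$space %||% "features"))

  rows <- list()
  for (e in entries) {
    vol <- e$volume
    if (config$reconstruct) {
      rec <- array(0, c(dim(volumeData(channelVolume(vol, 1L))), 0))
      chans <- list()
      shiftEst <- NA_real_
      for (ch in seq_len(nChannels(vol))) {
        ps <- forwardProject(channelVolume(vol, ch),
                             nAngles = config$nAngles,
                             axisOffsetPx = config$axisOffsetPx,
                             noiseSigma = config$noiseSigma,
                             seed = config$seed + ch)
        if (ch == 1L) {
          est <- estimateAxisShift(ps, axParams)
          shiftEst <- est$shift
          logLines <- c(logLines,
                        sprintf("%s: per-pair shifts [%s], median %.3f px",
                                e$id,
                                paste(sprintf("%.2f", est$pairShifts),
                                      collapse = ", "), est$shift))
        }
        psc <- applyAxisCorrection(ps, shiftEst)
        rv <- reconstructFBP(psc)
        cropped <- .cropCenter(volumeData(rv), dim(volumeData(vol))[1:3])
        # FBP retains negative ringing; clip for downstream segmentation
        chans[[ch]] <- pmax(cropped, 0)
      }
      arr <- array(0, c(dim(chans[[1L]]), length(chans)))
      for (ch in seq_along(chans)) arr[, , , ch] <- chans[[ch]]
      vol <- EmbryoVolume(arr, voxelSize(vol), e$volume@channelLabels)
    }
    nuclear <- channelVolume(vol, config$channels$nuclear)
    masks <- segmentEmbryos(nuclear, segParams)
    logLines <- c(logLines, sprintf("%s: %d instance(s) pass size criterion",
                                    e$id, length(masks)))
    for (mk in masks) {
      lm <- detectLandmarks(channelVolume(vol, config$channels$anterior),
                            channelVolume(vol, config$channels$posterior),
                            mk)
      id <- if (length(masks) > 1L)
        sprintf("%s_i%02d", e$id, mk@instanceId) else e$id
      rows[[length(rows) + 1L]] <- list(volume = vol, mask = mk,
                                        landmarks = lm, id = id,
                                        group = e$group)
    }
  }
  if (length(rows) == 0L) stop("no embryo instance segmented")
  descriptors <- descriptorTable(rows)

  model <- NULL
  assign_ <- NULL
  if (nrow(descriptors) >= 3L) {
    feats <- setdiff(names(descriptors)[vapply(descriptors, is.numeric,
                                               logical(1L))],
                     c("embryo_id", "group_label"))
    sds <- vapply(descriptors[feats], sd, numeric(1L))
    usable <- feats[!is.na(sds) & sds > 0]
    preferred <- intersect(morphospaceFeatures(), usable)
    model <- fitMorphospace(descriptors,
                            if (length(preferred) >= 3L) preferred else usable)
    ms <- config$morphospace
    k <- min(ms$k %||% 4L, nrow(scores(model)))
    assign_ <- clusterEmbryos(model, method = ms$method %||% "hierarchical",
                              k = k, seed = ms$seed %||% 1L,
                              space = ms$space %||% "features")
  } else {
    logLines <- c(logLines, "fewer than 3 embryos: morphospace skipped")
  }

  artifacts <- character(0)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(config$outDir, "descriptors.csv")
    .writeCsv(descriptors, p1)
    artifacts <- p1
    lmdf <- do.call(rbind, lapply(rows, function(r)
      data.frame(embryo_id = r$id,
                 anterior_z = r$landmarks@anterior[1L] - 1,
                 anterior_y = r$landmarks@anterior[2L] - 1,
                 anterior_x = r$landmarks@anterior[3L] - 1,
                 posterior_z = r$landmarks@posterior[1L] - 1,
                 posterior_y = r$landmarks@posterior[2L] - 1,
                 posterior_x = r$landmarks@posterior[3L] - 1)))
    p2 <- file.path(config$outDir, "landmarks.csv")
    .writeCsv(lmdf, p2)
    artifacts <- c(artifacts, p2)
    if (!is.null(model)) {
      p3 <- file.path(config$outDir, "morphospace.json")
      writeMorphospaceJson(model, p3)
      sc <- scores(model)
      p4 <- file.path(config$outDir, "scores_clusters.csv")
      .writeCsv(data.frame(embryo_id = model@embryoIds,
                           group_label = model@groupLabels,
                           PC1 = sc[, 1L],
                           PC2 = if (ncol(sc) > 1L) sc[, 2L] else NA_real_,
                           cluster = as.integer(clusterLabels(assign_))),
                p4)
      artifacts <- c(artifacts, p3, p4)
    }
    p5 <- file.path(config$outDir, "run.log")
    writeLines(logLines, p5)
    artifacts <- c(artifacts, p5)
  }
  invisible(list(status = 0L, descriptors = descriptors, model = model,
                 clusters = assign_, artifacts = artifacts, log = logLines))
}
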