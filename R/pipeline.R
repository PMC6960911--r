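#' @include illumination.R ergcm.R emsrcm.R features.R classifier.R
NULL

.configKeys <- c("greenHueRange", "heBins", "minAreaFrac", "diskRadius",
                 "msrSigmas", "msrEpsilon", "closingRadius", "tophatRadius",
                 "openingRadius", "uejrTA", "uejrTN", "svmCost", "matchIoU",
                 "seed")

#' Construct a pipeline configuration
#'
#' All tunables of the segmentation pipeline with their working defaults.
#'
#' @param greenHueRange green hue band, radians.
#' @param heBins equalization bins.
#' @param minAreaFrac minimum region area fraction.
#' @param diskRadius primary-chain closing disk radius (px).
#' @param msrSigmas retinex surround scales (px).
#' @param msrEpsilon retinex log guard.
#' @param closingRadius,tophatRadius,openingRadius re-extraction chain disk
#'   radii (px).
#' @param uejrTA,uejrTN under-extraction thresholds (percent area / count).
#' @param svmCost linear SVM cost.
#' @param matchIoU region-to-tree match threshold.
#' @param seed integer seed.
#' @return a [PipelineConfig-class].
#' @export
pipelineConfig <- function(greenHueRange = c(pi / 2, pi), heBins = 256,
                           minAreaFrac = 5e-4, diskRadius = 5,
                           msrSigmas = c(15, 80, 250), msrEpsilon = 1e-6,
                           closingRadius = 20, tophatRadius = 24,
                           openingRadius = 0, uejrTA = 45, uejrTN = 20,
                           svmCost = 1, matchIoU = 0.5, seed = 1) {
  obj <- new("PipelineConfig", greenHueRange = greenHueRange, heBins = heBins,
             minAreaFrac = minAreaFrac, diskRadius = diskRadius,
             msrSigmas = msrSigmas, msrEpsilon = msrEpsilon,
             closingRadius = closingRadius, tophatRadius = tophatRadius,
             openingRadius = openingRadius, uejrTA = uejrTA, uejrTN = uejrTN,
             svmCost = svmCost, matchIoU = matchIoU, seed = seed)
  validObject(obj)
  obj
}

configToList <- function(cfg) {
  stopifnot(is(cfg, "PipelineConfig"))
  setNames(lapply(.configKeys, function(k) as.numeric(slot(cfg, k))),
           .configKeys)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round-trips losslessly; unknown keys are rejected with an error
#' so that typos cannot silently fall back to defaults.
#'
#' @param path YAML file path.
#' @param cfg a [PipelineConfig-class].
#' @return `readPipelineConfig` a [PipelineConfig-class];
#'   `writePipelineConfig` the path, invisibly.
#' @export
readPipelineConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .configKeys)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}

#' @rdname readPipelineConfig
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(configToList(cfg), path, precision = 15L)
  invisible(path)
}

#' Classify a scene's brightness and weed-cover conditions
#'
#' The green-cover ratio A is the fraction of pixels whose hue falls in the
#' green band; the weed-cover condition is `SWCR` (A < 35%), `MWCR`
#' (35% <= A < 60%) or `LWCR` (A >= 60%). The brightness condition is
#' [classifyBrightness()] on the same foreground.
#'
#' @param img an [RGBImage-class].
#' @param cfg a [PipelineConfig-class].
#' @return list with `bc`, `wcc`, `greenFraction` and `meanForegroundI`.
#' @export
classifyConditions <- function(img, cfg = pipelineConfig()) {
  stopifnot(is(img, "RGBImage"))
  hsi <- rgbToHsi(img)
  sg <- greenSelectionMask(hsi, cfg@greenHueRange)
  A <- mean(sg)
  wcc <- if (A < 0.35) "SWCR" else if (A < 0.60) "MWCR" else "LWCR"
  ia <- if (any(sg)) mean(hsi@intensity[sg]) else NA_real_
  bc <- if (!is.na(ia) && ia < 0.3) "IB" else "SB"
  list(bc = bc, wcc = wcc, greenFraction = A, meanForegroundI = ia)
}

#' Segment one orchard image
#'
#' The full pipeline: selective illumination compensation ([srihe()]);
#' primary extraction ([extractRoisErgcm()]); the under-extraction rule
#' ([uejrIsUnderExtracted()]) which, when it fires, swaps in the retinex
#' re-extraction ([extractRoisEmsrcm()]); per-region descriptors; and,
#' when a model is supplied and `applySvm` is `TRUE`, SVM confirmation that
#' removes regions classified as background. Deterministic given image,
#' model and configuration.
#'
#' @param img an [RGBImage-class].
#' @param model a [TreeSvmModel-class], or `NULL` to skip SVM filtering.
#' @param cfg a [PipelineConfig-class].
#' @param applySvm set `FALSE` to keep every candidate region (the
#'   "without SVM" pipeline variant).
#' @return a [SegmentationResult-class]. Candidate regions whose texture
#'   support is degenerate are dropped and recorded in the provenance. The
#'   provenance also carries `candidateLabelMap`, the label map of all
#'   featurizable candidates before SVM filtering (what `applySvm = FALSE`
#'   would return as final regions).
#' @export
segmentImage <- function(img, model = NULL, cfg = pipelineConfig(),
                         applySvm = !is.null(model)) {
  stopifnot(is(img, "RGBImage"))
  pre <- srihe(img, cfg@greenHueRange, cfg@heBins)
  rois <- extractRoisErgcm(pre, minAreaFrac = cfg@minAreaFrac,
                           diskRadius = cfg@diskRadius)
  backend <- "ERGCM"
  uejrA <- 100 * areaFraction(rois)
  uejrN <- regionCount(rois)
  underExtracted <- uejrIsUnderExtracted(rois, cfg@uejrTA, cfg@uejrTN)
  if (underExtracted) {
    rois <- extractRoisEmsrcm(pre, sigmas = cfg@msrSigmas,
                              epsilon = cfg@msrEpsilon,
                              closingRadius = cfg@closingRadius,
                              tophatRadius = cfg@tophatRadius,
                              openingRadius = cfg@openingRadius,
                              minAreaFrac = cfg@minAreaFrac)
    backend <- "EMSRCM"
  }
  feats <- regionFeatures(pre, rois, mode = "inner_rect")
  dropped <- attr(featureMatrix(feats), "droppedIds")
  if (applySvm && is.null(model))
    stop("applySvm = TRUE requires a trained model")
  if (applySvm && nrow(featureMatrix(feats)) > 0L) {
    cls <- classifyRegions(model, feats)
  } else {
    cls <- data.frame(
      score = rep(NA_real_, nrow(featureMatrix(feats))),
      label = factor(rep("tree", nrow(featureMatrix(feats))),
                     levels = c("background", "tree")))
  }
  tab <- regionTable(rois)
  tab <- tab[tab$id %in% feats@regionIds, , drop = FALSE]
  tab$score <- cls$score
  tab$label <- as.character(cls$label)
  rownames(tab) <- NULL
  keepIds <- feats@regionIds[cls$label == "tree"]
  finalRegions <- subsetRegions(rois, keepIds)
  candidates <- subsetRegions(rois, feats@regionIds)
  new("SegmentationResult", regions = finalRegions, table = tab,
      backend = backend,
      provenance = list(
        backend = backend,
        candidateLabelMap = labelMap(candidates),
        underExtracted = underExtracted,
        uejrA = uejrA,
        uejrN = uejrN,
        svmApplied = isTRUE(applySvm) && nrow(featureMatrix(feats)) > 0L,
        candidateA = 100 * areaFraction(rois),
        candidateN = regionCount(rois),
        droppedRegionIds = as.integer(dropped),
        config = configToList(cfg)))
}

#' Write the per-region table of a segmentation result to CSV
#'
#' Columns: `id`, `centroidRow`, `centroidCol`, `area`, `score`, `label`.
#'
#' @param result a [SegmentationResult-class].
#' @param path output CSV path.
#' @export
writeRegionCsv <- function(result, path) {
  stopifnot(is(result, "SegmentationResult"))
  tab <- result@table[, c("id", "centroidRow", "centroidCol", "area",
                          "score", "label")]
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
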