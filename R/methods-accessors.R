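#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("imgData", "RGBImage", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("imgHeight", "RGBImage", function(x) dim(x@data)[1L])

#' @rdname accessors
#' @export
setMethod("imgWidth", "RGBImage", function(x) dim(x@data)[2L])

#' @rdname accessors
#' @export
setMethod("labelMap", "RegionSet", function(x) x@labelMap)

#' @rdname accessors
#' @export
setMethod("regionTable", "RegionSet", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("regionCount", "RegionSet", function(x) nrow(x@regions))

#' @rdname accessors
#' @export
setMethod("areaFraction", "RegionSet",
          function(x) sum(x@labelMap > 0L) / length(x@labelMap))

#' @rdname accessors
#' @export
setMethod("featureMatrix", "RegionFeatures", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("featureLabels", "RegionFeatures", function(x) x@labels)

setMethod("show", "RGBImage", function(object) {
  cat(sprintf("RGBImage: %d x %d px, range [%.3f, %.3f]\n",
              imgHeight(object), imgWidth(object),
              min(object@data), max(object@data)))
})

setMethod("show", "HSIImage", function(object) {
  cat(sprintf("HSIImage: %d x %d px, mean intensity %.3f\n",
              nrow(object@intensity), ncol(object@intensity),
              mean(object@intensity)))
})

setMethod("show", "ChromaticMap", function(object) {
  cat(sprintf("ChromaticMap (%s): %d x %d px, range [%.3f, %.3f]\n",
              object@kind, nrow(object@data), ncol(object@data),
              min(object@data), max(object@data)))
})

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet: %d region(s), foreground area ratio A = %.2f%%\n",
              regionCount(object), 100 * areaFraction(object)))
  if (regionCount(object) > 0L)
    print(head(object@regions, 5L))
})

setMethod("show", "RegionFeatures", function(object) {
  cat(sprintf("RegionFeatures: %d region(s) x %d dims; labels: %s\n",
              nrow(object@features), ncol(object@features),
              paste(levels(object@labels), collapse = "/")))
})

setMethod("show", "TreeSvmModel", function(object) {
  cat(sprintf(
    "TreeSvmModel: linear SVM, %d dims, cost %.3g, trained on %s samples\n",
    length(object@weights), object@cost,
    paste(unlist(object@meta$classCounts), collapse = "+")))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: backend %s, %d candidate region(s), %d kept\n",
              object@backend, nrow(object@table), regionCount(object@regions)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px, %d trees, green target %.0f%%, brightness %.2f, seed %d\n",
    object@width, object@height, object@nTrees, 100 * object@greenTarget,
    object@brightness, as.integer(object@seed)))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf("SceneTruth: %d tree(s), %s/%s, weed cover %.1f%%\n",
              max(object@treeLabelMap), object@bc, object@wcc,
              100 * mean(object@weedMask)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig:\n")
  str(configToList(object), give.attr = FALSE, no.list = TRUE)
})
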