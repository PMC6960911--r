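#' @import methods
#' @importFrom stats rnorm runif quantile sd setNames complete.cases
#' @importFrom utils head read.csv write.csv str
NULL

#' RGBImage: an in-gamut RGB raster
#'
#' A true-color image stored as an `H x W x 3` numeric array with all
#' intensities in `[0, 1]`, rows indexed top to bottom ((1,1) is the top-left
#' pixel). All pipeline stages consume and produce this class.
#'
#' @slot data numeric array, `height x width x 3` (R, G, B planes).
#' @export
setClass("RGBImage", representation(data = "array"))

setValidity("RGBImage", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L || dim(d)[3L] != 3L)
    return("data must be an H x W x 3 array")
  if (dim(d)[1L] < 1L || dim(d)[2L] < 1L)
    return("image must have at least one row and one column")
  if (!all(is.finite(d)))
    return("image intensities must be finite")
  rng <- range(d)
  if (rng[1L] < 0 || rng[2L] > 1)
    return("image intensities must lie in [0, 1]")
  TRUE
})

#' Construct an RGBImage
#'
#' @param data numeric `H x W x 3` array with values in `[0, 1]`.
#' @return an [RGBImage-class] object.
#' @export
RGBImage <- function(data) {
  obj <- new("RGBImage", data = data)
  validObject(obj)
  obj
}

#' HSIImage: hue/saturation/intensity planes
#'
#' Hue is an angle in `[0, 2*pi]`; the band `[pi/2, pi]` is read as green
#' vegetation. Saturation and intensity lie in `[0, 1]`. Achromatic pixels
#' (R = G = B) carry hue 0 and saturation 0 by convention; black pixels carry
#' all three components 0.
#'
#' @slot hue numeric matrix, radians in `[0, 2*pi]`.
#' @slot sat numeric matrix in `[0, 1]`.
#' @slot intensity numeric matrix in `[0, 1]`.
#' @export
setClass("HSIImage",
         representation(hue = "matrix", sat = "matrix", intensity = "matrix"))

setValidity("HSIImage", function(object) {
  dm <- dim(object@hue)
  if (!identical(dm, dim(object@sat)) || !identical(dm, dim(object@intensity)))
    return("hue, sat and intensity must share dimensions")
  if (any(object@hue < -1e-9) || any(object@hue > 2 * pi + 1e-9))
    return("hue must lie in [0, 2*pi]")
  if (any(object@sat < -1e-9) || any(object@sat > 1 + 1e-9))
    return("saturation must lie in [0, 1]")
  if (any(object@intensity < -1e-9) || any(object@intensity > 1 + 1e-9))
    return("intensity must lie in [0, 1]")
  TRUE
})

#' LabImage: CIE L*a*b* planes (D65)
#'
#' @slot L lightness plane, `[0, 100]` for in-gamut sRGB input.
#' @slot a green-red opponent plane.
#' @slot b blue-yellow opponent plane.
#' @export
setClass("LabImage", representation(L = "matrix", a = "matrix", b = "matrix"))

setValidity("LabImage", function(object) {
  dm <- dim(object@L)
  if (!identical(dm, dim(object@a)) || !identical(dm, dim(object@b)))
    return("L, a and b must share dimensions")
  if (!all(is.finite(object@L), is.finite(object@a), is.finite(object@b)))
    return("Lab planes must be finite")
  TRUE
})

#' ChromaticMap: a real-valued per-pixel chromatic index
#'
#' Holds either the brightness-relative G-R index `(G - R) / I` used for
#' primary extraction, or the `2G - R - B` excess-green index computed on a
#' retinex reflectance image.
#'
#' @slot data numeric matrix of index values.
#' @slot kind `"relative_gr"` or `"twoG_R_B"`.
#' @export
setClass("ChromaticMap", representation(data = "matrix", kind = "character"))

setValidity("ChromaticMap", function(object) {
  if (!all(is.finite(object@data))) return("chromatic map must be finite")
  if (!object@kind %in% c("relative_gr", "twoG_R_B"))
    return("kind must be 'relative_gr' or 'twoG_R_B'")
  TRUE
})

#' RegionSet: labelled connected foreground components
#'
#' A label map (0 = background, 1..N = regions, 8-connected) together with a
#' per-region table of area, centroid and bounding box. Row/column coordinates
#' are 1-based with origin at the top-left pixel.
#'
#' @slot labelMap integer matrix; 0 background, labels contiguous 1..N.
#' @slot regions data.frame with columns `id`, `area`, `centroidRow`,
#'   `centroidCol`, `rowMin`, `rowMax`, `colMin`, `colMax`.
#' @export
setClass("RegionSet",
         representation(labelMap = "matrix", regions = "data.frame"))

setValidity("RegionSet", function(object) {
  n <- nrow(object@regions)
  labs <- sort(unique(as.integer(object@labelMap)))
  labs <- labs[labs > 0L]
  if (n != length(labs)) return("region table rows must match label count")
  if (n > 0L && !identical(labs, seq_len(n))) return("labels must be contiguous 1..N")
  if (n > 0L && sum(object@regions$area) != sum(object@labelMap > 0L))
    return("region areas must sum to the foreground pixel count")
  TRUE
})

#' RegionFeatures: per-region descriptor matrix
#'
#' One 78-dimensional row per region: 14 color statistics (mean and population
#' variance of R, G, B, H, S, a*, b*), 5 GLCM statistics (CON, ASM, ENT, IDM,
#' COR) and the 59-bin uniform-LBP histogram.
#'
#' @slot features numeric matrix, regions x 78, named columns.
#' @slot labels factor with levels `background`, `tree` (may be all NA for
#'   unlabelled regions).
#' @slot regionIds integer vector of the region ids the rows describe.
#' @export
setClass("RegionFeatures",
         representation(features = "matrix", labels = "factor",
                        regionIds = "integer"))

setValidity("RegionFeatures", function(object) {
  if (nrow(object@features) != length(object@labels) ||
      nrow(object@features) != length(object@regionIds))
    return("features, labels and regionIds must agree in length")
  if (any(!is.finite(object@features)))
    return("feature values must be finite (degenerate statistics map to 0)")
  TRUE
})

#' TreeSvmModel: a standardized linear SVM over region descriptors
#'
#' Stores the collapsed primal weight vector and bias of a linear-kernel
#' soft-margin SVM together with the per-dimension standardization fitted on
#' the training set. The decision score of a region is
#' `w . (x - center)/scale + bias`; scores strictly greater than zero are
#' called `tree`.
#'
#' @slot weights numeric weight vector (one entry per feature dimension).
#' @slot bias numeric scalar.
#' @slot center,scale numeric standardization vectors (zero-variance
#'   dimensions keep scale 1).
#' @slot featureNames character vector naming the expected columns.
#' @slot cost soft-margin cost parameter used at fit time.
#' @slot meta list of training metadata (class counts, seed, version).
#' @export
setClass("TreeSvmModel",
         representation(weights = "numeric", bias = "numeric",
                        center = "numeric", scale = "numeric",
                        featureNames = "character", cost = "numeric",
                        meta = "list"))

setValidity("TreeSvmModel", function(object) {
  p <- length(object@weights)
  if (length(object@center) != p || length(object@scale) != p ||
      length(object@featureNames) != p)
    return("weights, center, scale and featureNames must agree in length")
  if (any(object@scale <= 0)) return("scale entries must be positive")
  TRUE
})

#' SceneSpec: parameters of one synthetic orchard scene
#'
#' Defaults emulate nadir orchard frames at an effective resolution of about
#' 16 px/m, where a 2.8 m crown spans roughly 45 px: textured elliptical
#' crowns on a soil/withered-grass background, green weed patches driving the
#' scene's green-cover fraction, a global brightness factor separating
#' insufficient (IB) from sufficient (SB) brightness, then optical blur and
#' sensor noise. Rendering is fully deterministic given `seed`.
#'
#' @slot width,height image size in pixels.
#' @slot nTrees number of crowns to pack.
#' @slot crownSemiMinor,crownSemiMajor numeric length-2 ranges (px) for the
#'   ellipse semi-axes.
#' @slot minGap minimum clearance between crown bounding circles (px).
#' @slot crownColor,weedColor,soilColor base RGB triplets.
#' @slot crownMottleSigma,crownMottleAmp coarse multiplicative crown mottle:
#'   Gaussian correlation length (px) and relative amplitude.
#' @slot crownEdgeShade radial edge darkening of crowns (0 = flat disc;
#'   ~0.3 emulates canopy curvature self-shading seen from nadir).
#' @slot weedGrainSigma,weedGrainAmp fine weed grain: correlation length (px)
#'   and relative amplitude.
#' @slot weedChromaAmp amplitude of independent per-channel weed jitter.
#' @slot weedPatchSigma correlation length (px) of the weed patch field.
#' @slot weedClearance weed-free ring width around crowns (px), emulating
#'   understory suppression by canopy shade.
#' @slot greenTarget target green-cover fraction of the image (crowns plus
#'   visible weeds), achieved within +/- 5 points.
#' @slot colorJitter per-crown relative brightness jitter half-range.
#' @slot brightness global multiplicative brightness factor.
#' @slot blurSigma optical blur scale (px).
#' @slot noiseSigma additive sensor noise s.d.
#' @slot allowOverlap if `TRUE`, crowns may overlap (packing constraint off).
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
         representation(width = "numeric", height = "numeric",
                        nTrees = "numeric",
                        crownSemiMinor = "numeric", crownSemiMajor = "numeric",
                        minGap = "numeric",
                        crownColor = "numeric", weedColor = "numeric",
                        soilColor = "numeric",
                        crownMottleSigma = "numeric", crownMottleAmp = "numeric",
                        crownEdgeShade = "numeric",
                        weedGrainSigma = "numeric", weedGrainAmp = "numeric",
                        weedChromaAmp = "numeric", weedPatchSigma = "numeric",
                        weedClearance = "numeric",
                        greenTarget = "numeric", colorJitter = "numeric",
                        brightness = "numeric", blurSigma = "numeric",
                        noiseSigma = "numeric", allowOverlap = "logical",
                        seed = "numeric"))

setValidity("SceneSpec", function(object) {
  if (object@width < 32 || object@height < 32)
    return("scene must be at least 32 x 32")
  if (object@nTrees < 0) return("nTrees must be non-negative")
  if (length(object@crownSemiMinor) != 2L || length(object@crownSemiMajor) != 2L)
    return("crown axis ranges must have length 2")
  for (s in c("crownColor", "weedColor", "soilColor")) {
    v <- slot(object, s)
    if (length(v) != 3L || any(v < 0) || any(v > 1))
      return(sprintf("%s must be an RGB triplet in [0,1]", s))
  }
  if (object@greenTarget < 0 || object@greenTarget > 0.95)
    return("greenTarget must lie in [0, 0.95]")
  if (object@brightness <= 0) return("brightness must be positive")
  TRUE
})

#' SceneTruth: ground truth of a rendered scene
#'
#' @slot treeLabelMap integer matrix; 0 background, i = pixels of tree i.
#' @slot weedMask logical matrix of visible weed pixels.
#' @slot centroids numeric matrix (row, col) per tree.
#' @slot bc brightness condition label recomputed from the rendered pixels
#'   (`"IB"` or `"SB"`).
#' @slot wcc weed-cover condition label recomputed from the rendered pixels
#'   (`"SWCR"`, `"MWCR"` or `"LWCR"`).
#' @export
setClass("SceneTruth",
         representation(treeLabelMap = "matrix", weedMask = "matrix",
                        centroids = "matrix", bc = "character",
                        wcc = "character"))

#' PipelineConfig: every tunable of the segmentation pipeline
#'
#' Round-trips losslessly through YAML ([readPipelineConfig()] /
#' [writePipelineConfig()]); unknown keys are rejected.
#'
#' @slot greenHueRange hue band read as green, radians.
#' @slot heBins histogram-equalization bin count.
#' @slot minAreaFrac smallest kept region area as a fraction of image area.
#' @slot diskRadius radius (px) of the closing disk in primary extraction.
#' @slot msrSigmas the three Gaussian surround scales (px) of the retinex.
#' @slot msrEpsilon log-guard constant of the retinex.
#' @slot closingRadius,tophatRadius,openingRadius disk radii (px) of the
#'   grayscale morphology cascade of the re-extraction chain.
#' @slot uejrTA area-ratio threshold (percent) of the under-extraction rule.
#' @slot uejrTN region-count threshold of the under-extraction rule.
#' @slot svmCost soft-margin cost of the linear SVM.
#' @slot matchIoU IoU at or above which a predicted region matches a truth
#'   tree in the count metrics.
#' @slot seed integer seed used by stochastic helpers.
#' @export
setClass("PipelineConfig",
         representation(greenHueRange = "numeric", heBins = "numeric",
                        minAreaFrac = "numeric", diskRadius = "numeric",
                        msrSigmas = "numeric", msrEpsilon = "numeric",
                        closingRadius = "numeric", tophatRadius = "numeric",
                        openingRadius = "numeric",
                        uejrTA = "numeric", uejrTN = "numeric",
                        svmCost = "numeric", matchIoU = "numeric",
                        seed = "numeric"))

setValidity("PipelineConfig", function(object) {
  if (length(object@greenHueRange) != 2L ||
      object@greenHueRange[1L] >= object@greenHueRange[2L])
    return("greenHueRange must be an increasing length-2 vector")
  if (object@uejrTA <= 0 || object@uejrTA >= 100)
    return("uejrTA must lie in (0, 100)")
  if (object@uejrTN < 1) return("uejrTN must be >= 1")
  if (length(object@msrSigmas) != 3L || any(object@msrSigmas <= 0))
    return("msrSigmas must be three positive scales")
  if (object@matchIoU <= 0 || object@matchIoU > 1)
    return("matchIoU must lie in (0, 1]")
  TRUE
})

#' SegmentationResult: output of the full pipeline on one image
#'
#' @slot regions final [RegionSet-class] after (optional) SVM filtering.
#' @slot table data.frame with one row per candidate region: id, area,
#'   centroid, decision score and label; filtered regions are retained in the
#'   table with label `background`.
#' @slot backend `"ERGCM"` or `"EMSRCM"` — which extraction chain produced
#'   the candidate regions.
#' @slot provenance list of thresholds and stage statistics.
#' @export
setClass("SegmentationResult",
         representation(regions = "RegionSet", table = "data.frame",
                        backend = "character", provenance = "list"))
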