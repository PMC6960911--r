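#' @include AllClasses.R
NULL

#' Accessors for image and region classes
#'
#' `imgData` returns the raw array of an [RGBImage-class]; `imgHeight` and
#' `imgWidth` its pixel dimensions. `labelMap` and `regionTable` expose the
#' components of a [RegionSet-class]; `regionCount` returns the number of
#' regions N and `areaFraction` the foreground area ratio A (as a fraction of
#' the image area).
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))

#' @rdname accessors
#' @export
setGeneric("imgHeight", function(x) standardGeneric("imgHeight"))

#' @rdname accessors
#' @export
setGeneric("imgWidth", function(x) standardGeneric("imgWidth"))

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname accessors
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname accessors
#' @export
setGeneric("regionCount", function(x) standardGeneric("regionCount"))

#' @rdname accessors
#' @export
setGeneric("areaFraction", function(x) standardGeneric("areaFraction"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))
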