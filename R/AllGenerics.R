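#' @include AllClasses.R
NULL

#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))

#' @export
setGeneric("platform", function(object) standardGeneric("platform"))

#' @export
setGeneric("intensityUnits", function(object) standardGeneric("intensityUnits"))

#' @export
setGeneric("surfaceValues", function(object) standardGeneric("surfaceValues"))

#' @export
setGeneric("rawMax", function(object) standardGeneric("rawMax"))

#' @export
setGeneric("planeLevel", function(object) standardGeneric("planeLevel"))

#' @export
setGeneric("rawLevel", function(object) standardGeneric("rawLevel"))

#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))

#' @export
setGeneric("nPixels", function(object) standardGeneric("nPixels"))

#' @export
setGeneric("maskBoundary", function(object) standardGeneric("maskBoundary"))

#' @export
setGeneric("cropImage", function(image, box, ...) standardGeneric("cropImage"))

#' @export
setGeneric("binImage", function(image, k, ...) standardGeneric("binImage"))

#' @export
setGeneric("detectSaturation",
           function(image, ...) standardGeneric("detectSaturation"))

#' @export
setGeneric("normalizeImage",
           function(image, ...) standardGeneric("normalizeImage"))

#' @export
setGeneric("entropyThreshold",
           function(surface, ...) standardGeneric("entropyThreshold"))

#' @export
setGeneric("planeSegment",
           function(surface, plane, ...) standardGeneric("planeSegment"))

#' @export
setGeneric("surfaceExport",
           function(surface, plane, ...) standardGeneric("surfaceExport"))

#' @export
setGeneric("measureRegion",
           function(image, mask, plane, ...) standardGeneric("measureRegion"))

#' @export
setGeneric("estimateBackground",
           function(image, region, ...) standardGeneric("estimateBackground"))

#' @export
setGeneric("detectSignal",
           function(image, candidate, background, ...)
             standardGeneric("detectSignal"))
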