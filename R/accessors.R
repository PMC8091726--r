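#' @include AllGenerics.R
NULL

#' Accessors for the imaging containers
#'
#' `pixels()` returns the raw count matrix of a [RawImage-class];
#' `bitDepth()`, `platform()` and `intensityUnits()` its metadata.
#' `surfaceValues()` and `rawMax()` access a [NormalizedSurface-class];
#' `planeLevel()` and `rawLevel()` a [ThresholdPlane-class];
#' `maskMatrix()`, `nPixels()` and `maskBoundary()` a [RegionMask-class].
#'
#' @param object the container to access.
#' @name accessors
#' @aliases pixels bitDepth platform intensityUnits surfaceValues rawMax
#'   planeLevel rawLevel maskMatrix nPixels maskBoundary
NULL

#' @rdname accessors
#' @exportMethod pixels
setMethod("pixels", "RawImage", function(object) object@pixels)

#' @rdname accessors
#' @exportMethod bitDepth
setMethod("bitDepth", "RawImage", function(object) object@bitDepth)

#' @rdname accessors
#' @exportMethod platform
setMethod("platform", "RawImage", function(object) object@platform)

#' @rdname accessors
#' @exportMethod intensityUnits
setMethod("intensityUnits", "RawImage", function(object) object@units)

#' @rdname accessors
#' @exportMethod surfaceValues
setMethod("surfaceValues", "NormalizedSurface", function(object) object@values)

#' @rdname accessors
#' @exportMethod rawMax
setMethod("rawMax", "NormalizedSurface", function(object) object@rawMax)

#' @rdname accessors
#' @exportMethod planeLevel
setMethod("planeLevel", "ThresholdPlane", function(object) object@level)

#' @rdname accessors
#' @exportMethod rawLevel
setMethod("rawLevel", "ThresholdPlane", function(object) object@rawLevel)

#' @rdname accessors
#' @exportMethod maskMatrix
setMethod("maskMatrix", "RegionMask", function(object) object@mask)

#' @rdname accessors
#' @exportMethod nPixels
setMethod("nPixels", "RegionMask", function(object) sum(object@mask))

#' @rdname accessors
#' @exportMethod maskBoundary
setMethod("maskBoundary", "RegionMask", function(object) object@boundary)

#' @describeIn RawImage-class image dimensions (rows, columns).
#' @param x a `RawImage`.
#' @exportMethod dim
setMethod("dim", "RawImage", function(x) dim(x@pixels))

setMethod("show", "RawImage", function(object) {
  p <- object@pixels
  cat(sprintf("RawImage %dx%d, %d-bit [%s, %s]\n",
              nrow(p), ncol(p), object@bitDepth, object@platform,
              object@units))
  cat(sprintf("  counts: min %.0f, max %.0f (ceiling %.0f)\n",
              min(p), max(p), 2^object@bitDepth - 1))
})

setMethod("show", "NormalizedSurface", function(object) {
  cat(sprintf("NormalizedSurface %dx%d, rawMax %.0f [%s]\n",
              nrow(object@values), ncol(object@values), object@rawMax,
              object@source@platform))
})

setMethod("show", "ThresholdPlane", function(object) {
  cat(sprintf("ThresholdPlane level %.4f (raw %.1f), method %s\n",
              object@level, object@rawLevel, object@method))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask %dx%d: %d signal pixels, %d boundary pixels\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              nrow(object@boundary)))
})

setMethod("show", "BackgroundEstimate", function(object) {
  cat(sprintf("BackgroundEstimate over %d px: mean %.2f, sd %.2f\n",
              sum(object@region@mask), object@mean, object@sd))
})

setMethod("show", "IntensityMeasurement", function(object) {
  cat(sprintf(
    "IntensityMeasurement [mouse %s, day %s]\n", object@mouseId,
    format(object@day)))
  cat(sprintf(
    "  area %d px, total %.1f, net %.1f, mean net %.3f %s (%d saturated)\n",
    object@areaPx, object@totalRaw, object@netTotal, object@meanNet,
    object@units, object@saturatedInMask))
})

setMethod("show", "DilutionSeries", function(object) {
  cat(sprintf(
    "DilutionSeries: %d dilutions (%g .. %g), %d background wells\n",
    length(object@dilutionFactors), max(object@dilutionFactors),
    min(object@dilutionFactors), length(object@backgroundWells)))
})

#' Coerce an IntensityMeasurement to a one-row data.frame
#'
#' @param x an [IntensityMeasurement-class].
#' @param row.names,optional,... ignored; present for the S3 signature.
#' @return A one-row `data.frame` with the measurement columns used by the
#'   pipeline CSV output.
#' @export
as.data.frame.IntensityMeasurement <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(
    mouse_id = x@mouseId, day = x@day, units = x@units,
    area_px = x@areaPx, total_raw = x@totalRaw,
    plane_raw_level = x@backgroundRawLevel, net_total = x@netTotal,
    mean_net = x@meanNet, saturated_in_mask = x@saturatedInMask,
    stringsAsFactors = FALSE
  )
}
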