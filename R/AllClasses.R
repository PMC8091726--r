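#' @import methods
NULL

## Central containers. All images are single-channel 2D grids of
## non-negative integer counts; bit depth is the *logical* detector depth
## (16 for XVI/BIX-like data, 22 for LPT-like data), independent of the
## on-disk container width.

#' RawImage: a single-channel raw imaging frame
#'
#' Holds the unscaled integer counts exported from a small-animal imaging
#' platform, together with the logical detector bit depth, a free-text
#' platform tag (e.g. `"XVI"`, `"BIX"`, `"LPT"`) and the platform's
#' intensity-unit tag (`"radiant efficiency"`, `"counts"`, `"signal"`).
#'
#' @slot pixels numeric matrix of non-negative integer-valued counts.
#' @slot bitDepth single integer; pixel values must not exceed
#'   `2^bitDepth - 1`.
#' @slot platform character tag describing the imaging platform.
#' @slot units character tag describing the raw intensity units.
#'
#' @seealso [RawImage()], [readRawTiff()], [binImage()], [cropImage()]
#' @exportClass RawImage
setClass("RawImage",
  slots = c(
    pixels   = "matrix",
    bitDepth = "integer",
    platform = "character",
    units    = "character"
  )
)

setValidity("RawImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
  if (anyNA(p) || any(!is.finite(p))) return("pixels must be finite")
  if (any(p < 0)) return("pixel values must be non-negative")
  if (any(p != round(p))) return("pixel values must be integer counts")
  if (length(object@bitDepth) != 1L || is.na(object@bitDepth) ||
      object@bitDepth < 1L || object@bitDepth > 32L)
    return("bitDepth must be a single integer in [1, 32]")
  ceiling_ <- 2^object@bitDepth - 1
  if (any(p > ceiling_))
    return(sprintf("pixel values exceed the %d-bit ceiling %.0f",
                   object@bitDepth, ceiling_))
  if (length(object@platform) != 1L || length(object@units) != 1L)
    return("platform and units must be single strings")
  TRUE
})

#' Construct a RawImage
#'
#' @param pixels numeric matrix of non-negative integer counts (doubles that
#'   are whole numbers are accepted; 22-bit LPT data exceed the 16-bit range
#'   and are carried in doubles).
#' @param bitDepth logical detector bit depth, typically 16 or 22.
#' @param platform platform tag, e.g. `"XVI"`, `"BIX"`, `"LPT"`.
#' @param units intensity-unit tag, e.g. `"radiant efficiency"`,
#'   `"counts"`, `"signal"`.
#' @return A [RawImage-class] object.
#' @examples
#' img <- RawImage(matrix(0:3, 2, 2), bitDepth = 16)
#' dim(img)
#' @export
RawImage <- function(pixels, bitDepth = 16L, platform = "generic",
                     units = "counts") {
  storage.mode(pixels) <- "double"
  new("RawImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      platform = as.character(platform), units = as.character(units))
}

#' CropBox: a rectangular region of interest
#'
#' Coordinates are 0-based, half-open `[start, stop)` in (row, column)
#' order, matching the convention used by the command-line interface.
#'
#' @slot rowStart,rowStop,colStart,colStop single integers with
#'   `0 <= start < stop`.
#' @exportClass CropBox
setClass("CropBox",
  slots = c(rowStart = "integer", rowStop = "integer",
            colStart = "integer", colStop = "integer")
)

setValidity("CropBox", function(object) {
  v <- c(object@rowStart, object@rowStop, object@colStart, object@colStop)
  if (length(v) != 4L || anyNA(v)) return("all four coordinates required")
  if (object@rowStart < 0L || object@colStart < 0L)
    return("start coordinates must be >= 0")
  if (object@rowStart >= object@rowStop || object@colStart >= object@colStop)
    return("stop must be strictly greater than start")
  TRUE
})

#' @rdname CropBox-class
#' @param rowStart,rowStop,colStart,colStop 0-based, half-open pixel indices.
#' @return A [CropBox-class] object.
#' @export
CropBox <- function(rowStart, rowStop, colStart, colStop) {
  new("CropBox", rowStart = as.integer(rowStart), rowStop = as.integer(rowStop),
      colStart = as.integer(colStart), colStop = as.integer(colStop))
}

#' NormalizedSurface: the unit-interval 3D intensity surface
#'
#' Pixel values divided by the image maximum, so the brightest pixel maps to
#' exactly 1. `rawMax` retains the raw value mapped to 1 so that any level
#' on the surface can be converted back to raw units.
#'
#' @slot values numeric matrix in `[0, 1]` with maximum exactly 1.
#' @slot rawMax raw pixel value mapped to 1.
#' @slot source the [RawImage-class] the surface was built from.
#' @seealso [normalizeImage()], [entropyThreshold()], [planeSegment()]
#' @exportClass NormalizedSurface
setClass("NormalizedSurface",
  slots = c(values = "matrix", rawMax = "numeric", source = "RawImage")
)

setValidity("NormalizedSurface", function(object) {
  v <- object@values
  if (anyNA(v) || any(v < 0) || any(v > 1))
    return("surface values must lie in [0, 1]")
  if (length(object@rawMax) != 1L || object@rawMax <= 0)
    return("rawMax must be a single positive number")
  if (abs(max(v) - 1) > 1e-12)
    return("maximum surface value must be exactly 1")
  if (!identical(dim(v), dim(object@source@pixels)))
    return("surface and source image dimensions differ")
  TRUE
})

#' ThresholdPlane: a horizontal cut through the intensity surface
#'
#' @slot level cut height in normalized units, in `[0, 1]`.
#' @slot rawLevel the same cut expressed in raw units
#'   (`level * rawMax` of the surface it was derived from).
#' @slot method `"auto_entropy"` (Kapur maximum-entropy initial value) or
#'   `"manual"` (user-adjusted).
#' @seealso [entropyThreshold()], [thresholdPlane()], [planeSegment()]
#' @exportClass ThresholdPlane
setClass("ThresholdPlane",
  slots = c(level = "numeric", rawLevel = "numeric", method = "character")
)

setValidity("ThresholdPlane", function(object) {
  if (length(object@level) != 1L || is.na(object@level) ||
      object@level < 0 || object@level > 1)
    return("level must be a single value in [0, 1]")
  if (length(object@rawLevel) != 1L || object@rawLevel < 0)
    return("rawLevel must be a single non-negative value")
  if (!object@method %in% c("auto_entropy", "manual"))
    return("method must be 'auto_entropy' or 'manual'")
  TRUE
})

#' Construct a manual ThresholdPlane for a surface
#'
#' @param surface a [NormalizedSurface-class].
#' @param level plane height in normalized units (`[0, 1]`); give either
#'   this or `rawLevel`.
#' @param rawLevel plane height in raw units; converted through the
#'   surface's `rawMax`.
#' @return A [ThresholdPlane-class] with `method = "manual"`.
#' @export
thresholdPlane <- function(surface, level = NULL, rawLevel = NULL) {
  stopifnot(is(surface, "NormalizedSurface"))
  if (is.null(level) == is.null(rawLevel))
    stop("give exactly one of 'level' or 'rawLevel'")
  if (is.null(level)) level <- rawLevel / rawMax(surface)
  new("ThresholdPlane", level = as.numeric(level),
      rawLevel = as.numeric(level) * rawMax(surface), method = "manual")
}

#' RegionMask: a boolean pixel region with its boundary
#'
#' @slot mask logical matrix; `TRUE` marks region (signal) pixels.
#' @slot boundary integer matrix of (row, col) coordinates (1-based) of
#'   region pixels 4-adjacent to a non-region pixel or the image edge.
#' @seealso [planeSegment()], [measureRegion()], [ellipseMask()]
#' @exportClass RegionMask
setClass("RegionMask",
  slots = c(mask = "matrix", boundary = "matrix")
)

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (anyNA(object@mask)) return("mask must not contain NA")
  TRUE
})

#' Construct a RegionMask from a logical matrix
#'
#' The boundary (region pixels 4-adjacent to background or the image edge)
#' is computed automatically.
#'
#' @param mask logical matrix.
#' @return A [RegionMask-class] object.
#' @export
RegionMask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  new("RegionMask", mask = mask, boundary = .maskBoundary(mask))
}

# 4-connectivity boundary: region pixels with any non-region 4-neighbour,
# counting pixels beyond the image edge as non-region.
.maskBoundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  interior <- core &
    pad[1:nr, 2:(nc + 1L), drop = FALSE] &
    pad[3:(nr + 2L), 2:(nc + 1L), drop = FALSE] &
    pad[2:(nr + 1L), 1:nc, drop = FALSE] &
    pad[2:(nr + 1L), 3:(nc + 2L), drop = FALSE]
  which(core & !interior, arr.ind = TRUE)
}

#' BackgroundEstimate: raw-unit background statistics over a region
#'
#' Produced by [estimateBackground()] over a tumour-free region (the paper's
#' workflow uses an ellipse at the shoulder contralateral to the signal).
#'
#' @slot region the [RegionMask-class] the statistics were taken over.
#' @slot mean,sd mean and sample (n-1) standard deviation of the raw counts
#'   in the region; `sd` is `NA` for a single-pixel region.
#' @exportClass BackgroundEstimate
setClass("BackgroundEstimate",
  slots = c(region = "RegionMask", mean = "numeric", sd = "numeric")
)

setValidity("BackgroundEstimate", function(object) {
  if (sum(object@region@mask) < 1L) return("background region is empty")
  if (!is.na(object@sd) && object@sd < 0) return("sd must be >= 0")
  TRUE
})

#' IntensityMeasurement: a background-subtracted raw-unit measurement
#'
#' All quantities are in the raw, unscaled units of the source platform.
#' `netTotal = totalRaw - backgroundRawLevel * areaPx` implements the
#' plane-level background subtraction of the surface workflow.
#'
#' @slot totalRaw sum of raw counts inside the mask.
#' @slot backgroundRawLevel raw-unit height of the threshold plane.
#' @slot areaPx mask pixel count.
#' @slot netTotal background-subtracted total.
#' @slot meanNet `netTotal / areaPx` (0 for an empty mask).
#' @slot saturatedInMask number of bit-depth-ceiling pixels inside the mask.
#' @slot units intensity-unit tag inherited from the image.
#' @slot mouseId,day identifiers for longitudinal bookkeeping.
#' @seealso [measureRegion()], [foldChange()]
#' @exportClass IntensityMeasurement
setClass("IntensityMeasurement",
  slots = c(totalRaw = "numeric", backgroundRawLevel = "numeric",
            areaPx = "integer", netTotal = "numeric", meanNet = "numeric",
            saturatedInMask = "integer", units = "character",
            mouseId = "character", day = "numeric")
)

setValidity("IntensityMeasurement", function(object) {
  if (object@areaPx < 0L) return("areaPx must be >= 0")
  if (object@netTotal > object@totalRaw + 1e-9)
    return("netTotal cannot exceed totalRaw")
  if (object@areaPx == 0L &&
      (object@totalRaw != 0 || object@netTotal != 0 || object@meanNet != 0))
    return("an empty region must have zero totals")
  TRUE
})

#' DilutionSeries: replicated serial-dilution measurements
#'
#' Raw-unit well measurements of a (typically tenfold) serial dilution with
#' dedicated background wells, as used to establish platform dynamic range
#' and limit of detection.
#'
#' @slot dilutionFactors strictly decreasing positive factors, the top
#'   (least dilute) first, e.g. `10^(0:-5)`.
#' @slot replicateSignals list (one element per dilution) of numeric
#'   replicate measurements.
#' @slot backgroundWells numeric measurements of blank wells.
#' @seealso [dilutionLinearity()], [limitOfDetection()], [simDilutionPlate()]
#' @exportClass DilutionSeries
setClass("DilutionSeries",
  slots = c(dilutionFactors = "numeric", replicateSignals = "list",
            backgroundWells = "numeric")
)

setValidity("DilutionSeries", function(object) {
  f <- object@dilutionFactors
  if (length(f) < 2L) return("need at least 2 dilutions")
  if (any(f <= 0)) return("dilution factors must be positive")
  if (any(diff(f) >= 0)) return("dilution factors must be strictly decreasing")
  if (length(object@replicateSignals) != length(f))
    return("one replicate vector per dilution required")
  if (any(vapply(object@replicateSignals, length, 1L) < 1L))
    return("each dilution needs at least one replicate")
  TRUE
})

#' @rdname DilutionSeries-class
#' @param dilutionFactors strictly decreasing positive dilution factors.
#' @param replicateSignals list of numeric replicate vectors, one per factor.
#' @param backgroundWells numeric background-well measurements.
#' @return A [DilutionSeries-class] object.
#' @export
DilutionSeries <- function(dilutionFactors, replicateSignals,
                           backgroundWells = numeric()) {
  new("DilutionSeries", dilutionFactors = as.numeric(dilutionFactors),
      replicateSignals = lapply(replicateSignals, as.numeric),
      backgroundWells = as.numeric(backgroundWells))
}
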