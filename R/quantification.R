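#' @include segmentation.R
NULL

#' Measure background-subtracted tumour intensity in raw units
#'
#' All quantities come directly from the raw, unscaled counts. The plane's
#' raw-unit height defines the background level, which is subtracted as
#' `level x area`: `netTotal = sum(raw in mask) - rawLevel * areaPx`.
#' Saturated (ceiling-valued) pixels inside the mask are counted and
#' reported, since clipped peaks bias totals downwards.
#'
#' @param image the [RawImage-class] the mask refers to.
#' @param mask a [RegionMask-class] congruent with the image (typically
#'   from [planeSegment()] or a user-drawn region such as [ellipseMask()]).
#' @param plane the [ThresholdPlane-class] whose raw level defines the
#'   background to subtract; it should derive from this image's
#'   normalization.
#' @param mouseId,day identifiers carried into the result.
#' @param ... unused.
#' @return An [IntensityMeasurement-class].
#' @exportMethod measureRegion
setMethod("measureRegion",
  signature("RawImage", "RegionMask", "ThresholdPlane"),
  function(image, mask, plane, mouseId = NA_character_, day = NA_real_, ...) {
    if (!identical(dim(image@pixels), dim(mask@mask)))
      stop("congruence error: image and mask dimensions differ")
    m <- mask@mask
    area <- sum(m)
    if (area == 0L) {
      total <- net <- meanNet <- 0
      sat <- 0L
    } else {
      vals <- image@pixels[m]
      total <- sum(vals)
      net <- total - plane@rawLevel * area
      meanNet <- net / area
      sat <- sum(vals >= 2^image@bitDepth - 1)
    }
    new("IntensityMeasurement", totalRaw = total,
        backgroundRawLevel = plane@rawLevel, areaPx = as.integer(area),
        netTotal = net, meanNet = meanNet, saturatedInMask = as.integer(sat),
        units = image@units, mouseId = as.character(mouseId),
        day = as.numeric(day))
  })

#' Estimate background statistics over a tumour-free region
#'
#' Mirrors the workflow of drawing an ellipse over a region similar in
#' size to the tumour but containing only background signal (e.g. the
#' shoulder contralateral to the visible tumour), then summarizing the raw
#' counts in it.
#'
#' @param image a [RawImage-class].
#' @param region a non-empty [RegionMask-class].
#' @param ... unused.
#' @return A [BackgroundEstimate-class] with the region, its raw-unit mean
#'   and its sample (n-1) standard deviation (`NA` for a single pixel).
#' @exportMethod estimateBackground
setMethod("estimateBackground", signature("RawImage", "RegionMask"),
  function(image, region, ...) {
    if (!identical(dim(image@pixels), dim(region@mask)))
      stop("congruence error: image and region dimensions differ")
    vals <- image@pixels[region@mask]
    if (length(vals) == 0L)
      stop("degenerate input: empty background region")
    new("BackgroundEstimate", region = region, mean = mean(vals),
        sd = stats::sd(vals))
  })

#' Presence/absence call for a candidate signal region
#'
#' Declares a signal present when the mean raw intensity in the candidate
#' region exceeds the background mean by more than `k` background standard
#' deviations. This formalizes, with an explicit statistical rule, the
#' visual "was a tumour detected on this day" judgement; `k = 3` by
#' default.
#'
#' @param image a [RawImage-class].
#' @param candidate a non-empty [RegionMask-class] over the putative signal.
#' @param background a [BackgroundEstimate-class] from the same image (or a
#'   matched region on the same platform/settings).
#' @param k detection stringency in background standard deviations.
#' @param ... unused.
#' @return `TRUE` iff `mean(candidate) > background mean + k * background sd`.
#' @exportMethod detectSignal
setMethod("detectSignal",
  signature("RawImage", "RegionMask", "BackgroundEstimate"),
  function(image, candidate, background, k = 3, ...) {
    if (sum(candidate@mask) == 0L)
      stop("degenerate input: empty candidate region")
    if (is.na(background@sd))
      stop("degenerate input: background sd undefined (single-pixel region)")
    mean(image@pixels[candidate@mask]) >
      background@mean + k * background@sd
  })

#' Calliper tumour volume
#'
#' The standard external estimate of the volume of a palpable subcutaneous
#' tumour from calliper length and width: `length x width^2 / 2` (mm^3).
#'
#' @param length,width calliper measurements in mm; vectors recycle.
#'   Conventionally `length >= width`; a warning is issued otherwise.
#' @return Volume(s) in mm^3.
#' @examples
#' calliperVolume(10, 6)  # 180
#' @export
calliperVolume <- function(length, width) {
  if (any(length < 0) || any(width < 0))
    stop("domain error: calliper measurements must be non-negative")
  if (any(width > length))
    warning("width exceeds length; arguments may be swapped")
  length * width^2 / 2
}

#' Elliptical region mask
#'
#' Builds the elliptical region used for background estimation (the
#' "ellipse tool" of platform software): pixels inside the ellipse
#' `((row - centerRow)/radiusRow)^2 + ((col - centerCol)/radiusCol)^2 <= 1`.
#'
#' @param nrow,ncol mask dimensions.
#' @param centerRow,centerCol ellipse centre (1-based pixel coordinates).
#' @param radiusRow,radiusCol semi-axes in pixels.
#' @return A [RegionMask-class].
#' @export
ellipseMask <- function(nrow, ncol, centerRow, centerCol,
                        radiusRow, radiusCol = radiusRow) {
  stopifnot(radiusRow > 0, radiusCol > 0)
  r <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  RegionMask(((r - centerRow) / radiusRow)^2 +
             ((cc - centerCol) / radiusCol)^2 <= 1)
}

#' Disc mask centred on the image peak
#'
#' Convenience for phantom and recovery analyses: a circular region of
#' radius `radius` centred on the brightest pixel, emulating a user-drawn
#' tumour region guided by the 3D surface view.
#'
#' @param image a [RawImage-class].
#' @param radius disc radius in pixels.
#' @return A [RegionMask-class].
#' @export
peakDiscMask <- function(image, radius) {
  pk <- which(image@pixels == max(image@pixels), arr.ind = TRUE)[1, ]
  ellipseMask(nrow(image@pixels), ncol(image@pixels),
              pk[1], pk[2], radius, radius)
}
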