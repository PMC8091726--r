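#' @include image-io.R
NULL

#' Normalize a raw image to the unit interval
#'
#' Divides every pixel by the image maximum so that the brightest pixel is
#' exactly 1, producing the 3D intensity surface used for plane
#' thresholding. The raw maximum is retained so that any normalized level
#' can be converted back to raw units; all measurements are taken from the
#' raw counts, never from the normalized values.
#'
#' @param image a [RawImage-class] with at least one positive pixel.
#' @param ... unused.
#' @return A [NormalizedSurface-class].
#' @exportMethod normalizeImage
setMethod("normalizeImage", "RawImage", function(image, ...) {
  mx <- max(image@pixels)
  if (mx <= 0)
    stop("degenerate input: all-zero image cannot be normalized")
  new("NormalizedSurface", values = image@pixels / mx, rawMax = mx,
      source = image)
})

## Kapur maximum-entropy threshold on an nBins-uniform histogram of [0,1].
## Candidate cuts sit at the bin edges s/nBins, s = 1..nBins-1: the below
## partition holds bins 1..s, the above partition bins s+1..nBins. The
## selected cut maximizes the sum of the Shannon entropies of the two
## partitions' renormalized histograms; ties resolve to the lowest level
## (the most inclusive mask).
.kapurLevels <- function(values, nBins) {
  bin <- pmin(floor(values * nBins) + 1L, nBins)
  p <- tabulate(bin, nbins = nBins) / length(values)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)[-nBins]          # mass below each candidate cut
  Hc <- cumsum(-plogp)[-nBins]    # unnormalized entropy below
  Htot <- sum(-plogp)
  hb <- ifelse(P > 0, log(P) + Hc / P, 0)
  Pa <- 1 - P
  ha <- ifelse(Pa > 0, log(Pa) + (Htot - Hc) / Pa, 0)
  list(levels = seq_len(nBins - 1L) / nBins, objective = hb + ha)
}

#' Automatic plane threshold by maximum-entropy (Kapur) histogram cut
#'
#' Provides the initial height of the threshold plane through the 3D
#' intensity surface. The surface values are histogrammed into `nBins`
#' uniform bins on `[0, 1]`; the returned level is the bin edge that
#' maximizes the sum of Shannon entropies of the below- and above-threshold
#' partitions (Kapur's criterion). Ties are broken towards the lowest
#' level. The level is an *initial value*: the plane can subsequently be
#' adjusted with [thresholdPlane()], exactly as an analyst would nudge the
#' plane until it transcribes the tumour boundary.
#'
#' @param surface a [NormalizedSurface-class] with at least two distinct
#'   values (a constant surface has no meaningful cut).
#' @param nBins number of histogram bins (default 256).
#' @param ... unused.
#' @return A [ThresholdPlane-class] with `method = "auto_entropy"`.
#' @references Kapur, J.N., Sahoo, P.K., Wong, A.K.C. (1985) A new method
#'   for gray-level picture thresholding using the entropy of the
#'   histogram. Computer Vision, Graphics, and Image Processing 29(3).
#' @exportMethod entropyThreshold
setMethod("entropyThreshold", "NormalizedSurface",
  function(surface, nBins = 256L, ...) {
    nBins <- as.integer(nBins)
    stopifnot(nBins >= 2L)
    v <- as.vector(surface@values)
    if (length(unique(v)) < 2L)
      stop("degenerate input: constant surface has no threshold")
    k <- .kapurLevels(v, nBins)
    best <- which.max(k$objective)   # which.max takes the first (lowest) tie
    level <- k$levels[best]
    new("ThresholdPlane", level = level, rawLevel = level * surface@rawMax,
        method = "auto_entropy")
  })

#' Cut the intensity surface with a horizontal plane
#'
#' Pixels strictly above the plane level are signal; pixels at or below it
#' are background/noise. The signal region's boundary (4-connectivity) is
#' extracted for visualization, delineating the tumour outline the plane
#' transcribes on the surface.
#'
#' @param surface a [NormalizedSurface-class].
#' @param plane a [ThresholdPlane-class] (or a bare numeric level in
#'   `[0, 1]`, treated as a manual plane).
#' @param largestComponent if `TRUE`, restrict the mask to its largest
#'   4-connected component (useful when the crop contains stray bright
#'   specks); off by default because images are already cropped to the
#'   tumour neighbourhood. Uses `EBImage::bwlabel`.
#' @param ... unused.
#' @return A [RegionMask-class].
#' @exportMethod planeSegment
setMethod("planeSegment", signature("NormalizedSurface", "ThresholdPlane"),
  function(surface, plane, largestComponent = FALSE, ...) {
    mask <- surface@values > plane@level
    if (largestComponent && any(mask)) {
      lab <- EBImage::bwlabel(mask)
      keep <- which.max(tabulate(lab[lab > 0]))
      mask <- lab == keep
      message("planeSegment: restricted mask to largest connected component")
    }
    RegionMask(mask)
  })

#' @rdname planeSegment
setMethod("planeSegment", signature("NormalizedSurface", "numeric"),
  function(surface, plane, ...) {
    planeSegment(surface, thresholdPlane(surface, level = plane), ...)
  })

#' Export the surface, plane and boundary for 3D rendering
#'
#' Builds a plotting-backend-agnostic export of the 3D intensity plot:
#' one vertex per pixel (`x` = column, `y` = row, `z` = normalized value),
#' the plane level in both normalized and raw units, and the signal
#' boundary as polyline(s) traced at half-pixel resolution. The grid values
#' are carried losslessly; rendering is left to the caller's backend.
#'
#' @param surface a [NormalizedSurface-class].
#' @param plane a [ThresholdPlane-class].
#' @param ... unused.
#' @return A list with `vertices` (data.frame `x`, `y`, `z`), `grid` (the
#'   value matrix), `level`, `rawLevel`, `rawMax`, `method` and
#'   `boundary` (list of data.frames with `x`, `y`).
#' @seealso [writeSurfaceExport()] for the CSV + JSON on-disk form.
#' @exportMethod surfaceExport
setMethod("surfaceExport", signature("NormalizedSurface", "ThresholdPlane"),
  function(surface, plane, ...) {
    v <- surface@values
    idx <- expand.grid(y = seq_len(nrow(v)), x = seq_len(ncol(v)))
    mask <- v > plane@level
    cl <- grDevices::contourLines(x = seq_len(nrow(v)), y = seq_len(ncol(v)),
                                  z = mask + 0, levels = 0.5)
    boundary <- lapply(cl, function(b) data.frame(x = b$y, y = b$x))
    list(
      vertices = data.frame(x = idx$x, y = idx$y,
                            z = v[cbind(idx$y, idx$x)]),
      grid = v, level = plane@level, rawLevel = plane@rawLevel,
      rawMax = surface@rawMax, method = plane@method, boundary = boundary
    )
  })

#' Write / read a surface export as CSV grid + JSON metadata
#'
#' `writeSurfaceExport()` stores the normalized grid as a headerless CSV
#' and the plane metadata (level, raw level, raw max, method, platform,
#' units, bit depth) as a JSON sidecar. `readSurfaceExport()` reverses the
#' operation, reproducing the surface grid exactly up to the full double
#' precision written.
#'
#' @param surface a [NormalizedSurface-class].
#' @param plane a [ThresholdPlane-class].
#' @param prefix output path prefix; writes `<prefix>_surface.csv` and
#'   `<prefix>_surface.json`.
#' @return `writeSurfaceExport()`: the two paths, invisibly.
#'   `readSurfaceExport()`: a list with `surface` (a
#'   [NormalizedSurface-class]) and `plane` (a [ThresholdPlane-class]).
#' @export
writeSurfaceExport <- function(surface, plane, prefix) {
  csv <- paste0(prefix, "_surface.csv")
  js <- paste0(prefix, "_surface.json")
  utils::write.table(format(surface@values, digits = 17, trim = TRUE),
                     csv, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  src <- surface@source
  jsonlite::write_json(list(
    level = plane@level, raw_level = plane@rawLevel, method = plane@method,
    raw_max = surface@rawMax, platform = src@platform, units = src@units,
    bit_depth = src@bitDepth
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' @rdname writeSurfaceExport
#' @export
readSurfaceExport <- function(prefix) {
  csv <- paste0(prefix, "_surface.csv")
  js <- paste0(prefix, "_surface.json")
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(csv, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  raw <- RawImage(round(vals * meta$raw_max), bitDepth = meta$bit_depth,
                  platform = meta$platform, units = meta$units)
  surface <- new("NormalizedSurface", values = vals, rawMax = meta$raw_max,
                 source = raw)
  plane <- new("ThresholdPlane", level = meta$level,
               rawLevel = meta$raw_level, method = meta$method)
  list(surface = surface, plane = plane)
}

#' Write a RegionMask as a 0/255 PNG and a run-length CSV
#'
#' @param mask a [RegionMask-class].
#' @param prefix output path prefix; writes `<prefix>_mask.png` and
#'   `<prefix>_mask_rle.csv` (columns `value`, `length`, in column-major
#'   run order, plus the dimensions on the first row comment-free via
#'   `nrow`/`ncol` columns).
#' @return The two paths, invisibly.
#' @export
writeMask <- function(mask, prefix) {
  pngPath <- paste0(prefix, "_mask.png")
  csvPath <- paste0(prefix, "_mask_rle.csv")
  png::writePNG(mask@mask + 0, pngPath)
  r <- rle(as.vector(mask@mask))
  utils::write.csv(data.frame(value = as.integer(r$values),
                              length = r$lengths,
                              nrow = nrow(mask@mask), ncol = ncol(mask@mask)),
                   csvPath, row.names = FALSE)
  invisible(c(pngPath, csvPath))
}

#' @rdname writeMask
#' @export
readMaskRle <- function(csvPath) {
  d <- utils::read.csv(csvPath)
  v <- inverse.rle(structure(list(lengths = d$length,
                                  values = as.logical(d$value)),
                             class = "rle"))
  RegionMask(matrix(v, nrow = d$nrow[1], ncol = d$ncol[1]))
}
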