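#' @include accessors.R
NULL

## On-disk convention: logical bit depths up to 16 are stored as 16-bit
## unsigned TIFF; deeper data (the LPT's 22-bit) go into the 32-bit
## container. In both cases the stored sample equals the integer count
## after the container rescaling, so read(write(x)) is bit-exact.

.containerBits <- function(bitDepth) if (bitDepth <= 16L) 16L else 32L

#' Read a raw single-channel imaging TIFF
#'
#' Reads the unscaled sample values of a grayscale TIFF exported from an
#' imaging platform. Multi-channel (RGB) files are rejected, as are files
#' whose values exceed the declared bit-depth ceiling `2^bitDepth - 1`
#' (an integrity failure: the file cannot be what it is declared to be).
#'
#' @param path path to a single-channel grayscale TIFF.
#' @param bitDepth logical detector bit depth (16 for XVI/BIX-like data,
#'   22 for LPT-like data stored in a 32-bit container).
#' @param platform,units metadata tags attached to the result.
#' @return A [RawImage-class].
#' @seealso [writeRawTiff()]
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeRawTiff(RawImage(matrix(0:3, 2, 2)), f)
#' readRawTiff(f)
#' @export
readRawTiff <- function(path, bitDepth = 16L, platform = "generic",
                        units = "counts") {
  if (!file.exists(path)) stop("file not found: ", path)
  bitDepth <- as.integer(bitDepth)
  raw <- tiff::readTIFF(path, as.is = TRUE, convert = FALSE)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] > 1L)
      stop("unsupported format: multi-channel TIFF (", dim(raw)[3],
           " channels); a single-channel grayscale image is required")
    raw <- raw[, , 1L]
  }
  if (bitDepth > 16L) {
    # 32-bit container: readTIFF rescales to [0,1]; undo with the logical
    # ceiling. Exact for integer counts because the container resolution
    # (2^32-1 steps) far exceeds the 22-bit grid.
    scaled <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(scaled)) == 3L) scaled <- scaled[, , 1L]
    raw <- round(scaled * (2^bitDepth - 1))
  }
  ceiling_ <- 2^bitDepth - 1
  if (any(raw > ceiling_))
    stop(sprintf(
      "integrity error: value %.0f exceeds the declared %d-bit ceiling %.0f",
      max(raw), bitDepth, ceiling_))
  RawImage(raw, bitDepth = bitDepth, platform = platform, units = units)
}

#' Write a RawImage as a grayscale TIFF
#'
#' Logical bit depths up to 16 are written as 16-bit unsigned TIFF; deeper
#' data are written into the 32-bit container. Re-reading with
#' [readRawTiff()] at the same declared bit depth reproduces the counts
#' bit-exactly.
#'
#' @param image a [RawImage-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRawTiff <- function(image, path) {
  stopifnot(is(image, "RawImage"))
  validObject(image)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write to ", path, ": no such directory")
  bits <- .containerBits(image@bitDepth)
  # 16-bit container stores round(x * 65535); dividing by 65535 makes the
  # stored sample equal the count itself. The 32-bit container rescales by
  # 2^32-1, exact on the 22-bit integer grid after the back-conversion.
  denom <- if (bits == 16L) 65535 else 2^image@bitDepth - 1
  ok <- tiff::writeTIFF(image@pixels / denom, path, bits.per.sample = bits,
                        reduce = FALSE)
  if (!isTRUE(ok == 1)) stop("failed to write TIFF: ", path)
  invisible(path)
}

#' @describeIn cropImage Crop a RawImage to a 0-based half-open box;
#'   pixel values and metadata are copied unchanged.
#' @param image a [RawImage-class].
#' @param box a [CropBox-class] (0-based, half-open, rows then columns).
#' @param ... unused.
#' @return `cropImage`: a [RawImage-class] of dimensions
#'   `(rowStop - rowStart, colStop - colStart)`.
#' @examples
#' img <- RawImage(matrix(1:12, 3, 4))
#' dim(cropImage(img, CropBox(0, 2, 1, 3)))
#' @exportMethod cropImage
setMethod("cropImage", signature("RawImage", "CropBox"),
  function(image, box, ...) {
    validObject(box)
    d <- dim(image@pixels)
    if (box@rowStop > d[1] || box@colStop > d[2])
      stop(sprintf("crop box [%d,%d)x[%d,%d) out of bounds for %dx%d image",
                   box@rowStart, box@rowStop, box@colStart, box@colStop,
                   d[1], d[2]))
    RawImage(image@pixels[(box@rowStart + 1L):box@rowStop,
                          (box@colStart + 1L):box@colStop, drop = FALSE],
             bitDepth = image@bitDepth, platform = image@platform,
             units = image@units)
  })

#' @describeIn cropImage Convenience: box given as `c(rowStart, rowStop,
#'   colStart, colStop)`.
setMethod("cropImage", signature("RawImage", "numeric"),
  function(image, box, ...) {
    stopifnot(length(box) == 4L)
    cropImage(image, CropBox(box[1], box[2], box[3], box[4]))
  })

#' Sum-bin an image in k x k blocks
#'
#' Each output pixel is the *sum* of its `k x k` source block, mirroring
#' detector binning: 8 x 8 binning multiplies per-pixel signal by 64
#' relative to no binning. Total image intensity is conserved. If block
#' sums exceed the bit-depth ceiling they are either clipped
#' (`clip = TRUE`) or the logical bit depth is widened with a warning
#' (`clip = FALSE`, the default), keeping the sums exact.
#'
#' @param image a [RawImage-class]; `k` must divide both dimensions
#'   (non-divisible inputs are rejected so that sums stay exact).
#' @param k integer block edge, `>= 1`.
#' @param clip if `TRUE`, clip sums at `2^bitDepth - 1` instead of widening
#'   the container.
#' @param ... unused.
#' @return A [RawImage-class] with dimensions `dim(image) / k`.
#' @examples
#' img <- RawImage(matrix(1, 16, 16))
#' max(pixels(binImage(img, 8)))  # 64
#' @exportMethod binImage
setMethod("binImage", signature("RawImage", "numeric"),
  function(image, k, clip = FALSE, ...) {
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    if (k == 1L) return(image)
    d <- dim(image@pixels)
    if (d[1] %% k != 0L || d[2] %% k != 0L)
      stop(sprintf("shape error: k = %d does not divide %dx%d", k, d[1], d[2]))
    m <- d[1] %/% k; n <- d[2] %/% k
    # fold rows then columns: column-major reshape keeps blocks contiguous
    p <- image@pixels
    dim(p) <- c(k, m, d[2])
    rows <- colSums(p)                    # m x ncol, summed within row-blocks
    rows <- t(rows)                       # ncol x m
    dim(rows) <- c(k, n, m)
    out <- t(colSums(rows))               # m x n block sums
    bd <- image@bitDepth
    ceiling_ <- 2^bd - 1
    if (any(out > ceiling_)) {
      if (clip) {
        out <- pmin(out, ceiling_)
      } else {
        bd <- min(c(16L, 22L, 32L)[c(16L, 22L, 32L) >= ceiling(log2(max(out) + 1))])
        warning(sprintf(
          "binned sums exceed the %d-bit ceiling; widening to %d-bit container",
          image@bitDepth, bd))
      }
    }
    RawImage(out, bitDepth = bd, platform = image@platform,
             units = image@units)
  })

#' Flag saturated (ceiling-valued) pixels
#'
#' A pixel is saturated when it equals the bit-depth ceiling
#' `2^bitDepth - 1`, i.e. the detector clipped the signal. Saturated
#' regions invalidate intensity comparisons and should be screened before
#' quantification.
#'
#' @param image a [RawImage-class].
#' @param ... unused.
#' @return A list with `count` (number of saturated pixels) and `mask`
#'   (a [RegionMask-class] of the saturated pixels).
#' @exportMethod detectSaturation
setMethod("detectSaturation", "RawImage", function(image, ...) {
  sat <- image@pixels >= 2^image@bitDepth - 1
  list(count = sum(sat), mask = RegionMask(sat))
})
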