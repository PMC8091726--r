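#' @include series-stats.R
NULL

## Synthetic scenes with the structure the analysis assumes: an imaging-bed
## background, a mouse-body plateau clearly above it (as seen on
## high-dynamic-range platforms), smooth Gaussian tumour blobs, additive
## detector noise, integer rounding and bit-depth clipping. Every generator
## is deterministic given a seed and emits its ground truth alongside, so
## recovery tests never depend on the pipeline under test.

# Evaluate an expression with a temporary RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.defaultBodyMask <- function(nrow, ncol) {
  ellipseMask(nrow, ncol, centerRow = nrow / 2, centerCol = ncol / 2,
              radiusRow = 0.40 * nrow, radiusCol = 0.34 * ncol)@mask
}

.gaussianBlob <- function(nrow, ncol, row, col, sigma, amplitude) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  cc <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  amplitude * exp(-((r - row)^2 + (cc - col)^2) / (2 * sigma^2))
}

#' Generate a synthetic mouse image with ground truth
#'
#' Renders a bed-level background, a mouse-body plateau and Gaussian
#' tumour blobs, adds seeded Gaussian detector noise, rounds to integer
#' counts and clips at the bit-depth ceiling. The returned ground truth
#' holds the exact (pre-rounding, pre-clipping) discrete blob integrals,
#' the plateau levels and the body mask.
#'
#' @param nrow,ncol image dimensions (default 96 x 96, a tumour-
#'   neighbourhood crop size).
#' @param bedLevel imaging-bed background level in counts (default 500).
#' @param bodyLevel mouse-body plateau level in counts (default 2000;
#'   must exceed `bedLevel`).
#' @param bodyMask logical matrix marking the body; default a centred
#'   ellipse covering most of the frame.
#' @param tumours data.frame with columns `row`, `col`, `sigma`,
#'   `amplitude` (one Gaussian blob per row); may be empty.
#' @param noiseSd additive Gaussian noise sd in counts (default 20).
#' @param noiseModel `"gaussian"` (default) or `"poisson"` (counts drawn
#'   as Poisson with the noiseless scene as mean; `noiseSd` ignored).
#' @param bitDepth detector bit depth; levels must fit the range.
#' @param seed integer seed; identical seeds give identical images.
#' @return A list: `image` (a [RawImage-class]) and `truth` (list with
#'   `blobIntegrals`, `bedLevel`, `bodyLevel`, `bodyMask`, `truePeak`,
#'   `clipped`).
#' @export
simMouseImage <- function(nrow = 96, ncol = 96, bedLevel = 500,
                          bodyLevel = 2000, bodyMask = NULL,
                          tumours = data.frame(), noiseSd = 20,
                          noiseModel = c("gaussian", "poisson"),
                          bitDepth = 16L, seed = NULL) {
  noiseModel <- match.arg(noiseModel)
  ceiling_ <- 2^bitDepth - 1
  if (bodyLevel <= bedLevel)
    stop("bodyLevel must exceed bedLevel (the body plateau sits above the bed)")
  if (bedLevel < 0 || bodyLevel > ceiling_)
    stop("domain error: plateau levels outside the bit-depth range")
  if (is.null(bodyMask)) bodyMask <- .defaultBodyMask(nrow, ncol)
  scene <- matrix(bedLevel, nrow, ncol)
  scene[bodyMask] <- bodyLevel
  blobIntegrals <- numeric(0)
  if (nrow(tumours) > 0L) {
    if (any(tumours$amplitude < 0) || any(tumours$sigma <= 0))
      stop("domain error: amplitudes must be >= 0 and sigma > 0")
    blobIntegrals <- numeric(nrow(tumours))
    for (i in seq_len(nrow(tumours))) {
      blob <- .gaussianBlob(nrow, ncol, tumours$row[i], tumours$col[i],
                            tumours$sigma[i], tumours$amplitude[i])
      blobIntegrals[i] <- sum(blob)
      scene <- scene + blob
    }
  }
  truePeak <- max(scene)
  img <- .withSeed(seed, {
    noisy <- switch(noiseModel,
      gaussian = scene + if (noiseSd > 0)
        stats::rnorm(length(scene), 0, noiseSd) else 0,
      poisson = stats::rpois(length(scene), scene))
    matrix(pmin(pmax(round(noisy), 0), ceiling_), nrow, ncol)
  })
  list(image = RawImage(img, bitDepth = bitDepth, units = "counts",
                        platform = "synthetic"),
       truth = list(blobIntegrals = blobIntegrals, bedLevel = bedLevel,
                    bodyLevel = bodyLevel, bodyMask = bodyMask,
                    truePeak = truePeak, clipped = truePeak > ceiling_))
}

#' Generate a synthetic serial-dilution plate
#'
#' Replicate well signals decay geometrically from `topSignal` on top of a
#' common background, with seeded Gaussian well noise:
#' `signal(d) = background + topSignal * step^-(d-1) + noise`.
#' Background wells carry noise only. The analytic detection crossing is
#' computable from the parameters (`topSignal * factor` against
#' `k * noiseSd`).
#'
#' @param topSignal raw signal of the least dilute wells above background
#'   (default 10000).
#' @param nDilutions number of dilutions (default 6, spanning a 10^5
#'   dynamic range at tenfold steps).
#' @param step dilution step (default 10, tenfold).
#' @param replicates wells per dilution (default 3, triplicates).
#' @param nBackground background wells (default 6).
#' @param background background level in counts (default 500).
#' @param noiseSd well noise sd in counts (default 20).
#' @param seed integer seed.
#' @return A list: `series` (a [DilutionSeries-class]) and `truth`
#'   (list with `expectedMeans`, `dilutionFactors`, `background`,
#'   `topSignal`, `noiseSd`).
#' @export
simDilutionPlate <- function(topSignal = 10000, nDilutions = 6, step = 10,
                             replicates = 3, nBackground = 6,
                             background = 500, noiseSd = 20, seed = NULL) {
  stopifnot(topSignal > background, background >= 0, nDilutions >= 2)
  factors <- step^-(seq_len(nDilutions) - 1)
  expected <- background + topSignal * factors
  .withSeed(seed, {
    reps <- lapply(expected, function(mu)
      mu + if (noiseSd > 0) stats::rnorm(replicates, 0, noiseSd) else
        numeric(replicates))
    bg <- background + if (noiseSd > 0)
      stats::rnorm(nBackground, 0, noiseSd) else numeric(nBackground)
    list(series = DilutionSeries(factors, reps, bg),
         truth = list(expectedMeans = expected, dilutionFactors = factors,
                      background = background, topSignal = topSignal,
                      noiseSd = noiseSd))
  })
}

#' Generate a phantom-mouse repositioning series
#'
#' Repeated single-blob scenes in which the blob amplitude varies by
#' seeded multiplicative (log-normal) jitter and its position by uniform
#' shifts, emulating random repositioning of a phantom mouse between
#' acquisitions. The realized amplitudes and their coefficient of variance
#' are recorded as ground truth.
#'
#' @param baseSignal median blob amplitude in counts (default 2000).
#' @param jitterFraction multiplicative jitter scale (log-normal sigma);
#'   the amplitude CV is approximately `100 * jitterFraction` percent.
#'   Position shifts are uniform within `+/- 40 * jitterFraction` pixels.
#' @param nRepeats number of acquisitions (default 12).
#' @param sigma blob sd in pixels (default 4).
#' @param noiseSd detector noise sd in counts (default 5; the phantom is a
#'   bright static object, so noise is low relative to signal).
#' @param seed integer seed.
#' @param ... further scene parameters passed to [simMouseImage()].
#' @return A list: `images` (list of [RawImage-class]), `truth` (list with
#'   `amplitudes`, `cvPercent`, `centers`).
#' @export
simPhantomSeries <- function(baseSignal = 2000, jitterFraction = 0.2,
                             nRepeats = 12, sigma = 4, noiseSd = 5,
                             seed = NULL, ...) {
  stopifnot(jitterFraction >= 0, jitterFraction < 1, nRepeats >= 1)
  .withSeed(seed, {
    amps <- baseSignal * exp(stats::rnorm(nRepeats, 0, jitterFraction))
    maxShift <- 40 * jitterFraction
    dr <- round(stats::runif(nRepeats, -maxShift, maxShift))
    dc <- round(stats::runif(nRepeats, -maxShift, maxShift))
    images <- vector("list", nRepeats)
    centers <- cbind(row = 48 + dr, col = 48 + dc)
    for (i in seq_len(nRepeats)) {
      sc <- simMouseImage(
        tumours = data.frame(row = centers[i, 1], col = centers[i, 2],
                             sigma = sigma, amplitude = amps[i]),
        noiseSd = noiseSd,
        seed = sample.int(.Machine$integer.max, 1), ...)
      images[[i]] <- sc$image
    }
    list(images = images,
         truth = list(amplitudes = amps,
                      cvPercent = if (nRepeats > 1)
                        coefficientOfVariance(amps) else 0,
                      centers = centers))
  })
}

#' Generate a longitudinal tumour-growth timecourse
#'
#' A single blob growing exponentially over an imaging schedule:
#' amplitude on day `d` is `initialAmplitude * exp(rate * (d - days[1]))`.
#' Optional clipping (via the scene bit depth) emulates detector
#' saturation on the brightest days.
#'
#' @param days imaging days, strictly increasing (default the 14/17/21/24
#'   twice-weekly schedule).
#' @param initialAmplitude blob amplitude on the first day (default 500
#'   counts).
#' @param rate per-day exponential growth rate (default `log(2)/3.5`,
#'   a doubling every 3.5 days).
#' @param sigma blob sd in pixels (default 4).
#' @param row,col blob centre (default the body centre).
#' @param noiseSd detector noise sd in counts (default 0, noiseless).
#' @param seed integer seed.
#' @param ... further scene parameters passed to [simMouseImage()]
#'   (e.g. `bitDepth` to force saturation).
#' @return A list with one element per day: `day`, `image` (a
#'   [RawImage-class]), `trueAmplitude`, `trueBlobIntegral`.
#' @export
simGrowthTimecourse <- function(days = c(14, 17, 21, 24),
                                initialAmplitude = 500,
                                rate = log(2) / 3.5, sigma = 4,
                                row = 48, col = 48, noiseSd = 0,
                                seed = NULL, ...) {
  stopifnot(length(days) >= 1, all(diff(days) > 0), is.finite(rate))
  .withSeed(seed, {
    lapply(days, function(d) {
      amp <- initialAmplitude * exp(rate * (d - days[1]))
      sc <- simMouseImage(
        tumours = data.frame(row = row, col = col, sigma = sigma,
                             amplitude = amp),
        noiseSd = noiseSd,
        seed = sample.int(.Machine$integer.max, 1), ...)
      list(day = d, image = sc$image, trueAmplitude = amp,
           trueBlobIntegral = sc$truth$blobIntegrals[1])
    })
  })
}
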