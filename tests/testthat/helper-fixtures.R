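# Shared fixture builders. Everything is generated in code; no binary
# fixtures on disk.

# A seeded random raw image with values drawn uniformly on [0, maxVal].
randomImage <- function(seed, nrow = 16, ncol = 16, maxVal = 999,
                        bitDepth = 16L) {
  set.seed(seed)
  RawImage(matrix(sample(0:maxVal, nrow * ncol, replace = TRUE), nrow, ncol),
           bitDepth = bitDepth)
}

# Independent brute-force Kapur objective: for each candidate cut, build
# the two partitions explicitly and sum their Shannon entropies.
bruteForceEntropyLevel <- function(values, nBins = 256L) {
  bin <- pmin(floor(values * nBins) + 1L, nBins)
  p <- tabulate(bin, nbins = nBins) / length(values)
  shannon <- function(q) {
    q <- q[q > 0]
    if (length(q) == 0L) return(0)
    q <- q / sum(q)
    -sum(q * log(q))
  }
  obj <- vapply(seq_len(nBins - 1L), function(s) {
    below <- p[1:s]; above <- p[(s + 1L):nBins]
    (if (sum(below) > 0) shannon(below) else 0) +
      (if (sum(above) > 0) shannon(above) else 0)
  }, 0)
  which.max(obj) / nBins
}

# Measure one growth-timecourse frame with the plane at the body plateau.
# maskType "plane" uses the segmentation mask (noiseless work); "disc"
# uses a user-style fixed disc at the peak (noisy work).
measureFrame <- function(frame, bodyLevel = 2000, maskType = c("plane", "disc"),
                         discRadius = 12) {
  maskType <- match.arg(maskType)
  surf <- normalizeImage(frame$image)
  plane <- thresholdPlane(surf, rawLevel = bodyLevel)
  mask <- if (maskType == "plane") planeSegment(surf, plane) else
    peakDiscMask(frame$image, discRadius)
  d <- as.data.frame(measureRegion(frame$image, mask, plane,
                                   mouseId = "m", day = frame$day))
  d
}

timecourseMeasurements <- function(tc, ...) {
  do.call(rbind, lapply(tc, measureFrame, ...))
}
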