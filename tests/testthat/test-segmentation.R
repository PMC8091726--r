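# Normalization, maximum-entropy plane threshold, plane segmentation and
# surface export.

test_that("normalization divides by the raw maximum and is idempotent", {
  img <- RawImage(matrix(c(100, 400, 200, 50), 2, 2))
  surf <- normalizeImage(img)
  expect_equal(surfaceValues(surf),
               matrix(c(0.25, 1, 0.5, 0.125), 2, 2))
  expect_equal(rawMax(surf), 400)
  # constant image: all values map to 1
  expect_true(all(surfaceValues(normalizeImage(RawImage(matrix(7, 3, 3)))) == 1))
  # all-zero image is degenerate
  expect_error(normalizeImage(RawImage(matrix(0, 2, 2))), "degenerate")
  # renormalizing an integer rescale of the surface changes nothing
  for (seed in 1:4) {
    x <- randomImage(seed, 12, 12)
    s1 <- surfaceValues(normalizeImage(x))
    x2 <- RawImage(pixels(x) * 3)   # positive rescale, no clipping
    expect_equal(surfaceValues(normalizeImage(x2)), s1)
  }
})

test_that("entropy threshold equals the exhaustive-search oracle", {
  for (seed in 1:8) {
    surf <- normalizeImage(randomImage(seed, 32, 32))
    pl <- entropyThreshold(surf)
    expect_equal(planeLevel(pl),
                 bruteForceEntropyLevel(as.vector(surfaceValues(surf))))
    expect_equal(rawLevel(pl), planeLevel(pl) * rawMax(surf))
    expect_identical(pl@method, "auto_entropy")
  }
  # a coarser histogram is honoured
  surf <- normalizeImage(randomImage(99, 32, 32))
  expect_equal(planeLevel(entropyThreshold(surf, nBins = 64)),
               bruteForceEntropyLevel(as.vector(surfaceValues(surf)), 64L))
})

test_that("bimodal images are separated and constant surfaces rejected", {
  p <- matrix(0, 10, 10); p[, 6:10] <- 1000
  surf <- normalizeImage(RawImage(p))
  pl <- entropyThreshold(surf)
  expect_gt(planeLevel(pl), 0)
  expect_lt(planeLevel(pl), 1)
  mask <- planeSegment(surf, pl)
  expect_identical(maskMatrix(mask), p == 1000)
  expect_error(entropyThreshold(normalizeImage(RawImage(matrix(5, 4, 4)))),
               "degenerate")
})

test_that("the auto threshold is invariant to positive rescaling of the raw image", {
  for (seed in 1:5) {
    x <- randomImage(seed, 24, 24, maxVal = 5000)
    l1 <- planeLevel(entropyThreshold(normalizeImage(x)))
    l2 <- planeLevel(entropyThreshold(normalizeImage(RawImage(pixels(x) * 7))))
    expect_equal(l1, l2)
  }
})

test_that("plane segmentation is a strict cut with a 4-connected boundary", {
  surf <- normalizeImage(randomImage(13, 20, 20))
  # floor cut keeps everything positive; ceiling cut keeps nothing
  expect_equal(nPixels(planeSegment(surf, 0)), sum(surfaceValues(surf) > 0))
  expect_equal(nPixels(planeSegment(surf, 1)), 0)
  # counting oracle at an interior level
  mask <- planeSegment(surf, 0.4)
  expect_equal(nPixels(mask), sum(surfaceValues(surf) > 0.4))
  # boundary: every boundary pixel is in the mask and touches background/edge
  b <- maskBoundary(mask)
  m <- maskMatrix(mask)
  for (i in seq_len(nrow(b))) {
    r <- b[i, 1]; c <- b[i, 2]
    expect_true(m[r, c])
    nbrs <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    atEdge <- any(nbrs[, 1] < 1 | nbrs[, 1] > nrow(m) |
                  nbrs[, 2] < 1 | nbrs[, 2] > ncol(m))
    inside <- nbrs[nbrs[, 1] >= 1 & nbrs[, 1] <= nrow(m) &
                   nbrs[, 2] >= 1 & nbrs[, 2] <= ncol(m), , drop = FALSE]
    expect_true(atEdge || any(!m[inside]))
  }
})

test_that("raising the plane never adds pixels to the mask", {
  for (seed in 1:5) {
    surf <- normalizeImage(randomImage(seed + 40, 24, 24))
    levels <- sort(runif(4))
    masks <- lapply(levels, function(l) maskMatrix(planeSegment(surf, l)))
    for (i in seq_len(3))
      expect_true(all(masks[[i + 1]] <= masks[[i]]))
  }
})

test_that("segmentation masks are invariant to positive raw rescaling", {
  for (seed in 1:5) {
    x <- randomImage(seed + 60, 24, 24, maxVal = 4000)
    s1 <- normalizeImage(x)
    s2 <- normalizeImage(RawImage(pixels(x) * 5))
    pl <- entropyThreshold(s1)
    expect_identical(maskMatrix(planeSegment(s1, pl)),
                     maskMatrix(planeSegment(s2, entropyThreshold(s2))))
  }
})

test_that("largest-component filtering keeps the biggest blob only", {
  p <- matrix(0, 12, 12)
  p[2:5, 2:5] <- 100      # 16 px component
  p[9:10, 9:10] <- 100    # 4 px component
  surf <- normalizeImage(RawImage(p))
  expect_message(
    mask <- planeSegment(surf, 0.5, largestComponent = TRUE),
    "largest connected component")
  expect_equal(nPixels(mask), 16)
})

test_that("surface export is lossless and round-trips through CSV + JSON", {
  surf <- normalizeImage(randomImage(17, 8, 10))
  pl <- entropyThreshold(surf)
  ex <- surfaceExport(surf, pl)
  # 2x2 direct mapping of vertices
  small <- normalizeImage(RawImage(matrix(c(1, 2, 3, 4), 2, 2)))
  exs <- surfaceExport(small, thresholdPlane(small, level = 0.5))
  expect_equal(sort(exs$vertices$z), sort(as.vector(surfaceValues(small))))
  expect_equal(exs$level, 0.5)
  # full-grid vertices agree with the matrix
  expect_equal(ex$vertices$z,
               surfaceValues(surf)[cbind(ex$vertices$y, ex$vertices$x)])
  expect_equal(ex$grid, surfaceValues(surf))
  # disk round trip
  prefix <- file.path(withr::local_tempdir(), "surf")
  writeSurfaceExport(surf, pl, prefix)
  back <- readSurfaceExport(prefix)
  expect_equal(surfaceValues(back$surface), surfaceValues(surf))
  expect_equal(rawMax(back$surface), rawMax(surf))
  expect_equal(planeLevel(back$plane), planeLevel(pl))
  expect_identical(back$plane@method, "auto_entropy")
})

test_that("mask export round-trips through the run-length CSV", {
  surf <- normalizeImage(randomImage(23, 15, 9))
  mask <- planeSegment(surf, 0.5)
  prefix <- file.path(withr::local_tempdir(), "m")
  paths <- writeMask(mask, prefix)
  expect_true(all(file.exists(paths)))
  back <- readMaskRle(paths[2])
  expect_identical(maskMatrix(back), maskMatrix(mask))
})
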