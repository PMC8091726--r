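# Raw-unit measurement with plane-level background subtraction, background
# estimation, detection calls and calliper volume.

test_that("measureRegion implements plane-level background subtraction", {
  img <- RawImage(matrix(50, 6, 6))
  surf <- normalizeImage(img)
  plane <- thresholdPlane(surf, rawLevel = 50)
  full <- RegionMask(matrix(TRUE, 6, 6))
  m <- measureRegion(img, full, plane)
  expect_equal(m@netTotal, 0)
  expect_equal(m@totalRaw, 50 * 36)
  # empty mask: all totals zero
  m0 <- measureRegion(img, RegionMask(matrix(FALSE, 6, 6)), plane)
  expect_equal(m0@totalRaw, 0)
  expect_equal(m0@netTotal, 0)
  expect_equal(m0@areaPx, 0L)
  # shape mismatch is a congruence error
  expect_error(measureRegion(img, RegionMask(matrix(TRUE, 3, 3)), plane),
               "congruence")
})

test_that("noiseless blob net totals match the discrete-integral oracle", {
  sc <- simMouseImage(noiseSd = 0, seed = 1,
                      tumours = data.frame(row = 48, col = 48, sigma = 4,
                                           amplitude = 2000))
  img <- sc$image
  surf <- normalizeImage(img)
  plane <- thresholdPlane(surf, rawLevel = sc$truth$bodyLevel)
  mask <- planeSegment(surf, plane)
  m <- measureRegion(img, mask, plane)
  # independent summation oracle: add up (pixel - plateau) over the mask
  oracle <- sum((pixels(img) - sc$truth$bodyLevel)[maskMatrix(mask)])
  expect_equal(m@netTotal, oracle)
  # and the truth blob integral is recovered up to rounding/truncation
  expect_lt(abs(m@netTotal - sc$truth$blobIntegrals[1]) /
              sc$truth$blobIntegrals[1], 0.005)
  expect_equal(m@saturatedInMask, 0L)
})

test_that("net totals increase strictly with blob amplitude (noiseless)", {
  nets <- vapply(c(500, 1000, 2000, 4000), function(a) {
    sc <- simMouseImage(noiseSd = 0, seed = 1,
                        tumours = data.frame(row = 48, col = 48, sigma = 4,
                                             amplitude = a))
    surf <- normalizeImage(sc$image)
    plane <- thresholdPlane(surf, rawLevel = sc$truth$bodyLevel)
    measureRegion(sc$image, planeSegment(surf, plane), plane)@netTotal
  }, 0)
  expect_true(all(diff(nets) > 0))
})

test_that("net total is invariant to a constant offset matched by the plane", {
  sc <- simMouseImage(noiseSd = 0, seed = 2,
                      tumours = data.frame(row = 40, col = 50, sigma = 5,
                                           amplitude = 1500))
  img <- sc$image
  surf <- normalizeImage(img)
  plane <- thresholdPlane(surf, rawLevel = sc$truth$bodyLevel)
  mask <- planeSegment(surf, plane)
  m1 <- measureRegion(img, mask, plane)
  off <- 300
  img2 <- RawImage(pixels(img) + off, bitDepth = bitDepth(img))
  surf2 <- normalizeImage(img2)
  plane2 <- thresholdPlane(surf2, rawLevel = sc$truth$bodyLevel + off)
  m2 <- measureRegion(img2, mask, plane2)
  expect_equal(m2@netTotal, m1@netTotal)
})

test_that("background estimation gives raw-unit mean and sample sd", {
  img <- RawImage(matrix(25, 5, 5))
  reg <- ellipseMask(5, 5, 3, 3, 2, 2)
  bg <- estimateBackground(img, reg)
  expect_equal(bg@mean, 25)
  expect_equal(bg@sd, 0)
  # hand-computed sample sd of {1, 2, 3}
  img3 <- RawImage(matrix(c(1, 2, 3, 9), 2, 2))
  reg3 <- RegionMask(matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2))
  bg3 <- estimateBackground(img3, reg3)
  expect_equal(bg3@mean, 2)
  expect_equal(bg3@sd, 1)
  expect_error(estimateBackground(img, RegionMask(matrix(FALSE, 5, 5))),
               "degenerate")
  # seeded noisy plateau: the estimate sits near the true level
  sc <- simMouseImage(noiseSd = 20, seed = 5)
  reg <- ellipseMask(96, 96, 48, 48, 10, 10)
  bg <- estimateBackground(sc$image, reg)
  n <- nPixels(reg)
  expect_lt(abs(bg@mean - sc$truth$bodyLevel), 3 * 20 / sqrt(n) + 0.5)
})

test_that("detection calls compare candidate mean to background + k sd", {
  # constructed: candidate 10 sd above background
  set.seed(8)
  p <- matrix(round(rnorm(400, 100, 5)), 20, 20)
  p[p < 0] <- 0
  cand <- ellipseMask(20, 20, 5, 5, 3, 3)
  p[maskMatrix(cand)] <- 200
  img <- RawImage(p)
  bgReg <- ellipseMask(20, 20, 15, 15, 3, 3)
  bg <- estimateBackground(img, bgReg)
  expect_true(detectSignal(img, cand, bg, k = 3))
  # k = 0 boundary: minutely above the background mean is enough
  p2 <- matrix(100, 10, 10)
  cand2 <- ellipseMask(10, 10, 3, 3, 2, 2)
  p2[maskMatrix(cand2)] <- 101
  img2 <- RawImage(p2)
  bgm <- RegionMask(!maskMatrix(cand2))
  expect_true(detectSignal(img2, cand2, estimateBackground(img2, bgm), k = 0))
  # degenerate background (single pixel, undefined sd)
  one <- RegionMask(matrix(c(TRUE, rep(FALSE, 99)), 10, 10))
  expect_error(detectSignal(img2, cand2, estimateBackground(img2, one)),
               "degenerate")
  expect_error(detectSignal(img2, RegionMask(matrix(FALSE, 10, 10)),
                            estimateBackground(img2, bgm)), "degenerate")
})

test_that("null candidates are almost never called present at k = 3", {
  # candidate drawn from the same distribution as background: the
  # candidate *mean* over ~80 px must beat mean + 3 per-pixel sd, which a
  # null region essentially never does
  hits <- 0L
  for (seed in 1:100) {
    sc <- simMouseImage(noiseSd = 25, seed = seed, nrow = 64, ncol = 64)
    cand <- ellipseMask(64, 64, 26, 26, 5, 5)
    bgReg <- ellipseMask(64, 64, 40, 40, 5, 5)
    bg <- estimateBackground(sc$image, bgReg)
    hits <- hits + detectSignal(sc$image, cand, bg, k = 3)
  }
  expect_lte(hits, 2L)
})

test_that("calliper volume follows length x width^2 / 2", {
  expect_equal(calliperVolume(10, 6), 180)
  expect_equal(calliperVolume(7, 0), 0)
  set.seed(3)
  L <- runif(20, 1, 20); W <- L * runif(20, 0.2, 1)
  expect_equal(calliperVolume(L, W), L * W^2 / 2)
  expect_error(calliperVolume(-1, 1), "domain")
  expect_warning(calliperVolume(3, 5), "swapped")
})
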