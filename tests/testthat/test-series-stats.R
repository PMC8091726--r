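# Fold change, coefficient of variance, dilution linearity, limit of
# detection and detection heat-tables.

makeSeries <- function(dayA, a, dayB, b) {
  data.frame(mouse_id = rep(paste0("m", seq_along(a)), 2),
             day = rep(c(dayA, dayB), each = length(a)),
             net_total = c(a, b))
}

test_that("fold change is the ratio of group means across days", {
  s <- makeSeries(17, c(10, 20, 30), 24, c(20, 40, 60))
  expect_equal(foldChange(s, 17, 24), 2)
  expect_equal(foldChange(s, 17, 17), 1)
  # identical values on both days
  s2 <- makeSeries(1, c(5, 5), 2, c(5, 5))
  expect_equal(foldChange(s2, 1, 2), 1)
  # uniform multiplicative growth of day-B values scales the fold change
  s3 <- makeSeries(17, c(10, 20, 30), 24, 3 * c(20, 40, 60))
  expect_equal(foldChange(s3, 17, 24), 6)
  # per-mouse variant differs when growth is heterogeneous
  s4 <- makeSeries(1, c(10, 100), 2, c(40, 100))
  expect_equal(foldChange(s4, 1, 2), 140 / 110)
  expect_equal(foldChange(s4, 1, 2, perMouse = TRUE), mean(c(4, 1)))
  expect_error(foldChange(makeSeries(1, c(0, 0), 2, c(1, 1)), 1, 2), "domain")
  expect_error(foldChange(s, 17, 99), "present")
  dup <- rbind(s, s[1, ])
  expect_error(foldChange(dup, 17, 24), "duplicate")
})

test_that("coefficient of variance is percent sample sd over mean", {
  expect_equal(coefficientOfVariance(c(4, 4, 4)), 0)
  expect_equal(coefficientOfVariance(c(1, 2, 3)), 50)
  # invariant under positive rescaling
  set.seed(2)
  x <- runif(20, 10, 50)
  expect_equal(coefficientOfVariance(x * 37), coefficientOfVariance(x))
  expect_error(coefficientOfVariance(5), "at least 2")
  expect_error(coefficientOfVariance(c(-1, 1)), "zero mean")
})

test_that("limit of detection finds the statistical crossing", {
  # constructed crossing: dilutions 1, .1, .01, .001 with signals
  # 1000, 100, 10, 1 over background 0 +/- sd 1 -> k=3 threshold 3
  s <- DilutionSeries(10^-(0:3),
                      list(c(1000), c(100), c(10), c(1)),
                      backgroundWells = c(-1, 0, 1, 0))
  sdBg <- sd(c(-1, 0, 1, 0))
  expect_equal(limitOfDetection(s, k = 3), 0.01)   # 10 > 3*sdBg, 1 is not
  # everything at background: nothing detectable
  flat <- DilutionSeries(10^-(0:2), list(c(0), c(0), c(0)),
                         backgroundWells = c(-1, 1, 0, 0))
  expect_true(is.na(limitOfDetection(flat, k = 3)))
  # k = 0 degenerates to mean-above-background
  expect_equal(limitOfDetection(s, k = 0), 0.001)
  expect_error(limitOfDetection(DilutionSeries(c(1, .1), list(1, 1))),
               "background")
})

test_that("dilution linearity: slope 1 and full range for proportional signal", {
  sim <- simDilutionPlate(noiseSd = 0, seed = 1)
  rep <- dilutionLinearity(sim$series, k = 3)
  expect_equal(rep$slope, 1, tolerance = 1e-12)
  expect_equal(rep$linearRange, 6)
  expect_equal(rep$summary$normalized[1], 1)
  # noiseless geometric means
  expect_equal(rep$summary$mean, sim$truth$expectedMeans)
  # bottom dilutions pinned at background fall out of the range
  s <- DilutionSeries(10^-(0:4),
                      lapply(c(10000, 1000, 100, 0, 0), function(x)
                        rep(500 + x, 3)),
                      backgroundWells = c(499, 500, 501, 500))
  r <- dilutionLinearity(s, k = 3)
  expect_equal(r$linearRange, 3)
  expect_false(any(r$summary$detectable[4:5]))
  expect_equal(r$lod, 0.01)
})

test_that("empty detectable range is a result, not an error", {
  s <- DilutionSeries(10^-(0:2), list(c(500), c(500), c(500)),
                      backgroundWells = c(499, 501, 500))
  r <- dilutionLinearity(s, k = 3)
  expect_equal(r$linearRange, 0)
  expect_true(is.na(r$slope))
  expect_true(is.na(r$lod))
})

test_that("noisy plates recover the analytic LOD within one dilution step", {
  # analytic crossing: topSignal * f > ~ k * noiseSd ; with top 10000,
  # sd 20, k 3 the crossing sits between f = 1e-2 (signal 100) and
  # f = 1e-3 (signal 10): expect LOD 1e-2 within one step either way
  hits <- integer(0)
  for (seed in 1:100) {
    sim <- simDilutionPlate(topSignal = 10000, noiseSd = 20, seed = seed)
    lod <- limitOfDetection(sim$series, k = 3)
    hits <- c(hits, round(log10(lod)))
  }
  expect_true(all(hits %in% c(-1, -2, -3)))
  expect_equal(sort(unique(hits))[which.max(table(hits))], -2)
})

test_that("exponential growth fold change is recovered on synthetic series", {
  r <- log(2) / 3.5
  # noiseless closed form on the measurement series
  tc <- simGrowthTimecourse(days = c(17, 24), rate = r, noiseSd = 0, seed = 4)
  meas <- timecourseMeasurements(tc)
  expect_equal(foldChange(meas, 17, 24), exp(r * 7), tolerance = 0.01)
  # with noise, mean recovery over seeds stays within the MC interval
  ratios <- vapply(1:30, function(seed) {
    tc <- simGrowthTimecourse(days = c(17, 24), rate = r,
                              initialAmplitude = 2000, noiseSd = 100,
                              seed = seed)
    meas <- timecourseMeasurements(tc, maskType = "disc")
    foldChange(meas, 17, 24)
  }, 0)
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 4), 3 * se + 0.02)
})

test_that("detection tables record the earliest detected day per platform", {
  calls <- expand.grid(lesion = c("m8-knee", "m9-abdomen"),
                       platform = c("XVI", "BIX", "LPT"),
                       day = c(31, 34, 38, 41), stringsAsFactors = FALSE)
  calls$detected <- FALSE
  calls$detected[calls$lesion == "m8-knee" & calls$platform == "LPT" &
                   calls$day %in% c(34, 38)] <- TRUE
  calls$detected[calls$lesion == "m9-abdomen" & calls$platform == "BIX" &
                   calls$day == 41] <- TRUE
  tab <- detectionTable(calls)
  expect_equal(tab$LPT[tab$lesion == "m8-knee"], 34)
  expect_equal(tab$BIX[tab$lesion == "m9-abdomen"], 41)
  expect_true(is.na(tab$XVI[tab$lesion == "m8-knee"]))   # never detected
  # duplicates are an input error
  expect_error(detectionTable(rbind(calls, calls[1, ])), "duplicate")
  # CSV round trip preserves earliest days and never-markers
  path <- file.path(withr::local_tempdir(), "det.csv")
  writeDetectionTable(tab, path)
  back <- readDetectionTable(path)
  expect_equal(back$LPT, tab$LPT)
  expect_equal(is.na(back$XVI), is.na(tab$XVI))
})
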