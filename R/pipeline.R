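#' @include synthetic.R
NULL

## Manifest-driven workflows chaining the modules end to end. Each run
## writes its outputs plus a JSON run manifest recording every input,
## parameter and seed, sufficient to reproduce the run exactly.

.writeRunManifest <- function(outDir, name, params, items = NULL,
                              errors = NULL) {
  manifest <- list(
    tool = "irfpquant", version = as.character(utils::packageVersion("irfpquant")),
    workflow = name, timestamp = NA, params = params, items = items,
    errors = errors)
  # timestamp intentionally NA-able for byte-identical reruns
  path <- file.path(outDir, paste0(name, "_run_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

.manifestLevel <- function(row, surface) {
  # exact [[ indexing: $ would partial-match 'level' onto 'level_raw'
  if (!is.null(row[["level"]]) && !is.na(row[["level"]]))
    thresholdPlane(surface, level = row[["level"]])
  else if (!is.null(row[["level_raw"]]) && !is.na(row[["level_raw"]]))
    thresholdPlane(surface, rawLevel = row[["level_raw"]])
  else NULL
}

#' Quantify tumour intensity for every image in a manifest
#'
#' Runs the full workflow per manifest row: read TIFF, crop, optionally
#' sum-bin, normalize, threshold (maximum-entropy initial value unless a
#' manual level is supplied), plane-segment and measure in raw units.
#' Per-item failures are recorded and the run continues. Every subjective
#' choice (crop box, plane level) ends up in the run manifest.
#'
#' @param manifest path to a CSV, or a data.frame, with columns `path`,
#'   `mouse_id`, `day` and optionally `platform`, `units`, `bit_depth`,
#'   crop coordinates `row_start`, `row_stop`, `col_start`, `col_stop`
#'   (0-based, half-open) and a manual plane height as `level`
#'   (normalized) or `level_raw` (raw units).
#' @param outDir output directory; created if missing. Writes
#'   `measurements.csv` and `quantify_run_manifest.json`.
#' @param binK sum-binning block edge applied after cropping (default 1,
#'   none).
#' @param nBins histogram bins for the automatic threshold.
#' @param largestComponent restrict masks to their largest connected
#'   component.
#' @param seed recorded in the manifest (the workflow itself is
#'   deterministic).
#' @return A list: `measurements` (data.frame, one row per successful
#'   item), `errors` (data.frame of failed items), `manifestPath`,
#'   `status` (0 = all items succeeded, 1 = partial failure).
#' @export
runQuantify <- function(manifest, outDir, binK = 1L, nBins = 256L,
                        largestComponent = FALSE, seed = NULL) {
  items <- if (is.data.frame(manifest)) manifest else
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); errs <- list()
  for (i in seq_len(nrow(items))) {
    row <- items[i, ]
    res <- tryCatch({
      img <- readRawTiff(row$path,
        bitDepth = if (!is.null(row$bit_depth)) row$bit_depth else 16L,
        platform = if (!is.null(row$platform)) row$platform else "generic",
        units = if (!is.null(row$units)) row$units else "counts")
      if (!is.null(row$row_start) && !is.na(row$row_start))
        img <- cropImage(img, c(row$row_start, row$row_stop,
                                row$col_start, row$col_stop))
      if (binK > 1L) img <- binImage(img, binK)
      surf <- normalizeImage(img)
      plane <- .manifestLevel(row, surf)
      if (is.null(plane)) plane <- entropyThreshold(surf, nBins = nBins)
      mask <- planeSegment(surf, plane, largestComponent = largestComponent)
      m <- measureRegion(img, mask, plane, mouseId = row$mouse_id,
                         day = row$day)
      d <- as.data.frame(m)
      d$platform <- platform(img)
      d$plane_level <- planeLevel(plane)
      d$method <- plane@method
      d
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- data.frame(
        path = row$path, mouse_id = row$mouse_id, day = row$day,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- res
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mouse_id = character(), day = numeric(), units = character(),
               area_px = integer(), total_raw = numeric(),
               plane_raw_level = numeric(), net_total = numeric(),
               mean_net = numeric(), saturated_in_mask = integer(),
               platform = character(), plane_level = numeric(),
               method = character())
  errors <- if (length(errs)) do.call(rbind, errs) else
    data.frame(path = character(), mouse_id = character(), day = numeric(),
               error = character())
  utils::write.csv(measurements, file.path(outDir, "measurements.csv"),
                   row.names = FALSE)
  mp <- .writeRunManifest(outDir, "quantify",
    params = list(binK = binK, nBins = nBins,
                  largestComponent = largestComponent, seed = seed),
    items = if (is.data.frame(manifest)) "inline data.frame" else manifest,
    errors = errors$error)
  list(measurements = measurements, errors = errors, manifestPath = mp,
       status = if (nrow(errors) > 0L) 1L else 0L)
}

#' Dilution-series workflow: linearity report from a tidy CSV
#'
#' @param input path to a CSV, or a data.frame, with columns `dilution`
#'   (factor, background wells as `NA` or 0), `signal` (raw measurement)
#'   and optionally `role` (`"sample"`/`"background"`).
#' @param outDir output directory; writes `dilution_summary.csv` and
#'   `dilution_report.json`.
#' @param k detection stringency; `subtractBackground` as in
#'   [dilutionLinearity()].
#' @param subtractBackground see [dilutionLinearity()].
#' @param seed recorded in the manifest.
#' @return The [dilutionLinearity()] report (list), plus `series`.
#' @export
runDilution <- function(input, outDir, k = 3, subtractBackground = TRUE,
                        seed = NULL) {
  d <- if (is.data.frame(input)) input else
    utils::read.csv(input, stringsAsFactors = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  isBg <- if ("role" %in% names(d)) d$role == "background" else
    is.na(d$dilution) | d$dilution == 0
  f <- sort(unique(d$dilution[!isBg]), decreasing = TRUE)
  series <- DilutionSeries(
    f, lapply(f, function(x) d$signal[!isBg & d$dilution == x]),
    backgroundWells = d$signal[isBg])
  rep <- dilutionLinearity(series, k = k,
                           subtractBackground = subtractBackground)
  utils::write.csv(rep$summary, file.path(outDir, "dilution_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(slope = rep$slope, linear_range = rep$linearRange, lod = rep$lod,
         k = k, subtract_background = subtractBackground),
    file.path(outDir, "dilution_report.json"), auto_unbox = TRUE,
    digits = NA, na = "null")
  .writeRunManifest(outDir, "dilution",
    params = list(k = k, subtractBackground = subtractBackground,
                  seed = seed))
  c(rep, list(series = series))
}

#' Phantom repositioning workflow: coefficient-of-variance report
#'
#' Quantifies each image of a repositioning series with a user-style disc
#' region centred on the signal peak and the plane at a stated background
#' level, then reports the CV of the net totals.
#'
#' @param images list of [RawImage-class] (or a manifest CSV as in
#'   [runQuantify()], in which case images are read from disk).
#' @param outDir output directory; writes `phantom_measurements.csv` and
#'   `phantom_report.json`.
#' @param backgroundRawLevel raw-unit plane height used for subtraction
#'   (the body/phantom plateau).
#' @param discRadius region radius in pixels.
#' @param seed recorded in the manifest.
#' @return A list: `cvPercent`, `netTotals`, `measurements`.
#' @export
runPhantom <- function(images, outDir, backgroundRawLevel, discRadius = 12,
                       seed = NULL) {
  if (!is.list(images) || (length(images) && !is(images[[1]], "RawImage"))) {
    items <- if (is.data.frame(images)) images else
      utils::read.csv(images, stringsAsFactors = FALSE)
    images <- lapply(seq_len(nrow(items)), function(i)
      readRawTiff(items$path[i],
        bitDepth = if (!is.null(items$bit_depth)) items$bit_depth[i] else 16L))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    surf <- normalizeImage(img)
    plane <- thresholdPlane(surf, rawLevel = backgroundRawLevel)
    mask <- peakDiscMask(img, discRadius)
    d <- as.data.frame(measureRegion(img, mask, plane,
                                     mouseId = sprintf("repeat_%02d", i)))
    d
  })
  meas <- do.call(rbind, rows)
  cv <- if (nrow(meas) > 1L) coefficientOfVariance(meas$net_total) else NA_real_
  utils::write.csv(meas, file.path(outDir, "phantom_measurements.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(cv_percent = cv, n = nrow(meas),
         background_raw_level = backgroundRawLevel,
         disc_radius = discRadius),
    file.path(outDir, "phantom_report.json"), auto_unbox = TRUE, digits = NA)
  .writeRunManifest(outDir, "phantom",
    params = list(backgroundRawLevel = backgroundRawLevel,
                  discRadius = discRadius, seed = seed))
  list(cvPercent = cv, netTotals = meas$net_total, measurements = meas)
}

#' Detection heat-table workflow
#'
#' @param calls path to a CSV, or a data.frame, with columns `lesion`,
#'   `platform`, `day`, `detected`.
#' @param outDir output directory; writes `detection_table.csv`.
#' @param seed recorded in the manifest.
#' @return The detection table (see [detectionTable()]).
#' @export
runDetect <- function(calls, outDir, seed = NULL) {
  d <- if (is.data.frame(calls)) calls else
    utils::read.csv(calls, stringsAsFactors = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(d) == 0L) {
    tab <- data.frame(lesion = character())
  } else {
    if (is.character(d$detected)) d$detected <- as.logical(d$detected)
    tab <- detectionTable(d)
  }
  writeDetectionTable(tab, file.path(outDir, "detection_table.csv"))
  .writeRunManifest(outDir, "detect", params = list(seed = seed))
  tab
}

#' Write a synthetic fixture set to disk
#'
#' Generates a growth timecourse with [simGrowthTimecourse()], writes each
#' frame as a TIFF with a JSON ground-truth sidecar, and returns a
#' manifest data.frame directly consumable by [runQuantify()].
#'
#' @param outDir output directory.
#' @param mice number of simulated mice (each gets an independent
#'   sub-seed).
#' @param seed integer seed.
#' @param ... passed to [simGrowthTimecourse()].
#' @return The manifest data.frame (also written as `manifest.csv`).
#' @export
runSimulate <- function(outDir, mice = 2, seed = 1, ...) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truth <- list()
  for (m in seq_len(mice)) {
    tc <- simGrowthTimecourse(seed = seed + m, ...)
    for (frame in tc) {
      path <- file.path(outDir,
                        sprintf("mouse%02d_day%02d.tif", m, frame$day))
      writeRawTiff(frame$image, path)
      rows[[length(rows) + 1L]] <- data.frame(
        path = path, mouse_id = sprintf("mouse%02d", m), day = frame$day,
        platform = "synthetic", units = "counts", bit_depth = 16L,
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- list(
        mouse_id = sprintf("mouse%02d", m), day = frame$day,
        true_amplitude = frame$trueAmplitude,
        true_blob_integral = frame$trueBlobIntegral)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
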