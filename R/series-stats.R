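#' @include quantification.R
NULL

## Longitudinal and replicate statistics operate on the tidy measurement
## data.frame emitted by the pipeline (columns mouse_id, day and a value
## column, net_total by default), so they compose with external CSVs as
## readily as with in-session measurements.

.seriesValues <- function(series, day, value) {
  if (is.data.frame(series)) {
    stopifnot(all(c("mouse_id", "day", value) %in% names(series)))
    if (anyDuplicated(series[c("mouse_id", "day")]))
      stop("duplicate (mouse_id, day) entries in series")
    series[[value]][series$day == day]
  } else stop("series must be a data.frame of measurements")
}

#' Fold change between two imaging days
#'
#' The ratio of the across-mice mean measurement on `dayB` to the mean on
#' `dayA` (group-mean fold change, as used for "fold increase from average
#' tumour size"). Set `perMouse = TRUE` for the mean of per-mouse ratios
#' instead, which weights animals equally and suits per-mouse trajectory
#' plots; the two differ whenever tumour sizes are heterogeneous.
#'
#' @param series data.frame with columns `mouse_id`, `day` and the value
#'   column (one row per mouse per day).
#' @param dayA,dayB the two days to compare (`dayA` is the denominator).
#' @param value name of the measurement column (default `"net_total"`).
#' @param perMouse average per-mouse ratios instead of the ratio of means.
#' @return A single numeric fold change.
#' @export
foldChange <- function(series, dayA, dayB, value = "net_total",
                       perMouse = FALSE) {
  a <- .seriesValues(series, dayA, value)
  b <- .seriesValues(series, dayB, value)
  if (length(a) == 0L || length(b) == 0L)
    stop("both days must be present in the series")
  if (perMouse) {
    sa <- series[series$day == dayA, ]
    sb <- series[series$day == dayB, ]
    common <- intersect(sa$mouse_id, sb$mouse_id)
    if (length(common) == 0L) stop("no mouse measured on both days")
    ra <- sa[[value]][match(common, sa$mouse_id)]
    rb <- sb[[value]][match(common, sb$mouse_id)]
    if (any(ra <= 0)) stop("domain error: non-positive day-A measurement")
    return(mean(rb / ra))
  }
  if (mean(a) <= 0)
    stop("domain error: non-positive mean at the denominator day")
  mean(b) / mean(a)
}

#' Coefficient of variance (percent)
#'
#' `100 * sample sd / mean`, the repeatability statistic used to compare
#' measurement variability across platforms (e.g. phantom-mouse
#' repositioning series).
#'
#' @param values numeric vector, at least 2 values, non-zero mean.
#' @return CV in percent.
#' @examples
#' coefficientOfVariance(c(1, 2, 3))  # 50
#' @export
coefficientOfVariance <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("domain error: zero mean")
  100 * stats::sd(values) / m
}

#' Limit of detection of a dilution series
#'
#' The smallest (most dilute) dilution whose replicate mean exceeds the
#' background-well mean by more than `k` background standard deviations.
#' This replaces the subjective "last visible dilution" call with an
#' explicit statistical rule.
#'
#' @param series a [DilutionSeries-class] with at least one background well.
#' @param k detection stringency in background standard deviations
#'   (`k = 0` degenerates to mean-above-background).
#' @return The dilution factor, or `NA` if no dilution is detectable.
#' @export
limitOfDetection <- function(series, k = 3) {
  stopifnot(is(series, "DilutionSeries"), k >= 0)
  bg <- series@backgroundWells
  if (length(bg) < 1L) stop("at least one background well required")
  sdBg <- if (length(bg) > 1L) stats::sd(bg) else 0
  thr <- mean(bg) + k * sdBg
  means <- vapply(series@replicateSignals, mean, 0)
  det <- series@dilutionFactors[means > thr]
  if (length(det) == 0L) NA_real_ else min(det)
}

#' Dilution-series linearity and detectable range
#'
#' Summarizes a serial dilution: per-dilution replicate means and sds,
#' means normalized so the top (least dilute) dilution maps to 1, the
#' log10-log10 slope of background-subtracted signal against dilution
#' factor over the detectable range (slope 1 = perfect proportionality),
#' and the extent of that range. Dilutions at or below the limit of
#' detection are excluded from the fit.
#'
#' @param series a [DilutionSeries-class].
#' @param k detection stringency passed to [limitOfDetection()].
#' @param subtractBackground subtract the background-well mean before
#'   normalization and log-log fitting (default `TRUE`; recorded in the
#'   result).
#' @return A list: `summary` (data.frame `dilution`, `mean`, `sd`, `net`,
#'   `normalized`, `detectable`), `slope` (log-log slope over the
#'   detectable range, `NA` if fewer than 2 detectable dilutions),
#'   `linearRange` (number of detectable dilutions), `lod` (dilution
#'   factor or `NA`), `subtractBackground`.
#' @export
dilutionLinearity <- function(series, k = 3, subtractBackground = TRUE) {
  stopifnot(is(series, "DilutionSeries"))
  f <- series@dilutionFactors
  means <- vapply(series@replicateSignals, mean, 0)
  sds <- vapply(series@replicateSignals,
                function(x) if (length(x) > 1L) stats::sd(x) else NA_real_, 0)
  bg <- if (length(series@backgroundWells) > 0L)
    mean(series@backgroundWells) else 0
  net <- if (subtractBackground) means - bg else means
  lod <- if (length(series@backgroundWells) > 0L)
    limitOfDetection(series, k = k) else min(f)
  detectable <- if (is.na(lod)) rep(FALSE, length(f)) else f >= lod
  normalized <- net / net[1]
  slope <- NA_real_
  if (sum(detectable & net > 0) >= 2L) {
    sel <- detectable & net > 0
    slope <- unname(stats::coef(
      stats::lm(log10(net[sel]) ~ log10(f[sel])))[2])
  }
  list(summary = data.frame(dilution = f, mean = means, sd = sds, net = net,
                            normalized = normalized, detectable = detectable),
       slope = slope, linearRange = sum(detectable), lod = lod,
       subtractBackground = subtractBackground)
}

#' Earliest-detection heat-table
#'
#' Collapses per-day presence/absence calls into the earliest day each
#' lesion was detected on each platform, the layout of a detection
#' heatmap; never-detected combinations are `NA` ("crosses").
#'
#' @param calls data.frame with columns `lesion`, `platform`, `day`,
#'   `detected` (logical); duplicate (lesion, platform, day) rows are an
#'   input error.
#' @return A data.frame with one row per lesion and one column per
#'   platform holding the earliest detected day (`NA` = never).
#' @export
detectionTable <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("lesion", "platform", "day", "detected") %in% names(calls)))
  if (anyDuplicated(calls[c("lesion", "platform", "day")]))
    stop("input error: duplicate (lesion, platform, day) entries")
  lesions <- unique(calls$lesion)
  platforms <- unique(calls$platform)
  out <- data.frame(lesion = lesions, stringsAsFactors = FALSE)
  for (p in platforms) {
    out[[p]] <- vapply(lesions, function(l) {
      d <- calls$day[calls$lesion == l & calls$platform == p & calls$detected]
      if (length(d) == 0L) NA_real_ else min(d)
    }, 0)
  }
  out
}

#' Write / read a detection heat-table as CSV
#'
#' @param table a detection table from [detectionTable()].
#' @param path CSV path.
#' @return `writeDetectionTable()`: `path`, invisibly;
#'   `readDetectionTable()`: the table.
#' @export
writeDetectionTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "never")
  invisible(path)
}

#' @rdname writeDetectionTable
#' @export
readDetectionTable <- function(path) {
  d <- utils::read.csv(path, na.strings = "never", check.names = FALSE)
  d$lesion <- as.character(d$lesion)
  d
}
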