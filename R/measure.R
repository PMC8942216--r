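# Calibrated area estimation and wound-closure time series.
#
# The splint's inner circle has a known physical area A_in, so an unknown
# wound area follows from pixel counts alone:
#     A_u = A_in * (wound_px / splint_px)                       (area)
# and closure on day i is measured against the day-0 baseline:
#     C_P = 100 - (A_i / A_0) * 100                             (closure %)
# Day 0 is 0% closure by construction, 100% means fully closed, and wound
# expansion beyond the day-0 size shows as negative closure.

#' Calibrated wound area in mm^2
#'
#' Scales the wound/splint pixel-count ratio by the known inner-ring area
#' `A_in = pi * (inner_diameter / 2)^2`. Because both counts come from the
#' same image, the unknown mm-per-pixel scale cancels.
#'
#' @param wound_px wound pixel count (>= 0).
#' @param splint_px inner-ring pixel count (> 0).
#' @param geometry a [SplintGeometry-class].
#' @return Area in mm^2. A zero or missing `splint_px` is a
#'   calibration-impossible condition and raises an error (impute first).
#' @export
#' @examples
#' woundAreaMm2(1000, 4000, splintGeometry())  # pi * 25 / 4 = 19.63495
woundAreaMm2 <- function(wound_px, splint_px, geometry = splintGeometry()) {
  stopifnot(all(wound_px >= 0))
  if (any(is.na(splint_px)) || any(splint_px <= 0))
    stop("calibration impossible: splint_px must be > 0 (impute missing splints first)")
  innerAreaMm2(geometry) * wound_px / splint_px
}

#' Wound-closure percentage
#'
#' `100 - (ai / a0) * 100`: 0% when the wound is at its day-0 size, 100%
#' when fully closed, negative during expansion beyond the day-0 size.
#'
#' @param a0 day-0 open area (> 0).
#' @param ai day-i open area (>= 0), vectorized.
#' @return Closure percentage(s).
#' @export
#' @examples
#' closurePercentage(28.27, 28.27)  # 0
#' closurePercentage(28.27, 0)      # 100
#' closurePercentage(50, 60)        # -20
closurePercentage <- function(a0, ai) {
  if (!is.finite(a0) || a0 <= 0) stop("a0 must be a positive area")
  stopifnot(all(ai >= 0))
  100 - (ai / a0) * 100
}

#' Build a wound's measurement series
#'
#' Takes per-day records for one wound (possibly with missing splints and
#' missing days), applies the chosen splint imputation, computes calibrated
#' areas, fills missing timepoints from temporal neighbors, and derives the
#' closure curve against the day-0 area.
#'
#' Records carry `wound_px = NA` for days where measurement failed entirely
#' (the day is treated as missing and temporally filled) and `wound_px = 0`
#' for days where segmentation confidently found no wound (a closed wound,
#' area 0).
#'
#' @param records data.frame: `wound_id`, `day`, `wound_px`, `splint_px`
#'   (`NA` when the splint was missing), and optionally `splint_imputed`.
#' @param geometry a [SplintGeometry-class].
#' @param imputation "mean", "nearest" or "none" (with "none", records
#'   lacking a splint are treated as missing days).
#' @param days full day grid; defaults to `0:max(records$day)`.
#' @return A [WoundSeries-class].
#' @export
buildSeries <- function(records, geometry = splintGeometry(),
                        imputation = c("nearest", "mean", "none"),
                        days = NULL) {
  imputation <- match.arg(imputation)
  stopifnot(nrow(records) > 0L, length(unique(records$wound_id)) == 1L)
  if (!"splint_imputed" %in% names(records)) records$splint_imputed <- FALSE
  records <- records[order(records$day), , drop = FALSE]
  measured <- !is.na(records$wound_px)
  rec <- records[measured, , drop = FALSE]
  if (nrow(rec) > 0L && any(is.na(rec$splint_px))) {
    rec <- switch(imputation,
                  mean = imputeSplintMean(rec),
                  nearest = imputeSplintNearest(rec),
                  none = rec)
  }
  rec$area_mm2 <- ifelse(!is.na(rec$splint_px) & rec$splint_px > 0,
                         innerAreaMm2(geometry) * rec$wound_px / rec$splint_px,
                         NA_real_)
  if (is.null(days)) days <- 0:max(records$day)
  area <- rep(NA_real_, length(days))
  idx <- match(rec$day, days)
  area[idx[!is.na(idx)]] <- rec$area_mm2[!is.na(idx)]
  fl <- fillMissingValues(area)
  a0 <- fl$values[days == 0L]
  if (length(a0) != 1L || !is.finite(a0) || a0 <= 0)
    stop("series error: no positive day-0 area obtainable")
  out <- data.frame(
    day = days,
    wound_px = rec$wound_px[match(days, rec$day)],
    splint_px = rec$splint_px[match(days, rec$day)],
    area_mm2 = fl$values,
    splint_imputed = ifelse(is.na(match(days, rec$day)), FALSE,
                            rec$splint_imputed[match(days, rec$day)]),
    timepoint_filled = fl$filled)
  new("WoundSeries", wound_id = records$wound_id[1L], records = out,
      day0_area_mm2 = a0, closure = closurePercentage(a0, fl$values))
}

#' Fill missing timepoints of an existing series
#'
#' Re-applies the temporal neighbor-mean fill to a series' area values and
#' rebuilds the closure curve (useful after editing records).
#'
#' @param series a [WoundSeries-class].
#' @return A [WoundSeries-class] with completed areas and updated flags.
#' @export
fillMissingTimepoints <- function(series) {
  stopifnot(is(series, "WoundSeries"))
  r <- series@records
  fl <- fillMissingValues(r$area_mm2)
  r$area_mm2 <- fl$values
  r$timepoint_filled <- r$timepoint_filled | fl$filled
  a0 <- r$area_mm2[r$day == 0L]
  new("WoundSeries", wound_id = series@wound_id, records = r,
      day0_area_mm2 = a0, closure = closurePercentage(a0, r$area_mm2))
}

#' Per-day mean closure curve across wounds
#'
#' @param series_list list of [WoundSeries-class] sharing one day grid.
#' @return data.frame: `day`, `mean_closure`, `n`.
#' @export
averageSeries <- function(series_list) {
  stopifnot(length(series_list) > 0L)
  days <- series_list[[1L]]@records$day
  for (s in series_list)
    if (!identical(s@records$day, days))
      stop("all series must share the same day grid")
  cl <- vapply(series_list, function(s) s@closure, numeric(length(days)))
  cl <- matrix(cl, nrow = length(days))
  data.frame(day = days, mean_closure = rowMeans(cl),
             n = rep(length(series_list), length(days)))
}

#' Plot closure curves
#'
#' Per-wound closure percentage versus day, with the cohort mean overlaid.
#'
#' @param series_list list of [WoundSeries-class].
#' @return A ggplot object.
#' @export
plotClosureCurves <- function(series_list) {
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(wound_id = s@wound_id, day = s@records$day,
               closure = s@closure)))
  avg <- averageSeries(series_list)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$closure,
                                   group = .data$wound_id)) +
    ggplot2::geom_line(alpha = 0.35) +
    ggplot2::geom_line(data = avg,
                       ggplot2::aes(x = .data$day, y = .data$mean_closure,
                                    group = NULL),
                       linewidth = 1.1, colour = "steelblue") +
    ggplot2::labs(x = "Day", y = "Wound closure (%)") +
    ggplot2::theme_minimal()
}
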