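# Segmentation metrics, series-comparison statistics, and the
# missing-reference-object robustness experiments.

#' Dice and IoU overlap scores between binary masks
#'
#' `dice = 2|A&B| / (|A| + |B|)`, `iou = |A&B| / |A|B|`; both are defined as
#' 1 when both masks are empty (perfect agreement on "nothing there"). For
#' any pair of binary masks `dice = 2 * iou / (1 + iou)`.
#'
#' @param pred,truth logical matrices of one shape.
#' @return Named numeric: `dice`, `iou`.
#' @export
segmentationScores <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("mask shapes differ")
  pred <- pred != 0; truth <- truth != 0
  inter <- sum(pred & truth)
  a <- sum(pred); b <- sum(truth)
  if (a + b == 0L) return(c(dice = 1, iou = 1))
  c(dice = 2 * inter / (a + b), iou = inter / (a + b - inter))
}

#' Pearson, Spearman and Kendall correlation of two curves
#'
#' @param curve_x,curve_y numeric vectors, equal length >= 3, no missing
#'   values. Constant input has no defined correlation and raises an error.
#' @return Named numeric: `pearson`, `spearman`, `kendall`.
#' @export
correlationSuite <- function(curve_x, curve_y) {
  stopifnot(length(curve_x) == length(curve_y), length(curve_x) >= 3L,
            !anyNA(curve_x), !anyNA(curve_y))
  if (stats::sd(curve_x) == 0 || stats::sd(curve_y) == 0)
    stop("undefined correlation: constant input")
  c(pearson = stats::cor(curve_x, curve_y, method = "pearson"),
    spearman = stats::cor(curve_x, curve_y, method = "spearman"),
    kendall = stats::cor(curve_x, curve_y, method = "kendall"))
}

#' Root-mean-square error between two series
#'
#' @param series_a,series_b numeric vectors of equal length.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) stop("series lengths differ")
  sqrt(mean((series_a - series_b)^2))
}

#' Ground-truth measurement records for a phantom cohort
#'
#' Extracts per-scene pixel counts directly from the generator's masks: the
#' wound-of-interest pixel count (secondary wounds excluded) and the
#' splint-inner pixel count (`NA` when the splint is missing).
#'
#' @param cohort a [PhantomCohort-class].
#' @return data.frame: `wound_id`, `day`, `wound_px`, `splint_px`,
#'   `splint_imputed`.
#' @export
cohortRecords <- function(cohort) {
  stopifnot(is(cohort, "PhantomCohort"))
  m <- cohort@manifest
  data.frame(
    wound_id = m$wound_id, day = m$day,
    wound_px = round(m$true_area_mm2 / m$mm_per_pixel^2),
    splint_px = vapply(cohort@scenes, function(s)
      if (s@splint_present) as.numeric(sum(s@splint_inner_mask)) else NA_real_,
      numeric(1)),
    splint_imputed = FALSE, stringsAsFactors = FALSE)
}

# mean closure curve from records via per-wound series
recordsMeanCurve <- function(records, geometry, imputation, n_days) {
  series <- lapply(split(records, records$wound_id), function(r)
    buildSeries(r, geometry, imputation, days = 0:(n_days - 1L)))
  averageSeries(unname(series))
}

#' Splint-removal robustness experiment
#'
#' Artificially removes splint measurements from a phantom cohort — either a
#' seeded random subset bringing total splint absence to a target fraction,
#' or every scene inside a fixed 8-day window — then re-runs imputation and
#' measurement and compares the cohort-mean closure curve against the
#' unperturbed baseline.
#'
#' @param cohort a [PhantomCohort-class].
#' @param pattern `list(type = "fraction", value = f)` for a total missing
#'   fraction `f`, or `list(type = "window", from = a)` for days
#'   `[a, a + 7]`.
#' @param technique splint imputation: "mean" or "nearest".
#' @param geometry a [SplintGeometry-class].
#' @param seed seed for the random removal draw.
#' @return List: `baseline` and `perturbed` mean-curve data.frames
#'   (day, mean_closure, n), `deviation` (per-day absolute difference in
#'   percentage points), `max_abs_dev`, `mean_abs_dev`, plus the realized
#'   pattern and splint availability before/after.
#' @export
splintRemovalExperiment <- function(cohort, pattern,
                                    technique = c("nearest", "mean"),
                                    geometry = splintGeometry(), seed = 1L) {
  technique <- match.arg(technique)
  stopifnot(is.list(pattern), pattern$type %in% c("fraction", "window"))
  records <- cohortRecords(cohort)
  n_days <- length(unique(records$day))
  baseline_avail <- mean(!is.na(records$splint_px))
  baseline <- recordsMeanCurve(records, geometry, technique, n_days)

  perturbed_records <- records
  if (pattern$type == "fraction") {
    target_missing <- floor(pattern$value * nrow(records))
    already <- sum(is.na(records$splint_px))
    extra <- target_missing - already
    if (extra > 0) {
      if (1 - baseline_avail >= pattern$value)
        extra <- 0  # already at or past the target
      have <- which(!is.na(records$splint_px))
      if (extra >= length(have))
        stop("pattern would remove all splints; imputation impossible")
      drop <- withSeed(seed, sample(have, extra))
      perturbed_records$splint_px[drop] <- NA_real_
    }
  } else {
    a <- pattern$from
    perturbed_records$splint_px[perturbed_records$day >= a &
                                perturbed_records$day <= a + 7] <- NA_real_
  }
  if (all(is.na(perturbed_records$splint_px)))
    stop("pattern removed all splints; imputation impossible")
  perturbed <- recordsMeanCurve(perturbed_records, geometry, technique, n_days)
  dev <- abs(perturbed$mean_closure - baseline$mean_closure)
  list(baseline = baseline, perturbed = perturbed,
       deviation = data.frame(day = baseline$day, abs_dev = dev),
       max_abs_dev = max(dev), mean_abs_dev = mean(dev),
       pattern = pattern, technique = technique,
       availability_before = baseline_avail,
       availability_after = mean(!is.na(perturbed_records$splint_px)))
}
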