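# Mask cleanup and missing-splint handling.
#
# Five post-processing techniques operate downstream of segmentation:
#   1. splint channel: keep the largest connected component;
#   2. wound channel: among components above a minimum size, keep the one
#      whose centroid is closest to the crop center (secondary stitch wounds
#      sit near the periphery);
#   3. impute a missing splint measurement with the cohort-mean splint size;
#   4. or with the splint size of the wound closest in size;
#   5. fill missing timepoints from their temporal neighbors.

#' Threshold per-class score maps into binary masks
#'
#' A pixel is included iff its score is greater than or equal to the
#' channel's threshold (inclusive comparison).
#'
#' @param maps a [ProbabilityMaps-class].
#' @param config a [PostprocessConfig-class].
#' @return List of logical matrices: `wound`, `splint`.
#' @export
thresholdMaps <- function(maps, config = postprocessConfig()) {
  stopifnot(is(maps, "ProbabilityMaps"), is(config, "PostprocessConfig"))
  list(wound = maps@wound >= config@min_wound_pixel_intensity,
       splint = maps@splint >= config@min_splint_pixel_intensity)
}

#' Keep only the largest connected component
#'
#' Empty input stays empty; a tie in pixel count is broken toward the
#' component whose first pixel comes earliest in raster-scan order, which is
#' the lowest component label by construction.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Logical matrix containing at most one component.
#' @export
largestComponent <- function(mask, connectivity = 8) {
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Select the most central wound component above the minimum size
#'
#' Among connected components with pixel count strictly greater than
#' `min_wound_size`, returns the one whose centroid has minimal Euclidean
#' distance to `image_centroid`. When no component qualifies (or the optional
#' `max_centroid_distance` cap excludes the winner) the result is empty.
#'
#' @param mask logical matrix.
#' @param config a [PostprocessConfig-class].
#' @return Logical matrix with at most one component.
#' @export
selectCentralWound <- function(mask, config = postprocessConfig()) {
  stopifnot(is(config, "PostprocessConfig"))
  lab <- labelComponents(mask, config@connectivity)
  st <- componentStats(lab)
  st <- st[st$size > config@min_wound_size, , drop = FALSE]
  if (nrow(st) == 0L) return(mask & FALSE)
  d <- sqrt((st$cx - config@image_centroid[1L])^2 +
            (st$cy - config@image_centroid[2L])^2)
  best <- st$label[which.min(d)]
  if (min(d) > config@max_centroid_distance) return(mask & FALSE)
  lab == best
}

#' Clean a raw prediction into final masks
#'
#' Composition of the cleanup steps: threshold both channels, keep the
#' largest splint component and the most central sufficiently large wound
#' component. Never increases the pixel count of either channel, and is
#' idempotent (re-cleaning `255 * masks` reproduces them).
#'
#' @param maps a [ProbabilityMaps-class].
#' @param config a [PostprocessConfig-class].
#' @return A [CleanMasks-class]; `wound_found`/`splint_found` report whether
#'   anything survived.
#' @export
cleanPrediction <- function(maps, config = postprocessConfig()) {
  th <- thresholdMaps(maps, config)
  cleanMasks(selectCentralWound(th$wound, config),
             largestComponent(th$splint, config@connectivity))
}

# ---- splint imputation ------------------------------------------------------

# records: data.frame with at least wound_id, day, wound_px, splint_px
# (NA when no splint was measured), splint_imputed.
checkRecords <- function(records) {
  need <- c("wound_id", "day", "wound_px", "splint_px", "splint_imputed")
  if (!all(need %in% names(records)))
    stop(paste("records needs columns:", paste(need, collapse = ", ")))
  records
}

#' Impute missing splint sizes with the cohort mean
#'
#' Every record lacking a splint pixel count receives the arithmetic mean of
#' all measured splint pixel counts; records with a measured splint are left
#' bit-identical.
#'
#' @param records measurement records data.frame (`splint_px` `NA` when
#'   missing).
#' @return The records with `splint_px` completed and `splint_imputed` set.
#' @export
imputeSplintMean <- function(records) {
  records <- checkRecords(records)
  have <- !is.na(records$splint_px)
  if (!any(have)) stop("imputation impossible: no record has a measured splint")
  miss <- !have
  if (any(miss)) {
    records$splint_px[miss] <- mean(records$splint_px[have])
    records$splint_imputed[miss] <- TRUE
  }
  records
}

#' Impute missing splint sizes from the closest-sized wound
#'
#' Each splintless record receives the splint pixel count of the splinted
#' record whose wound pixel count is closest to its own. Ties in wound-size
#' distance are broken toward the donor nearest in day, then toward the
#' lexicographically smallest donor wound_id.
#'
#' @inheritParams imputeSplintMean
#' @return The records with `splint_px` completed and `splint_imputed` set.
#' @export
imputeSplintNearest <- function(records) {
  records <- checkRecords(records)
  have <- which(!is.na(records$splint_px))
  if (length(have) == 0L)
    stop("imputation impossible: no record has a measured splint")
  miss <- which(is.na(records$splint_px))
  for (i in miss) {
    ds <- abs(records$wound_px[have] - records$wound_px[i])
    dd <- abs(records$day[have] - records$day[i])
    ord <- order(ds, dd, records$wound_id[have])
    donor <- have[ord[1L]]
    records$splint_px[i] <- records$splint_px[donor]
    records$splint_imputed[i] <- TRUE
  }
  records
}

#' Fill missing timepoints in a per-day value vector
#'
#' Interior missing days receive the mean of the previous (already filled)
#' and next available values, sweeping left to right so runs of consecutive
#' missing days are filled iteratively; missing leading/trailing days copy
#' the nearest measured value.
#'
#' @param values numeric vector ordered by day, `NA` where missing.
#' @return List: `values` (completed), `filled` (logical flags).
#' @export
#' @examples
#' fillMissingValues(c(10, NA, 20))$values   # 10 15 20
#' fillMissingValues(c(NA, 12, 14))$values   # 12 12 14
fillMissingValues <- function(values) {
  if (length(values) == 0L || all(is.na(values)))
    stop("series needs at least one measured day")
  filled <- is.na(values)
  meas <- which(!is.na(values))
  first <- meas[1L]; last <- meas[length(meas)]
  if (first > 1L) values[seq_len(first - 1L)] <- values[first]
  if (last < length(values))
    values[(last + 1L):length(values)] <- values[last]
  for (i in seq_along(values)) {
    if (!is.na(values[i])) next
    nxt <- i + which(!is.na(values[(i + 1L):length(values)]))[1L]
    values[i] <- (values[i - 1L] + values[nxt]) / 2
  }
  list(values = values, filled = filled)
}
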