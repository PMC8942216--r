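# End-to-end orchestration: preprocessing -> detection -> cropping ->
# segmentation -> post-processing -> measurement.

# rotate a scene to portrait (image, masks and bbox together)
orientScene <- function(scene) {
  d <- dim(scene@image)
  if (d[2L] <= d[1L]) return(scene)
  bbox <- scene@bbox
  new("PhantomScene",
      image = normalizeOrientation(scene@image),
      wound_mask = normalizeOrientation(scene@wound_mask),
      splint_inner_mask = normalizeOrientation(scene@splint_inner_mask),
      bbox = c(cx = unname(bbox["cy"]), cy = unname(1 - bbox["cx"]),
               w = unname(bbox["h"]), h = unname(bbox["w"]),
               confidence = unname(bbox["confidence"])),
      day = scene@day, wound_id = scene@wound_id,
      splint_present = scene@splint_present, params = scene@params)
}

measureScene <- function(scene, detector, segmenter, crop_side, post_config,
                         palette) {
  sc <- orientScene(scene)
  img <- downsampleHalf(sc@image)
  dets <- if (identical(detector, "oracle")) oracleDetect(sc)
          else circleDetect(img)
  sel <- selectWoundOfInterest(dets)
  if (is.null(sel)) return(list(wound_px = NA_real_, splint_px = NA_real_))
  cr <- cropAboutMidpoint(img, c(sel$cx, sel$cy), crop_side)
  maps <- if (identical(segmenter, "reference"))
    referenceSegment(cr$crop, palette)
  else predictMaps(segmenter, cr$crop)
  clean <- cleanPrediction(maps, post_config)
  list(wound_px = as.numeric(sum(clean@wound)),
       splint_px = if (clean@splint_found) as.numeric(sum(clean@splint))
                   else NA_real_)
}

#' Run the full measurement pipeline over a cohort of scenes
#'
#' Executes, per scene: portrait orientation, half-size down-sampling,
#' wound-of-interest detection, fixed-size cropping, segmentation into
#' per-class score maps, mask cleanup, and pixel counting; then, per wound:
#' splint imputation, temporal fill, calibrated areas and the closure curve.
#' A stage failure on one scene logs a warning and records a missing day for
#' that wound instead of aborting the run.
#'
#' @param input a [PhantomCohort-class], a list of [PhantomScene-class], or a
#'   directory written by [writeCohort()].
#' @param detector "oracle" (ground-truth adapter, phantoms only) or
#'   "circle" (classical splint detector), or a function
#'   `scene, image -> detections`.
#' @param segmenter "reference" (color-distance backend) or a trained
#'   [SegmenterModel-class] (its `input_size` overrides `crop_side`).
#' @param imputation "nearest", "mean" or "none".
#' @param geometry a [SplintGeometry-class].
#' @param crop_side crop side in pixels (default 352).
#' @param post_config a [PostprocessConfig-class]; defaults to thresholds
#'   20/40, minimum size 50 and the crop center as centroid.
#' @param palette rendering palette for the reference segmenter.
#' @param out_dir optional output directory for the measurement CSVs and the
#'   run manifest.
#' @param seed run seed recorded in the manifest (the reference path is
#'   fully deterministic).
#' @return List: `series` (per-wound [WoundSeries-class]), `summary`
#'   (cohort-mean closure data.frame), `records` (per-scene counts),
#'   `failures` (scene labels that fell back to missing days), `manifest`.
#' @export
runPipeline <- function(input, detector = "oracle", segmenter = "reference",
                        imputation = c("nearest", "mean", "none"),
                        geometry = splintGeometry(), crop_side = 352L,
                        post_config = NULL, palette = phantomPalette(),
                        out_dir = NULL, seed = 1L) {
  imputation <- match.arg(imputation)
  scenes <- if (is(input, "PhantomCohort")) input@scenes
  else if (is.character(input)) readCohortDir(input)
  else input
  if (length(scenes) == 0L) stop("startup error: no input scenes")
  if (is(segmenter, "SegmenterModel")) crop_side <- segmenter@config@input_size
  if (is.null(post_config))
    post_config <- postprocessConfig(image_centroid = c(crop_side / 2,
                                                        crop_side / 2))
  rows <- vector("list", length(scenes))
  failures <- character(0)
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    res <- tryCatch(
      measureScene(sc, detector, segmenter, crop_side, post_config, palette),
      error = function(e) {
        warning(sprintf("scene %s day %d failed: %s", sc@wound_id, sc@day,
                        conditionMessage(e)), call. = FALSE)
        list(wound_px = NA_real_, splint_px = NA_real_)
      })
    if (is.na(res$wound_px))
      failures <- c(failures, sprintf("%s_d%02d", sc@wound_id, sc@day))
    rows[[i]] <- data.frame(wound_id = sc@wound_id, day = sc@day,
                            wound_px = res$wound_px,
                            splint_px = res$splint_px,
                            splint_imputed = FALSE, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  n_days <- max(records$day) + 1L
  series <- lapply(split(records, records$wound_id), function(r)
    buildSeries(r, geometry, imputation, days = 0:(n_days - 1L)))
  series <- unname(series)
  summary <- averageSeries(series)
  manifest <- list(detector = if (is.character(detector)) detector else "custom",
                   segmenter = if (is.character(segmenter)) segmenter
                               else "model",
                   imputation = imputation, crop_side = crop_side,
                   seed = as.integer(seed),
                   inner_diameter_mm = geometry@inner_diameter_mm,
                   thresholds = c(post_config@min_wound_pixel_intensity,
                                  post_config@min_splint_pixel_intensity),
                   min_wound_size = post_config@min_wound_size,
                   n_scenes = length(scenes), failures = failures,
                   package_version = as.character(
                     utils::packageVersion("woundmetry")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeMeasurementsTable(series, file.path(out_dir, "measurements.csv"))
    sm <- summary
    sm$mean_closure <- fmtNum(sm$mean_closure, 2L)
    utils::write.csv(sm, file.path(out_dir, "cohort_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(series = series, summary = summary, records = records,
       failures = failures, manifest = manifest)
}

# read back a directory written by writeCohort()
readCohortDir <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("startup error: no manifest.csv in input")
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    stem <- file.path(dir, sprintf("%s_d%02d", man$wound_id[i], man$day[i]))
    readScene(stem, man$wound_id[i], man$day[i], man$splint_present[i],
              man$mm_per_pixel[i])
  })
}
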