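#' @import methods
NULL

# ---- geometry / simulation parameter classes --------------------------------

#' Splint reference-ring geometry
#'
#' The silicone splint sutured around an excisional wound has a fixed inner
#' and outer diameter; the filled disk bounded by the inner circle is the
#' known reference area used to calibrate wound size from pixel counts.
#'
#' @slot inner_diameter_mm inner-circle diameter in mm (default 10).
#' @slot outer_diameter_mm outer-circle diameter in mm (default 16).
#' @export
setClass("SplintGeometry",
  representation(inner_diameter_mm = "numeric", outer_diameter_mm = "numeric"),
  prototype(inner_diameter_mm = 10, outer_diameter_mm = 16),
  validity = function(object) {
    if (!(object@outer_diameter_mm > object@inner_diameter_mm &&
          object@inner_diameter_mm > 0))
      return("need outer_diameter_mm > inner_diameter_mm > 0")
    TRUE
  })

#' @param inner_diameter_mm,outer_diameter_mm ring diameters in mm.
#' @rdname SplintGeometry-class
#' @return `splintGeometry()` returns a `SplintGeometry` object.
#' @export
#' @examples
#' g <- splintGeometry()
#' innerAreaMm2(g)  # pi * 25
splintGeometry <- function(inner_diameter_mm = 10, outer_diameter_mm = 16) {
  new("SplintGeometry", inner_diameter_mm = inner_diameter_mm,
      outer_diameter_mm = outer_diameter_mm)
}

#' Known inner-ring area in mm^2
#' @param geometry a `SplintGeometry`.
#' @return Area of the filled inner disk, pi * (inner_diameter/2)^2.
#' @export
innerAreaMm2 <- function(geometry) {
  stopifnot(is(geometry, "SplintGeometry"))
  pi * (geometry@inner_diameter_mm / 2)^2
}

#' Phantom healing-curve parameters
#'
#' Parametrizes the open-area fraction of a simulated wound over time: a
#' linear rise to `expansion_peak` at `expansion_day` (early wound expansion),
#' then a smooth power-law decay reaching zero exactly at `closure_day`.
#'
#' @slot initial_diameter_mm day-0 wound diameter in mm (default 6, the
#'   biopsy-punch size).
#' @slot closure_day day at which the open area reaches zero.
#' @slot expansion_peak maximum open-area fraction (>= 1) reached early.
#' @slot expansion_day day of the expansion peak.
#' @slot noise_sd multiplicative day-to-day area noise (sd of a lognormal-ish
#'   factor; 0 disables).
#' @slot decay_shape exponent of the post-peak decay (>1 gives the slow tail
#'   near closure seen in healing curves).
#' @export
setClass("HealingParams",
  representation(initial_diameter_mm = "numeric", closure_day = "numeric",
                 expansion_peak = "numeric", expansion_day = "numeric",
                 noise_sd = "numeric", decay_shape = "numeric"),
  prototype(initial_diameter_mm = 6, closure_day = 15, expansion_peak = 1.15,
            expansion_day = 2, noise_sd = 0.03, decay_shape = 2),
  validity = function(object) {
    if (object@initial_diameter_mm <= 0) return("initial_diameter_mm must be > 0")
    if (object@closure_day <= 0) return("closure_day must be > 0")
    if (object@expansion_peak < 1) return("expansion_peak must be >= 1")
    if (object@expansion_day < 0 || object@expansion_day >= object@closure_day)
      return("need 0 <= expansion_day < closure_day")
    TRUE
  })

#' @param initial_diameter_mm,closure_day,expansion_peak,expansion_day,noise_sd,decay_shape
#'   see slots.
#' @rdname HealingParams-class
#' @return `healingParams()` returns a `HealingParams` object.
#' @export
healingParams <- function(initial_diameter_mm = 6, closure_day = 15,
                          expansion_peak = 1.15, expansion_day = 2,
                          noise_sd = 0.03, decay_shape = 2) {
  new("HealingParams", initial_diameter_mm = initial_diameter_mm,
      closure_day = closure_day, expansion_peak = expansion_peak,
      expansion_day = expansion_day, noise_sd = noise_sd,
      decay_shape = decay_shape)
}

#' Image corruption settings for phantom rendering
#'
#' Nuisances applied to the rendered image (never to the ground-truth masks):
#' lighting gain, defocus blur, partial occlusion of the wound, a second
#' off-center wound, landscape framing, a missing splint, plus the number of
#' false-positive components injected when faking a model prediction.
#'
#' @slot lighting_gain multiplicative brightness factor (1 = neutral).
#' @slot blur_sigma Gaussian blur sigma in pixels (0 = sharp).
#' @slot occlusion_fraction fraction (0-1) of the wound covered by a
#'   semi-transparent gray polygon.
#' @slot extra_wound add a second, off-center wound component.
#' @slot landscape render a wider-than-tall frame.
#' @slot missing_splint omit the splint (empty splint-inner mask).
#' @slot false_component_count false components for [corruptPrediction()].
#' @export
setClass("CorruptionSpec",
  representation(lighting_gain = "numeric", blur_sigma = "numeric",
                 occlusion_fraction = "numeric", extra_wound = "logical",
                 landscape = "logical", missing_splint = "logical",
                 false_component_count = "integer"),
  prototype(lighting_gain = 1, blur_sigma = 0, occlusion_fraction = 0,
            extra_wound = FALSE, landscape = FALSE, missing_splint = FALSE,
            false_component_count = 0L),
  validity = function(object) {
    if (object@occlusion_fraction < 0 || object@occlusion_fraction > 1)
      return("occlusion_fraction must lie in [0, 1]")
    if (object@false_component_count < 0L)
      return("false_component_count must be >= 0")
    TRUE
  })

#' @param lighting_gain,blur_sigma,occlusion_fraction,extra_wound,landscape,missing_splint,false_component_count
#'   see slots.
#' @rdname CorruptionSpec-class
#' @return `corruptionSpec()` returns a `CorruptionSpec` object.
#' @export
corruptionSpec <- function(lighting_gain = 1, blur_sigma = 0,
                           occlusion_fraction = 0, extra_wound = FALSE,
                           landscape = FALSE, missing_splint = FALSE,
                           false_component_count = 0L) {
  new("CorruptionSpec", lighting_gain = lighting_gain, blur_sigma = blur_sigma,
      occlusion_fraction = occlusion_fraction, extra_wound = extra_wound,
      landscape = landscape, missing_splint = missing_splint,
      false_component_count = as.integer(false_component_count))
}

# ---- scene ------------------------------------------------------------------

#' A synthetic splinted-wound scene with exact ground truth
#'
#' One rendered photograph plus its ground-truth wound and splint-inner masks,
#' a normalized bounding box for the wound of interest, and the generation
#' record (true open area in mm^2, mm-per-pixel scale, seed).
#'
#' @slot image numeric H x W x 3 array, 0-255.
#' @slot wound_mask logical H x W matrix (all wound components).
#' @slot splint_inner_mask logical H x W matrix (filled inner disk; empty
#'   when the splint is missing).
#' @slot bbox named numeric (cx, cy, w, h, confidence), normalized to [0,1].
#' @slot day integer day index (0-based).
#' @slot wound_id character identifier, e.g. "C1-M1-L".
#' @slot splint_present logical.
#' @slot params list: mm_per_pixel, true_area_mm2 (wound-of-interest only),
#'   seed, healing fraction, and the corruption applied.
#' @export
setClass("PhantomScene",
  representation(image = "array", wound_mask = "matrix",
                 splint_inner_mask = "matrix", bbox = "numeric",
                 day = "integer", wound_id = "character",
                 splint_present = "logical", params = "list"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3L] != 3L) return("image must be H x W x 3")
    if (!identical(dim(object@wound_mask), d[1:2]) ||
        !identical(dim(object@splint_inner_mask), d[1:2]))
      return("masks must share the image's H x W shape")
    if (object@day < 0L) return("day must be >= 0")
    if (object@splint_present && !any(object@splint_inner_mask))
      return("splint_present but splint_inner_mask empty")
    if (!object@splint_present && any(object@splint_inner_mask))
      return("splint absent but splint_inner_mask non-empty")
    TRUE
  })

# ---- segmentation-side containers -------------------------------------------

#' Per-class 8-bit score maps over one crop
#'
#' The object the mask-cleanup algorithm thresholds: a wound channel and a
#' splint-inner channel, each an H x W matrix of scores on the 0-255 scale.
#'
#' @slot wound numeric matrix, values in [0, 255].
#' @slot splint numeric matrix, values in [0, 255].
#' @export
setClass("ProbabilityMaps",
  representation(wound = "matrix", splint = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@wound), dim(object@splint)))
      return("wound and splint maps must share shape")
    rng <- range(object@wound, object@splint, 0)
    if (rng[1L] < 0 || rng[2L] > 255) return("scores must lie in [0, 255]")
    TRUE
  })

#' @param wound,splint score matrices (0-255).
#' @rdname ProbabilityMaps-class
#' @return `probabilityMaps()` returns a `ProbabilityMaps` object.
#' @export
probabilityMaps <- function(wound, splint) {
  new("ProbabilityMaps", wound = wound, splint = splint)
}

#' Post-processed binary masks for one crop
#'
#' Output of the mask-cleanup step: at most one connected component per
#' channel, with flags recording whether anything survived cleanup.
#'
#' @slot wound logical matrix (<= 1 component).
#' @slot splint logical matrix (<= 1 component).
#' @slot wound_found,splint_found logical flags.
#' @export
setClass("CleanMasks",
  representation(wound = "matrix", splint = "matrix",
                 wound_found = "logical", splint_found = "logical"),
  validity = function(object) {
    if (!identical(dim(object@wound), dim(object@splint)))
      return("masks must share shape")
    if (object@wound_found != any(object@wound) ||
        object@splint_found != any(object@splint))
      return("found flags must match mask emptiness")
    TRUE
  })

cleanMasks <- function(wound, splint) {
  new("CleanMasks", wound = wound, splint = splint,
      wound_found = any(wound), splint_found = any(splint))
}

# ---- configuration classes --------------------------------------------------

#' Mask-cleanup configuration
#'
#' Constants of the wound-mask cleanup procedure: score thresholds for the
#' two channels, the minimum wound component size, the crop centroid against
#' which wound candidates are ranked, and the pixel connectivity.
#'
#' @slot min_wound_pixel_intensity wound-channel threshold (default 20).
#' @slot min_splint_pixel_intensity splint-channel threshold (default 40).
#' @slot min_wound_size components must exceed this pixel count (default 50;
#'   strictly greater-than).
#' @slot image_centroid (x, y) center of the crop, default (176, 176) for a
#'   352 x 352 crop.
#' @slot connectivity 4 or 8 (default 8).
#' @slot max_centroid_distance optional cap (px) on the winning candidate's
#'   distance from the centroid; `Inf` (default) disables it.
#' @export
setClass("PostprocessConfig",
  representation(min_wound_pixel_intensity = "numeric",
                 min_splint_pixel_intensity = "numeric",
                 min_wound_size = "numeric", image_centroid = "numeric",
                 connectivity = "numeric", max_centroid_distance = "numeric"),
  prototype(min_wound_pixel_intensity = 20, min_splint_pixel_intensity = 40,
            min_wound_size = 50, image_centroid = c(176, 176),
            connectivity = 8, max_centroid_distance = Inf),
  validity = function(object) {
    th <- c(object@min_wound_pixel_intensity, object@min_splint_pixel_intensity)
    if (any(th < 0 | th > 255)) return("thresholds must lie in [0, 255]")
    if (object@min_wound_size < 1) return("min_wound_size must be >= 1")
    if (!object@connectivity %in% c(4, 8)) return("connectivity must be 4 or 8")
    if (length(object@image_centroid) != 2L) return("image_centroid is (x, y)")
    TRUE
  })

#' @param min_wound_pixel_intensity,min_splint_pixel_intensity,min_wound_size,image_centroid,connectivity,max_centroid_distance
#'   see slots.
#' @rdname PostprocessConfig-class
#' @return `postprocessConfig()` returns a `PostprocessConfig` object.
#' @export
postprocessConfig <- function(min_wound_pixel_intensity = 20,
                              min_splint_pixel_intensity = 40,
                              min_wound_size = 50,
                              image_centroid = c(176, 176),
                              connectivity = 8,
                              max_centroid_distance = Inf) {
  new("PostprocessConfig",
      min_wound_pixel_intensity = min_wound_pixel_intensity,
      min_splint_pixel_intensity = min_splint_pixel_intensity,
      min_wound_size = min_wound_size, image_centroid = image_centroid,
      connectivity = connectivity,
      max_centroid_distance = max_centroid_distance)
}

#' On-the-fly augmentation configuration
#'
#' Geometric transforms (flips, rotation) are applied identically to image
#' and masks; photometric transforms (linear contrast 127 + alpha*(v - 127),
#' intensity multiplier, Gaussian blur) touch the image only.
#'
#' @slot flip_prob probability of each of vertical/horizontal flip (0.5).
#' @slot rotation_range degrees, default c(-90, 90).
#' @slot contrast_alpha_range default c(0.5, 1.5).
#' @slot intensity_range multiplier range, default c(0.5, 1.5).
#' @slot blur_prob probability of Gaussian blur (0.35).
#' @slot blur_sigma_range sigma range in px, default c(0, 6).
#' @export
setClass("AugmentationConfig",
  representation(flip_prob = "numeric", rotation_range = "numeric",
                 contrast_alpha_range = "numeric", intensity_range = "numeric",
                 blur_prob = "numeric", blur_sigma_range = "numeric"),
  prototype(flip_prob = 0.5, rotation_range = c(-90, 90),
            contrast_alpha_range = c(0.5, 1.5), intensity_range = c(0.5, 1.5),
            blur_prob = 0.35, blur_sigma_range = c(0, 6)),
  validity = function(object) {
    pr <- c(object@flip_prob, object@blur_prob)
    if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
    for (r in list(object@rotation_range, object@contrast_alpha_range,
                   object@intensity_range, object@blur_sigma_range))
      if (length(r) != 2L || r[1L] > r[2L]) return("ranges must be ordered pairs")
    TRUE
  })

#' @param flip_prob,rotation_range,contrast_alpha_range,intensity_range,blur_prob,blur_sigma_range
#'   see slots.
#' @rdname AugmentationConfig-class
#' @return `augmentationConfig()` returns an `AugmentationConfig` object.
#' @export
augmentationConfig <- function(flip_prob = 0.5, rotation_range = c(-90, 90),
                               contrast_alpha_range = c(0.5, 1.5),
                               intensity_range = c(0.5, 1.5),
                               blur_prob = 0.35, blur_sigma_range = c(0, 6)) {
  new("AugmentationConfig", flip_prob = flip_prob,
      rotation_range = rotation_range,
      contrast_alpha_range = contrast_alpha_range,
      intensity_range = intensity_range, blur_prob = blur_prob,
      blur_sigma_range = blur_sigma_range)
}

#' Segmenter training configuration
#'
#' Desk-scale defaults: 30 epochs on 64-px crops with a narrow network. The
#' full-scale recipe (1000 epochs, batch 4, 352-px crops) is expressible by
#' raising `epochs` and `input_size`.
#'
#' @slot epochs training epochs (default 30).
#' @slot batch_size minibatch size (default 4).
#' @slot learning_rate Adam step size (default 1e-3).
#' @slot seed integer RNG seed for init, shuffling and augmentation.
#' @slot width channels in the first encoder block (default 8).
#' @slot input_size square crop side in px fed to the network (default 64).
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batch_size = "integer",
                 learning_rate = "numeric", seed = "integer",
                 width = "integer", input_size = "integer"),
  prototype(epochs = 30L, batch_size = 4L, learning_rate = 1e-3, seed = 1L,
            width = 8L, input_size = 64L),
  validity = function(object) {
    if (any(c(object@epochs, object@batch_size, object@width,
              object@input_size) < 1L)) return("counts must be positive")
    if (object@input_size %% 2L != 0L) return("input_size must be even")
    TRUE
  })

#' @param epochs,batch_size,learning_rate,seed,width,input_size see slots.
#' @rdname TrainConfig-class
#' @return `trainConfig()` returns a `TrainConfig` object.
#' @export
trainConfig <- function(epochs = 30L, batch_size = 4L, learning_rate = 1e-3,
                        seed = 1L, width = 8L, input_size = 64L) {
  new("TrainConfig", epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      seed = as.integer(seed), width = as.integer(width),
      input_size = as.integer(input_size))
}

#' A trained encoder-decoder segmentation model
#'
#' @slot weights named list of parameter arrays.
#' @slot config the `TrainConfig` used.
#' @slot log data.frame(epoch, train_loss, val_loss, train_iou, val_iou).
#' @export
setClass("SegmenterModel",
  representation(weights = "list", config = "TrainConfig", log = "data.frame"))

# ---- measurement containers -------------------------------------------------

#' One wound's ordered day-by-day measurement series
#'
#' @slot wound_id identifier.
#' @slot records data.frame with one row per day: `day`, `wound_px`,
#'   `splint_px`, `area_mm2`, `splint_imputed`, `timepoint_filled`.
#' @slot day0_area_mm2 the day-0 open area (closure baseline).
#' @slot closure per-day closure percentages aligned with `records$day`.
#' @export
setClass("WoundSeries",
  representation(wound_id = "character", records = "data.frame",
                 day0_area_mm2 = "numeric", closure = "numeric"),
  validity = function(object) {
    r <- object@records
    need <- c("day", "wound_px", "splint_px", "area_mm2", "splint_imputed",
              "timepoint_filled")
    if (!all(need %in% names(r)))
      return(paste("records needs columns:", paste(need, collapse = ", ")))
    if (is.unsorted(r$day, strictly = TRUE)) return("days must strictly increase")
    if (length(object@closure) != nrow(r))
      return("closure must align with records")
    TRUE
  })

# ---- accessors & show -------------------------------------------------------

#' @describeIn PhantomScene-class ground-truth wound mask.
#' @param scene,object a `PhantomScene`.
#' @export
woundMask <- function(scene) { stopifnot(is(scene, "PhantomScene")); scene@wound_mask }

#' @describeIn PhantomScene-class ground-truth splint-inner mask.
#' @export
splintInnerMask <- function(scene) { stopifnot(is(scene, "PhantomScene")); scene@splint_inner_mask }

#' @describeIn PhantomScene-class rendered RGB image (H x W x 3, 0-255).
#' @export
sceneImage <- function(scene) { stopifnot(is(scene, "PhantomScene")); scene@image }

#' @describeIn WoundSeries-class measurement records, one row per day.
#' @param series,object a `WoundSeries`.
#' @export
seriesRecords <- function(series) { stopifnot(is(series, "WoundSeries")); series@records }

#' @describeIn WoundSeries-class closure-percentage curve aligned with days.
#' @export
closureCurve <- function(series) {
  stopifnot(is(series, "WoundSeries"))
  stats::setNames(series@closure, series@records$day)
}

#' @describeIn WoundSeries-class wound identifier.
#' @export
woundId <- function(series) { stopifnot(is(series, "WoundSeries")); series@wound_id }

setMethod("show", "PhantomScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomScene %s day %d: %dx%d px, splint %s, wound %d px, %.3f mm^2 open\n",
              object@wound_id, object@day, d[1L], d[2L],
              if (object@splint_present) "present" else "missing",
              sum(object@wound_mask), object@params$true_area_mm2))
})

setMethod("show", "CleanMasks", function(object) {
  cat(sprintf("CleanMasks: wound %s (%d px), splint %s (%d px)\n",
              if (object@wound_found) "found" else "absent", sum(object@wound),
              if (object@splint_found) "found" else "absent", sum(object@splint)))
})

setMethod("show", "WoundSeries", function(object) {
  cat(sprintf("WoundSeries %s: days %d..%d, day-0 area %.3f mm^2, final closure %.1f%%\n",
              object@wound_id, min(object@records$day), max(object@records$day),
              object@day0_area_mm2, utils::tail(object@closure, 1L)))
})

setMethod("show", "SegmenterModel", function(object) {
  n <- sum(vapply(object@weights, length, integer(1)))
  cat(sprintf("SegmenterModel: %d parameters, input %dx%d, trained %d epochs\n",
              n, object@config@input_size, object@config@input_size,
              nrow(object@log)))
})
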