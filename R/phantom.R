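# Synthetic splinted-wound phantoms with exact ground truth.
#
# Phantoms emulate the nuisances of real wound-study photographs — warm/cold
# lighting, defocus blur, partial occlusion, landscape/portrait framing,
# second visible wounds, missing or damaged splints, and camera-distance
# (mm-per-pixel) changes — while keeping the ground-truth masks exact: all
# corruption is applied to the rendered image, never to the masks.

#' Default phantom rendering palette
#'
#' Mean RGB colors (0-255) used by the renderer and by the color-distance
#' reference segmenter. Skin, wound and splint are well separated in RGB so
#' segmentation difficulty is controlled by the corruption settings, not by
#' color ambiguity.
#'
#' @return Named list of length-3 RGB vectors: `skin`, `wound`, `splint`,
#'   `occluder`.
#' @export
phantomPalette <- function() {
  list(skin = c(205, 160, 140), wound = c(150, 45, 40),
       splint = c(240, 240, 245), occluder = c(120, 120, 120))
}

#' Open-area fraction of the phantom healing curve
#'
#' Piecewise curve of the open wound area relative to day 0: a linear rise to
#' `expansion_peak` at `expansion_day` (early wound expansion), then a smooth
#' power decay `peak * ((closure_day - d) / (closure_day - expansion_day))^q`
#' reaching zero exactly at `closure_day` and staying zero after.
#'
#' @param day numeric vector of days (>= 0).
#' @param params a [HealingParams-class] object.
#' @return Open-area fraction(s): 1 at day 0, peak at `expansion_day`,
#'   non-increasing afterwards, 0 at and after `closure_day`.
#' @export
#' @examples
#' p <- healingParams(expansion_peak = 1.2, expansion_day = 2, closure_day = 15)
#' healingFraction(0, p)   # 1
#' healingFraction(2, p)   # 1.2
#' healingFraction(20, p)  # 0
healingFraction <- function(day, params = healingParams()) {
  stopifnot(is(params, "HealingParams"))
  if (any(day < 0)) stop("day must be >= 0")
  ed <- params@expansion_day; cd <- params@closure_day
  pk <- params@expansion_peak; q <- params@decay_shape
  f <- numeric(length(day))
  rise <- day <= ed & ed > 0
  f[rise] <- 1 + (pk - 1) * day[rise] / ed
  if (ed == 0) f[day == 0] <- pk
  mid <- day > ed & day < cd
  f[mid] <- pk * ((cd - day[mid]) / (cd - ed))^q
  f[day == 0] <- 1   # exact baseline regardless of piece
  f[day >= cd] <- 0
  f
}

# Canvas dimensions: short side fits the outer splint with margin; frames are
# 4:3, portrait unless corruption$landscape.
phantomCanvas <- function(outer_r_px, landscape) {
  short <- ceiling(2 * outer_r_px * 1.15)
  long <- ceiling(short * 4 / 3)
  if (landscape) c(short, long) else c(long, short)
}

#' Render one synthetic splinted-wound scene
#'
#' Draws a circular (optionally irregular-boundary) wound inside an annular
#' splint on skin-colored background, records the exact ground-truth masks,
#' then applies the requested image corruptions. The realized open area in
#' mm^2 (wound-of-interest pixel count times `mm_per_pixel^2`) is stored in
#' the generation record.
#'
#' @param geometry a [SplintGeometry-class].
#' @param healing a [HealingParams-class].
#' @param corruption a [CorruptionSpec-class].
#' @param day day index (>= 0).
#' @param mm_per_pixel physical scale (mm per pixel, default 0.05).
#' @param wound_id identifier stored on the scene.
#' @param canvas optional c(H, W); defaults to a 4:3 frame that contains the
#'   outer splint with margin. A canvas too small for the splint is an error.
#' @param boundary_irregularity total amplitude of the low-order radial
#'   Fourier perturbation of the wound boundary, as a fraction of the radius
#'   (default 0.08, capped at 0.15).
#' @param seed optional integer seed; rendering is bit-reproducible given it.
#' @param render_image synthesize the RGB image (`TRUE`); with `FALSE` only
#'   the ground-truth masks and record are produced (cheaper when just pixel
#'   counts are needed); masks and record are identical either way.
#' @return A [PhantomScene-class].
#' @export
renderPhantom <- function(geometry = splintGeometry(),
                          healing = healingParams(),
                          corruption = corruptionSpec(),
                          day = 0, mm_per_pixel = 0.05, wound_id = "W",
                          canvas = NULL, boundary_irregularity = 0.08,
                          seed = NULL, render_image = TRUE) {
  stopifnot(is(geometry, "SplintGeometry"), is(healing, "HealingParams"),
            is(corruption, "CorruptionSpec"), mm_per_pixel > 0)
  boundary_irregularity <- min(boundary_irregularity, 0.15)
  withSeed(seed, {
    outer_r <- geometry@outer_diameter_mm / 2 / mm_per_pixel
    inner_r <- geometry@inner_diameter_mm / 2 / mm_per_pixel
    if (is.null(canvas)) canvas <- phantomCanvas(outer_r, corruption@landscape)
    h <- canvas[1L]; w <- canvas[2L]
    if (2 * outer_r > min(h, w))
      stop("canvas too small to contain the outer splint")

    frac <- healingFraction(day, healing)
    if (healing@noise_sd > 0 && day > 0)
      frac <- frac * exp(stats::rnorm(1L, 0, healing@noise_sd))
    r0 <- healing@initial_diameter_mm / 2 / mm_per_pixel
    wr <- r0 * sqrt(frac)

    # splint center with mild jitter, keeping the outer ring in frame
    jit <- 0.04 * min(h, w)
    cx <- w / 2 + stats::runif(1L, -jit, jit)
    cy <- h / 2 + stats::runif(1L, -jit, jit)

    harmonics <- NULL
    if (boundary_irregularity > 0 && wr > 0) {
      k <- 2:4
      amp <- stats::runif(3L)
      amp <- amp / sum(amp) * boundary_irregularity
      harmonics <- data.frame(k = k, amp = amp,
                              phase = stats::runif(3L, 0, 2 * pi))
      # keep the perturbed wound strictly inside the inner disk
      wr <- min(wr, inner_r * 0.92 / (1 + boundary_irregularity))
    }

    shape <- c(h, w)
    wound_main <- if (wr > 0) rasterDisk(shape, cx, cy, wr, harmonics)
                  else matrix(FALSE, h, w)
    wound_mask <- wound_main
    if (corruption@extra_wound) {
      ang <- stats::runif(1L, 0, 2 * pi)
      er <- max(1.2 / mm_per_pixel, 3)
      ex <- cx + cos(ang) * (outer_r + 2.5 * er)
      ey <- cy + sin(ang) * (outer_r + 2.5 * er)
      ex <- min(max(ex, er + 1), w - er - 1)
      ey <- min(max(ey, er + 1), h - er - 1)
      extra <- rasterDisk(shape, ex, ey, er)
      wound_mask <- wound_mask | (extra & !wound_main)
    }
    splint_inner <- if (corruption@missing_splint) matrix(FALSE, h, w)
                    else rasterDisk(shape, cx, cy, inner_r)

    # ---- render image -------------------------------------------------------
    pal <- phantomPalette()
    img <- array(0, dim = c(h, w, 3L))
    skin_tex <- matrix(stats::rnorm(h * w, 0, 4), h, w)
    d2 <- {
      xc <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
      yc <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
      sqrt((xc - cx)^2 + (yc - cy)^2)
    }
    if (render_image) {
      annulus <- !corruption@missing_splint & d2 >= inner_r & d2 <= outer_r
      for (k in 1:3) {
        ch <- matrix(pal$skin[k], h, w) + skin_tex
        ch[annulus] <- pal$splint[k] + skin_tex[annulus] * 0.3
        ch[wound_mask] <- pal$wound[k] + skin_tex[wound_mask] * 0.5
        img[, , k] <- ch
      }
    }

    # occlusion: semi-transparent gray band over part of the wound (image
    # only; masks remain ground truth)
    if (render_image && corruption@occlusion_fraction > 0 && any(wound_main)) {
      f <- corruption@occlusion_fraction
      ang <- stats::runif(1L, 0, 2 * pi)
      fgi <- which(wound_main)
      px <- ((fgi - 1L) %/% h) + 0.5; py <- ((fgi - 1L) %% h) + 0.5
      proj <- cos(ang) * px + sin(ang) * py
      thr <- stats::quantile(proj, 1 - f)
      projall <- cos(ang) * (matrix(rep(seq_len(w) - 0.5, each = h), h, w)) +
                 sin(ang) * (matrix(rep(seq_len(h) - 0.5, times = w), h, w))
      band <- projall >= thr & d2 <= wr * 1.4
      alpha <- 0.65
      for (k in 1:3)
        img[, , k][band] <- (1 - alpha) * img[, , k][band] + alpha * pal$occluder[k]
    }

    img <- img * corruption@lighting_gain
    if (corruption@blur_sigma > 0) img <- blurImage(img, corruption@blur_sigma)
    img <- clip255(img)

    # bounding box of the wound of interest, normalized
    if (any(wound_main)) {
      fgi <- which(wound_main)
      rr <- ((fgi - 1L) %% h) + 1L; cc <- ((fgi - 1L) %/% h) + 1L
      bbox <- c(cx = mean(cc - 0.5) / w, cy = mean(rr - 0.5) / h,
                w = (diff(range(cc)) + 1) / w, h = (diff(range(rr)) + 1) / h,
                confidence = 1)
    } else {
      bbox <- c(cx = cx / w, cy = cy / h, w = 0, h = 0, confidence = 0)
    }

    new("PhantomScene", image = img, wound_mask = wound_mask,
        splint_inner_mask = splint_inner, bbox = bbox, day = as.integer(day),
        wound_id = wound_id, splint_present = !corruption@missing_splint,
        params = list(mm_per_pixel = mm_per_pixel,
                      true_area_mm2 = sum(wound_main) * mm_per_pixel^2,
                      healing_fraction = frac, center = c(x = cx, y = cy),
                      wound_radius_px = wr, seed = seed,
                      corruption = corruption))
  })
}

# ---- cohort -----------------------------------------------------------------

#' A simulated cohort of phantom wound time series
#'
#' @slot scenes list of [PhantomScene-class], ordered by wound then day.
#' @slot manifest data.frame: `wound_id`, `day`, `splint_present`,
#'   `true_area_mm2`, `mm_per_pixel`, `seed`.
#' @slot seed the cohort seed.
#' @export
setClass("PhantomCohort",
  representation(scenes = "list", manifest = "data.frame", seed = "integer"))

setMethod("show", "PhantomCohort", function(object) {
  m <- object@manifest
  cat(sprintf("PhantomCohort: %d wounds x %d days (%d scenes), %.0f%% splints present\n",
              length(unique(m$wound_id)), length(unique(m$day)), nrow(m),
              100 * mean(m$splint_present)))
})

#' @describeIn PhantomCohort-class cohort manifest (ground truth per scene).
#' @param cohort a `PhantomCohort`.
#' @export
cohortManifest <- function(cohort) {
  stopifnot(is(cohort, "PhantomCohort")); cohort@manifest
}

#' @describeIn PhantomCohort-class list of scenes.
#' @export
cohortScenes <- function(cohort) {
  stopifnot(is(cohort, "PhantomCohort")); cohort@scenes
}

defaultHealingSampler <- function() {
  healingParams(initial_diameter_mm = stats::runif(1L, 5.4, 6.6),
                closure_day = stats::runif(1L, 12, 15),
                expansion_peak = stats::runif(1L, 1, 1.25),
                expansion_day = sample(1:3, 1L),
                noise_sd = 0.03)
}

defaultCorruptionSampler <- function() {
  corruptionSpec(
    lighting_gain = stats::runif(1L, 0.8, 1.25),
    blur_sigma = if (stats::runif(1L) < 0.3) stats::runif(1L, 0.5, 2) else 0,
    occlusion_fraction = if (stats::runif(1L) < 0.2) stats::runif(1L, 0.1, 0.3) else 0,
    extra_wound = stats::runif(1L) < 0.1,
    landscape = stats::runif(1L) < 0.5)
}

#' Generate a phantom cohort of wound time series
#'
#' Simulates `n_mice` mice with two wounds each ("L"/"R"), every wound imaged
#' daily over days 0..`n_days - 1`. Per-wound healing parameters and
#' per-scene corruptions are drawn from the supplied samplers; the physical
#' scale varies scene-to-scene by +/-20% around `mm_per_pixel` to emulate
#' camera-distance changes (the ring calibration must cancel it).
#'
#' @param n_mice number of mice (two wounds each).
#' @param n_days days per series (day 0 .. n_days - 1).
#' @param geometry a [SplintGeometry-class].
#' @param healing_sampler function() -> [HealingParams-class], drawn once per
#'   wound. Default varies punch size, closure day and expansion mildly.
#' @param corruption_sampler function() -> [CorruptionSpec-class], drawn once
#'   per scene.
#' @param missing_splint_pattern `NULL` (all splints present),
#'   `list(type = "fraction", value = f)` to drop the splint from
#'   `floor(f * n_scenes)` randomly chosen scenes, or
#'   `list(type = "window", from = a)` to drop it from every scene with
#'   day in `[a, a + 7]` (the fixed 8-day window design).
#' @param mm_per_pixel base physical scale. Camera distance varies by
#'   imaging session: each (mouse, day) session draws a factor uniformly in
#'   `[1 - scale_jitter, 1 + scale_jitter]`, shared by that mouse's two
#'   wounds up to a small (3%) within-session jitter and clamped to the same
#'   band.
#' @param scale_jitter half-width of the relative scale variation (0.2).
#' @param seed cohort seed; generation is reproducible given it.
#' @param render_image render RGB images (`TRUE`) or masks/ground truth only
#'   (`FALSE`; cheaper when only pixel counts are needed).
#' @return A [PhantomCohort-class].
#' @export
generateCohort <- function(n_mice = 4, n_days = 16,
                           geometry = splintGeometry(),
                           healing_sampler = defaultHealingSampler,
                           corruption_sampler = defaultCorruptionSampler,
                           missing_splint_pattern = NULL,
                           mm_per_pixel = 0.15, scale_jitter = 0.2,
                           seed = 1L, render_image = TRUE) {
  stopifnot(n_days >= 1, n_mice >= 1)
  if (!is.null(missing_splint_pattern)) {
    ok <- is.list(missing_splint_pattern) &&
      missing_splint_pattern$type %in% c("fraction", "window")
    if (!ok) stop("missing_splint_pattern must be NULL, fraction or window")
  }
  wounds <- as.vector(t(outer(sprintf("M%d", seq_len(n_mice)), c("L", "R"),
                              paste, sep = "-")))
  n_scenes <- length(wounds) * n_days
  withSeed(seed, {
    scene_seeds <- sample.int(.Machine$integer.max - 1L, n_scenes)
    healings <- stats::setNames(lapply(wounds, function(w) healing_sampler()),
                                wounds)
    corruptions <- lapply(seq_len(n_scenes), function(i) corruption_sampler())
    # camera distance per imaging session (mouse x day), shared by the L/R
    # wounds of that session up to a small jitter
    session <- matrix(stats::runif(n_mice * n_days, 1 - scale_jitter,
                                   1 + scale_jitter), n_mice, n_days)
    wound_index <- rep(seq_along(wounds), each = n_days)
    mouse_index <- ceiling(wound_index / 2)
    day_index <- rep(seq_len(n_days), times = length(wounds))
    fac <- session[cbind(mouse_index, day_index)] *
      stats::runif(n_scenes, 0.97, 1.03)
    fac <- pmin(pmax(fac, 1 - scale_jitter), 1 + scale_jitter)
    scales <- mm_per_pixel * fac
    # realized missing-splint pattern
    missing <- rep(FALSE, n_scenes)
    days_of <- rep(0:(n_days - 1L), times = length(wounds))
    if (!is.null(missing_splint_pattern)) {
      if (missing_splint_pattern$type == "fraction") {
        k <- floor(missing_splint_pattern$value * n_scenes)
        missing[sample.int(n_scenes, k)] <- TRUE
      } else {
        a <- missing_splint_pattern$from
        missing <- days_of >= a & days_of <= a + 7L
      }
    }
    scenes <- vector("list", n_scenes)
    i <- 0L
    for (wid in wounds) for (d in 0:(n_days - 1L)) {
      i <- i + 1L
      cor <- corruptions[[i]]
      cor@missing_splint <- cor@missing_splint || missing[i]
      scenes[[i]] <- renderPhantomMaybeImage(
        geometry, healings[[wid]], cor, d, scales[i], wid,
        seed = scene_seeds[i], render_image = render_image)
    }
    manifest <- data.frame(
      wound_id = vapply(scenes, function(s) s@wound_id, character(1)),
      day = vapply(scenes, function(s) s@day, integer(1)),
      splint_present = vapply(scenes, function(s) s@splint_present, logical(1)),
      true_area_mm2 = vapply(scenes, function(s) s@params$true_area_mm2,
                             numeric(1)),
      mm_per_pixel = vapply(scenes, function(s) s@params$mm_per_pixel,
                            numeric(1)),
      seed = scene_seeds, stringsAsFactors = FALSE)
    new("PhantomCohort", scenes = scenes, manifest = manifest,
        seed = as.integer(seed))
  })
}

# render with or without the RGB image (masks are always exact)
renderPhantomMaybeImage <- function(geometry, healing, corruption, day, mpp,
                                    wound_id, seed, render_image) {
  renderPhantom(geometry, healing, corruption, day, mpp, wound_id,
                seed = seed, render_image = render_image)
}

# ---- prediction corruption (fixture for mask cleanup) -----------------------

#' Fake a noisy model prediction from clean masks
#'
#' Builds 8-bit score maps equal to `255 * mask`, then injects off-center
#' false-positive components into the wound channel (each at least
#' `min_component_area` pixels, placed farther from the crop center than the
#' true wound and disjoint from it) and salt noise strictly below
#' `noise_level` on background pixels of both channels. Because the salt
#' stays below the wound threshold (20), thresholding alone removes it; the
#' false components are what the component-selection cleanup must remove.
#'
#' @param masks a [CleanMasks-class] (or list with logical `wound`, `splint`).
#' @param false_component_count how many false components to inject.
#' @param noise_level salt amplitude upper bound (exclusive), default 20.
#' @param noise_density fraction of background pixels receiving salt.
#' @param min_component_area minimum false-component pixel count (default 80).
#' @param seed optional integer seed.
#' @return A [ProbabilityMaps-class].
#' @export
corruptPrediction <- function(masks, false_component_count = 0L,
                              noise_level = 20, noise_density = 0.005,
                              min_component_area = 80, seed = NULL) {
  if (is(masks, "CleanMasks")) masks <- list(wound = masks@wound,
                                             splint = masks@splint)
  stopifnot(is.matrix(masks$wound), is.matrix(masks$splint))
  h <- nrow(masks$wound); w <- ncol(masks$wound)
  withSeed(seed, {
    wmap <- 255 * (masks$wound != 0)
    smap <- 255 * (masks$splint != 0)
    r_false <- ceiling(sqrt(min_component_area / pi)) + 1
    ccx <- w / 2; ccy <- h / 2
    true_d <- if (any(masks$wound)) {
      st <- componentStats(labelComponents(masks$wound, 8))
      max(sqrt((st$cx - ccx)^2 + (st$cy - ccy)^2))
    } else 0
    placed <- masks$wound != 0
    n_done <- 0L
    tries <- 0L
    while (n_done < false_component_count && tries < 500L) {
      tries <- tries + 1L
      ang <- stats::runif(1L, 0, 2 * pi)
      dist <- stats::runif(1L, max(true_d + 3 * r_false, 0.3 * min(h, w)),
                           0.48 * min(h, w))
      fx <- ccx + cos(ang) * dist; fy <- ccy + sin(ang) * dist
      if (fx < r_false + 1 || fx > w - r_false - 1 ||
          fy < r_false + 1 || fy > h - r_false - 1) next
      disk <- rasterDisk(c(h, w), fx, fy, r_false)
      if (any(disk & placed)) next
      wmap[disk] <- 255
      placed <- placed | disk
      n_done <- n_done + 1L
    }
    if (n_done < false_component_count)
      stop("could not place the requested false components")
    if (noise_density > 0 && noise_level > 1) {
      for (nm in c("wmap", "smap")) {
        m <- get(nm)
        bg <- which(m == 0)
        k <- floor(noise_density * length(bg))
        if (k > 0) {
          pick <- sample(bg, k)
          m[pick] <- stats::runif(k, 1, noise_level - 1e-9)
          assign(nm, m)
        }
      }
    }
    probabilityMaps(wmap, smap)
  })
}

# ---- scene export / import --------------------------------------------------

#' Write a phantom scene to disk (PNG + label mask + annotation JSON)
#'
#' Writes `<stem>.png` (RGB image), `<stem>_label.png` (8-bit label mask:
#' 0 background, 1 wound, 2 splint-inner) and `<stem>.json` (LabelMe-style
#' polygon annotation traced from the masks).
#'
#' @param scene a [PhantomScene-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the file stem used.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "PhantomScene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("%s_d%02d", scene@wound_id, scene@day))
  png::writePNG(scene@image / 255, paste0(stem, ".png"))
  lab <- matrix(0L, nrow(scene@wound_mask), ncol(scene@wound_mask))
  lab[scene@splint_inner_mask] <- 2L
  lab[scene@wound_mask] <- 1L
  png::writePNG(lab / 255, paste0(stem, "_label.png"))
  anns <- c(maskToAnnotations(scene@wound_mask, "wound"),
            if (scene@splint_present)
              maskToAnnotations(scene@splint_inner_mask, "splint"))
  writeAnnotationDocument(anns, paste0(stem, ".json"),
                          image_size = dim(scene@wound_mask))
  invisible(stem)
}

#' Write a whole cohort: scenes plus a manifest CSV
#'
#' @param cohort a [PhantomCohort-class].
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PhantomCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sc in cohort@scenes) writeScene(sc, dir)
  man <- cohort@manifest
  man$true_area_mm2 <- fmtNum(man$true_area_mm2, 4L)
  man$mm_per_pixel <- fmtNum(man$mm_per_pixel, 6L)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scene written by [writeScene()]
#'
#' Reconstructs image and masks from the image/label PNG pair. The
#' splint-inner mask is recovered by hole-filling the splint label (wound
#' pixels inside the ring are labelled as wound, so the inner disk is the
#' filled version of label 2).
#'
#' @param stem file stem as returned by [writeScene()] (no extension).
#' @param wound_id,day,splint_present,mm_per_pixel metadata (from a manifest).
#' @return A [PhantomScene-class] (generation record holds only what the
#'   files carry).
#' @export
readScene <- function(stem, wound_id = basename(stem), day = 0L,
                      splint_present = NA, mm_per_pixel = NA_real_) {
  img <- png::readPNG(paste0(stem, ".png")) * 255
  lab <- round(png::readPNG(paste0(stem, "_label.png")) * 255)
  if (length(dim(lab)) == 3L) lab <- lab[, , 1L]
  wound <- lab == 1L
  splint <- if (any(lab == 2L)) EBImage::fillHull(lab == 2L) > 0
            else matrix(FALSE, nrow(lab), ncol(lab))
  if (is.na(splint_present)) splint_present <- any(splint)
  h <- nrow(lab); w <- ncol(lab)
  bbox <- if (any(wound)) {
    fgi <- which(wound)
    rr <- ((fgi - 1L) %% h) + 1L; cc <- ((fgi - 1L) %/% h) + 1L
    c(cx = mean(cc - 0.5) / w, cy = mean(rr - 0.5) / h,
      w = (diff(range(cc)) + 1) / w, h = (diff(range(rr)) + 1) / h,
      confidence = 1)
  } else c(cx = 0.5, cy = 0.5, w = 0, h = 0, confidence = 0)
  new("PhantomScene", image = img, wound_mask = wound,
      splint_inner_mask = splint, bbox = bbox, day = as.integer(day),
      wound_id = wound_id, splint_present = splint_present,
      params = list(mm_per_pixel = mm_per_pixel,
                    true_area_mm2 = sum(wound) * mm_per_pixel^2))
}
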