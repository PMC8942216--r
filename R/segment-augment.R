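# On-the-fly training augmentation and the dice objective.

#' Augment one (image, masks) training sample
#'
#' Geometric transforms — vertical/horizontal flips (each with probability
#' `flip_prob`) and rotation by a uniform angle from `rotation_range` — are
#' applied identically to the image (bilinear) and masks (nearest neighbor),
#' with out-of-canvas samples filled by edge reflection. Photometric
#' transforms touch the image only: linear contrast `127 + alpha * (v - 127)`
#' with alpha from `contrast_alpha_range`, a brightness multiplier from
#' `intensity_range`, and Gaussian blur with probability `blur_prob` at a
#' sigma from `blur_sigma_range`. Pixel values are clipped to [0, 255].
#'
#' @param image H x W x 3 array (0-255).
#' @param masks list of logical H x W matrices sharing the image shape.
#' @param config an [AugmentationConfig-class].
#' @param seed optional integer seed.
#' @return List: `image`, `masks`.
#' @export
augmentSample <- function(image, masks, config = augmentationConfig(),
                          seed = NULL) {
  stopifnot(is(config, "AugmentationConfig"))
  d <- dim(image)
  for (m in masks)
    if (!identical(dim(m), d[1:2])) stop("image and masks must share shape")
  withSeed(seed, {
    vflip <- stats::runif(1L) < config@flip_prob
    hflip <- stats::runif(1L) < config@flip_prob
    ang <- stats::runif(1L, config@rotation_range[1L], config@rotation_range[2L])
    alpha <- stats::runif(1L, config@contrast_alpha_range[1L],
                          config@contrast_alpha_range[2L])
    gain <- stats::runif(1L, config@intensity_range[1L],
                         config@intensity_range[2L])
    do_blur <- stats::runif(1L) < config@blur_prob
    sigma <- stats::runif(1L, config@blur_sigma_range[1L],
                          config@blur_sigma_range[2L])

    geom <- function(m, interp) {
      if (vflip) m <- m[nrow(m):1, , drop = FALSE]
      if (hflip) m <- m[, ncol(m):1, drop = FALSE]
      if (ang != 0) m <- rotateAbout(m, ang, interp)
      m
    }
    image <- perChannel(image, function(m) geom(m, "bilinear"))
    masks <- lapply(masks, function(m) geom(m * 1, "nearest") > 0.5)
    if (alpha != 1) image <- 127 + alpha * (image - 127)
    if (gain != 1) image <- image * gain
    if (do_blur) image <- blurImage(image, sigma)
    if (alpha != 1 || gain != 1 || do_blur) image <- clip255(image)
    list(image = image, masks = masks)
  })
}

#' Smoothed dice loss
#'
#' `1 - (2 * sum(p * t) + s) / (sum(p) + sum(t) + s)` averaged over classes,
#' with smoothing constant `s = 1` by default. Symmetric in its arguments
#' and bounded in [0, 1].
#'
#' @param pred,target per-class scores in [0, 1]: a matrix, a list of
#'   matrices, or an H x W x C array.
#' @param smooth smoothing constant (default 1).
#' @return Scalar loss.
#' @export
#' @examples
#' t <- matrix(c(1, 0, 1, 0), 2, 2)
#' diceLoss(t, t) < 1e-3   # near-perfect
#' diceLoss(0 * t, t) > 0.9
diceLoss <- function(pred, target, smooth = 1) {
  as_list <- function(x) {
    if (is.list(x)) lapply(x, function(m) m * 1)
    else if (length(dim(x)) == 3L)
      lapply(seq_len(dim(x)[3L]), function(k) x[, , k] * 1)
    else list(x * 1)
  }
  p <- as_list(pred); t <- as_list(target)
  stopifnot(length(p) == length(t))
  per <- mapply(function(pi, ti) {
    if (!identical(dim(pi), dim(ti))) stop("shape mismatch")
    1 - (2 * sum(pi * ti) + smooth) / (sum(pi) + sum(ti) + smooth)
  }, p, t)
  mean(per)
}
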