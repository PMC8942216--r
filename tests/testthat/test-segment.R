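identityAug <- function() {
  augmentationConfig(flip_prob = 0, rotation_range = c(0, 0),
                     contrast_alpha_range = c(1, 1),
                     intensity_range = c(1, 1), blur_prob = 0)
}

test_that("the neutral augmentation config is the identity", {
  sc <- tinyScene(seed = 41, mpp = 0.2)
  masks <- list(wound = woundMask(sc), splint = splintInnerMask(sc))
  out <- augmentSample(sceneImage(sc), masks, identityAug(), seed = 1)
  expect_identical(out$image, sceneImage(sc))
  expect_identical(out$masks$wound, masks$wound)
})

test_that("contrast follows 127 + alpha*(v - 127) with clipping", {
  img <- array(255, c(4, 4, 3))
  cfg <- augmentationConfig(flip_prob = 0, rotation_range = c(0, 0),
                            contrast_alpha_range = c(1.5, 1.5),
                            intensity_range = c(1, 1), blur_prob = 0)
  out <- augmentSample(img, list(w = matrix(FALSE, 4, 4)), cfg, seed = 1)
  expect_true(all(out$image == 255))   # 127 + 1.5*128 = 319 -> clipped
  img2 <- array(100, c(4, 4, 3))
  out2 <- augmentSample(img2, list(w = matrix(FALSE, 4, 4)), cfg, seed = 1)
  expect_true(all(abs(out2$image - (127 + 1.5 * (100 - 127))) < 1e-9))
})

test_that("flips apply identically to image and masks and preserve counts", {
  sc <- tinyScene(seed = 42, mpp = 0.2)
  masks <- list(wound = woundMask(sc))
  cfg <- augmentationConfig(flip_prob = 1, rotation_range = c(0, 0),
                            contrast_alpha_range = c(1, 1),
                            intensity_range = c(1, 1), blur_prob = 0)
  out <- augmentSample(sceneImage(sc), masks, cfg, seed = 2)
  expect_identical(sum(out$masks$wound), sum(masks$wound))
  # flipping twice (v+h then v+h) restores the original
  back <- augmentSample(out$image, out$masks, cfg, seed = 3)
  expect_identical(back$image, sceneImage(sc))
  expect_identical(back$masks$wound, masks$wound)
})

test_that("rotation keeps mask pixel count within interpolation tolerance", {
  sc <- tinyScene(seed = 43, mpp = 0.2)
  masks <- list(wound = woundMask(sc))
  cfg <- augmentationConfig(flip_prob = 0, rotation_range = c(30, 30),
                            contrast_alpha_range = c(1, 1),
                            intensity_range = c(1, 1), blur_prob = 0)
  out <- augmentSample(sceneImage(sc), masks, cfg, seed = 4)
  n0 <- sum(masks$wound)
  expect_lt(abs(sum(out$masks$wound) - n0) / n0, 0.05)
})

test_that("augmentation rejects mismatched shapes", {
  expect_error(augmentSample(array(0, c(8, 8, 3)),
                             list(w = matrix(FALSE, 4, 4))), "shape")
})

test_that("dice loss matches its closed form, is symmetric and bounded", {
  t <- matrix(0, 10, 10); t[3:7, 3:7] <- 1
  expect_lt(diceLoss(t, t), 1 / 50)            # <= s / (2*area + s)
  expect_gt(diceLoss(0 * t, t), 0.9)
  half <- matrix(rep(c(1, 0), each = 50), 10, 10)
  # p = t = half-ones: 1 - (2*50 + 1)/(50 + 50 + 1) = 0 exactly
  expect_equal(diceLoss(half, half), 0)
  set.seed(1)
  p <- matrix(runif(100), 10, 10)
  expect_equal(diceLoss(p, t), diceLoss(t, p))
  expect_true(diceLoss(p, t) >= 0 && diceLoss(p, t) <= 1)
})

test_that("dice and IoU obey dice = 2*iou/(1 + iou)", {
  set.seed(5)
  for (i in 1:20) {
    a <- matrix(runif(64) > 0.5, 8, 8)
    b <- matrix(runif(64) > 0.5, 8, 8)
    s <- segmentationScores(a, b)
    expect_equal(unname(s["dice"]), unname(2 * s["iou"] / (1 + s["iou"])))
  }
})

test_that("reference segmentation is exact on uncorrupted phantoms", {
  sc <- tinyScene(seed = 44)
  maps <- referenceSegment(sceneImage(sc))
  expect_identical(maps@wound >= 20, woundMask(sc))
  expect_identical(maps@splint >= 40, splintInnerMask(sc))
})

test_that("occlusion removes wound pixels from the reference segmentation", {
  sc <- tinyScene(seed = 45, occlusion_fraction = 0.3)
  maps <- referenceSegment(sceneImage(sc))
  got <- maps@wound >= 20
  expect_lt(sum(got), sum(woundMask(sc)))
  expect_true(all(woundMask(sc)[got]))   # no false positives, only drop-outs
})

test_that("blank crops give empty reference maps", {
  maps <- referenceSegment(array(0, c(64, 64, 3)))
  expect_false(any(maps@wound > 0))
  expect_false(any(maps@splint > 0))
})

test_that("training rejects empty validation splits and leaking ids", {
  co <- generateCohort(n_mice = 1, n_days = 2, mm_per_pixel = 0.32, seed = 1)
  expect_error(trainSegmenter(cohortScenes(co), val_ids = character(0)),
               "validation")
  expect_error(trainSegmenter(cohortScenes(co), val_ids = c("M1-L", "M1-R")),
               "training")
})

test_that("a short training run learns easy phantoms and logs curves", {
  co <- generateCohort(n_mice = 3, n_days = 4, mm_per_pixel = 0.32,
                       scale_jitter = 0.05, seed = 7,
                       corruption_sampler = function()
                         corruptionSpec(lighting_gain = runif(1, 0.9, 1.1)))
  ids <- unique(cohortManifest(co)$wound_id)
  cfg <- trainConfig(epochs = 8, seed = 3, width = 6L)
  model <- trainSegmenter(cohortScenes(co), val_ids = ids[6],
                          config = cfg,
                          augmentation = augmentationConfig(
                            rotation_range = c(-20, 20), blur_prob = 0))
  lg <- trainingLog(model)
  expect_identical(nrow(lg), 8L)
  expect_lt(lg$train_loss[8], lg$train_loss[1])
  expect_gt(lg$val_iou[8], lg$val_iou[1])
  # 5-epoch moving average of the loss is non-increasing on easy phantoms
  ma <- stats::filter(lg$train_loss, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 0.02))
  # prediction contract: shape, range, determinism
  sm <- woundmetry:::sceneToSample(cohortScenes(co)[[1]], 64L)
  m1 <- predictMaps(model, sm$image)
  expect_identical(dim(m1@wound), c(64L, 64L))
  expect_true(all(m1@wound >= 0 & m1@wound <= 255))
  m2 <- predictMaps(model, sm$image)
  expect_identical(m1@wound, m2@wound)
  expect_error(predictMaps(model, array(0, c(32, 32, 3))), "64")
  # determinism of training under a fixed seed
  model2 <- trainSegmenter(cohortScenes(co), val_ids = ids[6], config = cfg,
                           augmentation = augmentationConfig(
                             rotation_range = c(-20, 20), blur_prob = 0))
  expect_identical(model@weights, model2@weights)
})

test_that("network gradients match finite differences", {
  set.seed(9)
  s <- 8L
  X <- array(runif(s * s * 3), c(s, s, 3))
  Tg <- array(rbinom(s * s * 2, 1, 0.3), c(s, s, 2))
  wt <- woundmetry:::initWeights(4L)
  bw <- woundmetry:::netBackward(
    woundmetry:::netForward(X, wt, keep_cache = TRUE), Tg, wt)
  eps <- 1e-6
  lossAt <- function(w) woundmetry:::netBackward(
    woundmetry:::netForward(X, w, keep_cache = TRUE), Tg, w)$loss
  for (nm in names(wt)) {
    for (i in sample(length(wt[[nm]]), min(2, length(wt[[nm]])))) {
      wp <- wt; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- wt; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
      expect_equal(bw$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip through save/load", {
  wt <- woundmetry:::initWeights(4L)
  model <- new("SegmenterModel", weights = wt, config = trainConfig(width = 4L),
               log = data.frame())
  path <- withr::local_tempfile(fileext = ".rds")
  saveSegmenter(model, path)
  back <- loadSegmenter(path)
  expect_identical(back@weights, wt)
})
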