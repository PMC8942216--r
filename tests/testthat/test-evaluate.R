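test_that("overlap scores cover the degenerate and textbook cases", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  expect_equal(unname(segmentationScores(a, a)), c(1, 1))
  b <- matrix(FALSE, 10, 10); b[7:9, 7:9] <- TRUE
  expect_equal(unname(segmentationScores(a, b)), c(0, 0))
  e <- matrix(FALSE, 10, 10)
  expect_equal(unname(segmentationScores(e, e)), c(1, 1))
  # |A| = |B| = 100, overlap 50 -> dice .5, iou 1/3
  x <- matrix(FALSE, 20, 20); x[1:10, 1:10] <- TRUE
  y <- matrix(FALSE, 20, 20); y[6:15, 1:10] <- TRUE
  s <- segmentationScores(x, y)
  expect_equal(unname(s["dice"]), 0.5)
  expect_equal(unname(s["iou"]), 1 / 3)
  expect_error(segmentationScores(a, matrix(FALSE, 5, 5)), "shape")
  # symmetry
  expect_identical(segmentationScores(x, y), segmentationScores(y, x))
})

test_that("the correlation suite reports all three coefficients", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(unname(correlationSuite(x, x)), c(1, 1, 1))
  rev_rank <- correlationSuite(1:5, 5:1)
  expect_equal(unname(rev_rank[c("spearman", "kendall")]), c(-1, -1))
  mono <- correlationSuite(c(1, 2, 3, 5), c(1, 2, 4, 8))
  expect_equal(unname(mono["spearman"]), 1)
  expect_lt(mono["pearson"], 1)
  expect_error(correlationSuite(rep(1, 4), 1:4), "constant")
})

test_that("rmse matches its closed form and a brute-force loop", {
  expect_identical(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  set.seed(20)
  for (i in 1:10) {
    n <- sample(2:10, 1)
    a <- runif(n); b <- runif(n)
    acc <- 0
    for (j in seq_len(n)) acc <- acc + (a[j] - b[j])^2
    expect_equal(rmse(a, b), sqrt(acc / n))
  }
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("removing nothing leaves the closure curves untouched", {
  co <- generateCohort(n_mice = 2, n_days = 16, seed = 30,
                       render_image = FALSE)
  ex <- splintRemovalExperiment(co, list(type = "fraction", value = 0),
                                technique = "nearest", seed = 1)
  expect_identical(ex$baseline$mean_closure, ex$perturbed$mean_closure)
  expect_identical(ex$max_abs_dev, 0)
})

test_that("an 8-day window removal hits exactly half of a 16-day cohort", {
  co <- generateCohort(n_mice = 2, n_days = 16, seed = 31,
                       render_image = FALSE)
  ex <- splintRemovalExperiment(co, list(type = "window", from = 0),
                                technique = "mean", seed = 1)
  expect_equal(ex$availability_after, 0.5)
})

test_that("the removal experiment is reproducible under one seed", {
  co <- generateCohort(n_mice = 2, n_days = 16, seed = 32,
                       render_image = FALSE)
  a <- splintRemovalExperiment(co, list(type = "fraction", value = 0.5),
                               technique = "nearest", seed = 7)
  b <- splintRemovalExperiment(co, list(type = "fraction", value = 0.5),
                               technique = "nearest", seed = 7)
  expect_identical(a$perturbed, b$perturbed)
})

test_that("deviation grows with the removed fraction in expectation", {
  devs <- sapply(1:8, function(seed) {
    co <- generateCohort(n_mice = 2, n_days = 16, seed = 100 + seed,
                         render_image = FALSE)
    sapply(c(0.2, 0.5), function(f)
      splintRemovalExperiment(co, list(type = "fraction", value = f),
                              technique = "nearest", seed = seed)$mean_abs_dev)
  })
  expect_gt(mean(devs[2, ]), mean(devs[1, ]))
})

test_that("closest-size search recovers the camera scale when healing is synchronized", {
  # The mechanism behind closest-size imputation: an imputed splint's error
  # factor is (donor scale / recipient scale)^2, and matching on wound pixel
  # count pins the donor's scale to the recipient's precisely when wound
  # physical sizes are synchronized across the cohort (same punch, same
  # protocol). In that regime, under strongly heterogeneous camera distance,
  # the per-record splint estimate beats the cohort mean in expectation.
  oneCurve <- function() healingParams(initial_diameter_mm = 6,
                                       closure_day = 14, expansion_peak = 1.1,
                                       expansion_day = 2, noise_sd = 0.02)
  res <- sapply(1:20, function(seed) {
    co <- generateCohort(n_mice = 4, n_days = 16, seed = 200 + seed,
                         scale_jitter = 0.3, healing_sampler = oneCurve,
                         render_image = FALSE)
    rec <- cohortRecords(co)
    truth <- rec$splint_px
    drop <- sample(seq_len(nrow(rec)), nrow(rec) / 2)
    r2 <- rec; r2$splint_px[drop] <- NA
    c(nearest = mean(abs(log(imputeSplintNearest(r2)$splint_px[drop] /
                               truth[drop]))),
      mean = mean(abs(log(imputeSplintMean(r2)$splint_px[drop] /
                            truth[drop]))))
  })
  expect_lt(mean(res["nearest", ]), mean(res["mean", ]))
})

test_that("both imputation techniques keep curve deviation acceptable at 50% removal", {
  devs <- sapply(1:5, function(seed) {
    co <- generateCohort(n_mice = 4, n_days = 16, seed = 400 + seed,
                         render_image = FALSE)
    sapply(c("nearest", "mean"), function(tech)
      splintRemovalExperiment(co, list(type = "fraction", value = 0.5),
                              tech, seed = seed)$mean_abs_dev)
  })
  expect_lt(mean(devs["nearest", ]), 10)
  expect_lt(mean(devs["mean", ]), 10)
})
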