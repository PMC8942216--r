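test_that("healing fraction has exact endpoints and the stated peak", {
  p <- healingParams(expansion_peak = 1.2, expansion_day = 2,
                     closure_day = 15, noise_sd = 0)
  expect_identical(healingFraction(0, p), 1)
  expect_equal(healingFraction(2, p), 1.2)
  expect_identical(healingFraction(20, p), 0)   # closure_day + 5
  expect_error(healingFraction(-1, p), "day")
  # non-increasing after the expansion peak
  d <- seq(2, 16, by = 0.25)
  expect_true(all(diff(healingFraction(d, p)) <= 1e-12))
})

test_that("rendered day-0 wound area matches the analytic disk", {
  sc <- renderPhantom(healing = healingParams(noise_sd = 0), day = 0,
                      mm_per_pixel = 0.05, seed = 3)
  expected_px <- pi * 3^2 / 0.05^2
  expect_lt(abs(sum(woundMask(sc)) - expected_px) / expected_px, 0.02)
  # realized record agrees with the pixel count exactly
  expect_equal(sc@params$true_area_mm2, sum(woundMask(sc)) * 0.05^2)
})

test_that("missing splint propagates to flag and empty mask", {
  sc <- tinyScene(missing_splint = TRUE)
  expect_false(sc@splint_present)
  expect_false(any(splintInnerMask(sc)))
})

test_that("wound mask sits strictly inside the splint-inner disk when clean", {
  for (seed in 1:5) {
    sc <- tinyScene(seed = seed)
    expect_true(all(splintInnerMask(sc)[woundMask(sc)]))
  }
})

test_that("an extra wound adds a disjoint, more peripheral component", {
  sc <- tinyScene(seed = 5, extra_wound = TRUE)
  lab <- labelComponents(woundMask(sc), 8)
  expect_identical(max(lab), 2L)
  st <- woundmetry:::componentStats(lab)
  ctr <- rev(dim(woundMask(sc))) / 2   # (x, y)
  d <- sqrt((st$cx - ctr[1])^2 + (st$cy - ctr[2])^2)
  # the off-center one is farther from the frame center
  expect_gt(max(d), min(d) + 5)
})

test_that("identical seed and spec give bit-identical scenes", {
  a <- tinyScene(seed = 99, occlusion_fraction = 0.2, blur_sigma = 1)
  b <- tinyScene(seed = 99, occlusion_fraction = 0.2, blur_sigma = 1)
  expect_identical(a@image, b@image)
  expect_identical(a@wound_mask, b@wound_mask)
  expect_identical(a@params$true_area_mm2, b@params$true_area_mm2)
})

test_that("a too-small canvas for the splint is a configuration error", {
  expect_error(renderPhantom(mm_per_pixel = 0.05, canvas = c(100, 100)),
               "canvas")
})

test_that("cohort generation yields complete L/R series and counts", {
  co <- generateCohort(n_mice = 4, n_days = 16, seed = 2, render_image = FALSE)
  m <- cohortManifest(co)
  expect_identical(nrow(m), 128L)                      # 8 series x 16 days
  expect_identical(length(unique(m$wound_id)), 8L)
  expect_true(all(table(m$wound_id) == 16))
  expect_true(all(grepl("-(L|R)$", m$wound_id)))
  for (w in unique(m$wound_id))
    expect_identical(sort(m$day[m$wound_id == w]), 0:15)
})

test_that("random missing-splint fraction removes exactly floor(f * n) scenes", {
  co <- generateCohort(n_mice = 4, n_days = 16, seed = 5, render_image = FALSE,
                       missing_splint_pattern = list(type = "fraction",
                                                     value = 0.25))
  expect_identical(sum(!cohortManifest(co)$splint_present), 32L)  # floor(.25*128)
})

test_that("window missing-splint pattern hits exactly days 0-7", {
  co <- generateCohort(n_mice = 2, n_days = 16, seed = 5, render_image = FALSE,
                       missing_splint_pattern = list(type = "window", from = 0))
  m <- cohortManifest(co)
  expect_true(all(!m$splint_present[m$day <= 7]))
  expect_true(all(m$splint_present[m$day > 7]))
})

test_that("cohort scale varies around the base mm-per-pixel by +/-20%", {
  co <- generateCohort(n_mice = 2, n_days = 8, seed = 3, mm_per_pixel = 0.15,
                       render_image = FALSE)
  s <- cohortManifest(co)$mm_per_pixel
  expect_true(all(s >= 0.15 * 0.8 & s <= 0.15 * 1.2))
  expect_gt(stats::sd(s), 0)
})

test_that("corrupted predictions round-trip under thresholding when clean", {
  sc <- tinyScene(seed = 21)
  cm <- woundmetry:::cleanMasks(woundMask(sc), splintInnerMask(sc))
  maps <- corruptPrediction(cm, false_component_count = 0L, noise_density = 0,
                            seed = 1)
  th <- thresholdMaps(maps)
  expect_identical(th$wound, woundMask(sc))
  expect_identical(th$splint, splintInnerMask(sc))
})

test_that("injected false components and salt behave as specified", {
  sc <- tinyScene(seed = 22)
  cm <- woundmetry:::cleanMasks(woundMask(sc), splintInnerMask(sc))
  maps <- corruptPrediction(cm, false_component_count = 2L, seed = 4)
  th <- thresholdMaps(maps)
  lab <- labelComponents(th$wound, 8)
  sizes <- tabulate(lab[lab > 0])
  expect_identical(sum(sizes > 50), 3L)   # true wound + 2 false components
  # salt noise stays strictly below the wound threshold of 20
  salted <- corruptPrediction(cm, 0L, noise_level = 20, noise_density = 0.01,
                              seed = 5)
  expect_identical(thresholdMaps(salted)$wound, woundMask(sc))
  expect_gt(sum(salted@wound > 0 & salted@wound < 20), 0)
})
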