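test_that("noiseless phantom has exact bookkeeping and the four design levels", {
  p <- generate_phantom(phantom_spec(noise_sigma = 0, void_fraction = 0,
                                     seed = 2))
  lv <- sort(unique(as.vector(p$image)))
  expect_identical(lv, c(0L, 40L, 100L, 200L))  # bg, CSF rim, grey, white
  lab <- p$truth$label_map
  expect_identical(p$truth$grey_area, sum(lab == 2L))
  expect_identical(p$truth$white_area, sum(lab == 3L))
  expect_identical(p$truth$mask_area, sum(lab >= 1L))
  expect_identical(sum(p$image == 100L), p$truth$grey_area)
  expect_identical(sum(p$image == 200L), p$truth$white_area)
  # without voids the mask is tissue plus the thin CSF rim only
  expect_gt(p$truth$shrinkage, 0.88)
})

test_that("phantoms are deterministic per seed and differ across seeds", {
  a <- generate_phantom(phantom_spec(seed = 10))
  b <- generate_phantom(phantom_spec(seed = 10))
  c <- generate_phantom(phantom_spec(seed = 11))
  expect_identical(a$image, b$image)
  expect_false(identical(a$image, c$image))
})

test_that("rasterized grey/white ratio tracks the requested target", {
  for (r in c(1.2, 1.5, 2.0)) {
    p <- generate_phantom(phantom_spec(noise_sigma = 0, void_fraction = 0,
                                       grey_white_ratio = r, seed = 3))
    expect_equal(p$truth$gwr, r, tolerance = 0.02)
  }
})

test_that("void fraction carves the requested tissue share", {
  p <- generate_phantom(phantom_spec(noise_sigma = 0, void_fraction = 0.25,
                                     seed = 6))
  # same spec without carving: identical deterministic geometry
  p0 <- generate_phantom(phantom_spec(noise_sigma = 0, void_fraction = 0,
                                      seed = 6))
  tissue0 <- p0$truth$grey_area + p0$truth$white_area
  carved <- tissue0 - p$truth$grey_area - p$truth$white_area
  expect_equal(carved / tissue0, 0.25, tolerance = 0.3)
  # shrinkage reflects the carving
  expect_lt(p$truth$shrinkage, 0.9)

  expect_error(generate_phantom(phantom_spec(void_fraction = 0.995)),
               "vanished|void")
})

test_that("dataset generation is balanced, labelled and stage-monotone", {
  ds <- generate_phantom_dataset(n_per_stage = 6, seed = 4, size = 96)
  expect_length(ds$images, 24L)
  expect_identical(as.vector(table(ds$labels)), rep(6L, 4))
  mean_shr <- tapply(ds$truths$shrinkage, ds$truths$stage, mean)
  expect_true(all(diff(mean_shr) < 0))   # atrophy grows with stage
  # per-phantom reproducibility from the stored spec
  p <- generate_phantom(ds$specs[[5]])
  expect_identical(p$image, ds$images[[5]])

  dsi <- generate_phantom_dataset(n_per_stage = 50, seed = 4, size = 64,
                                  imbalanced = TRUE)
  counts <- as.vector(table(dsi$labels))
  expect_true(all(diff(counts) < 0))     # mimics the skewed class sizes
  expect_gte(min(counts), 4L)
})

test_that("phantom histogram is multimodal enough for thresholding", {
  for (seed in 1:5) {
    p <- generate_phantom(phantom_spec(stage = sample(0:3, 1), seed = seed))
    g <- adaptive_thresholds(counts = compute_histogram(p$image))
    expect_lt(g$th1, g$th2)
  }
})
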