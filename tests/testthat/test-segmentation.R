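test_that("strict-inequality segmentation assigns tissues and moments", {
  img <- matrix(c(0L, 200L, 100L, 255L), 2, 2)  # [[0,100],[200,255]]
  seg <- segment_tissues(img, th1 = 50, th2 = 150)
  expect_identical(seg$grey_volume, 1L)
  expect_identical(seg$white_volume, 2L)
  expect_identical(sum(seg$grey_mask * seg$white_mask), 0L)  # disjoint
  expect_equal(seg$grey_mean, 100)
  expect_equal(seg$white_mean, mean(c(200, 255)))
  # population sd, not sample sd
  expect_equal(seg$white_std, sqrt(mean((c(200, 255) - 227.5)^2)))
  expect_equal(seg$gwr, 0.5)

  # pixels equal to a threshold belong to neither tissue
  seg2 <- segment_tissues(matrix(c(50L, 150L), 1, 2), th1 = 50, th2 = 150)
  expect_identical(seg2$grey_volume, 0L)
  expect_identical(seg2$white_volume, 0L)
  expect_true(seg2$white_empty && seg2$grey_empty)
})

test_that("gwr and shrinkage ratios behave at the edges", {
  img <- matrix(c(rep(100L, 200), rep(200L, 100), rep(0L, 100)), 20, 20)
  mask <- matrix(1L, 20, 20)
  seg <- segment_tissues(img, 50, 150, brain_mask = mask)
  expect_equal(seg$gwr, 2)
  expect_equal(seg$shrinkage, 300 / 400)

  # empty grey -> gwr 0; empty white -> gwr undefined
  segg <- segment_tissues(matrix(c(0L, 200L), 1, 2), 50, 150)
  expect_equal(segg$gwr, 0)
  segw <- segment_tissues(matrix(c(0L, 100L), 1, 2), 50, 150)
  expect_error(compute_gwr(segw), "empty")

  # tissue filling the whole mask saturates shrinkage at 1
  segf <- segment_tissues(matrix(100L + diag(2L) * 100L, 2, 2), 50, 150,
                          brain_mask = matrix(1L, 2, 2))
  expect_equal(compute_shrinkage(segf), 1)
  expect_error(compute_shrinkage(
    segment_tissues(matrix(c(0L, 100L), 1, 2), 50, 150,
                    brain_mask = matrix(0L, 1, 2))), "empty")
})

test_that("noiseless phantom volumes equal constructed areas exactly", {
  for (st in c(0, 2)) {
    p <- quick_phantom(stage = st, noise = 0, seed = 20 + st)
    g <- adaptive_thresholds(counts = compute_histogram(p$image))
    seg <- segment_tissues(p$image, g$th1, g$th2)
    expect_identical(seg$grey_volume, p$truth$grey_area)
    expect_identical(seg$white_volume, p$truth$white_area)
  }
})

test_that("feature extraction returns the fixed 17-vector deterministically", {
  p <- quick_phantom(stage = 1, noise = 5, seed = 9)
  r1 <- extract_features(p$image)
  r2 <- extract_features(p$image)
  expect_true(r1$ok)
  expect_length(r1$features, 17L)
  expect_identical(names(r1$features), feature_names())
  expect_identical(r1$features, r2$features)
  expect_true(all(is.finite(r1$features)))
})

test_that("degenerate slices produce failure records, not errors", {
  r <- extract_features(matrix(5L, 16, 16))         # constant
  expect_false(r$ok)
  expect_match(r$reason, "constant")

  bimodal <- matrix(c(rep(0L, 200), rep(200L, 56)), 16, 16)
  r2 <- extract_features(bimodal)                    # too few minima
  expect_false(r2$ok)

  tab <- extract_feature_table(list(quick_phantom(seed = 31)$image,
                                    matrix(5L, 16, 16)),
                               labels = c(0L, 0L))
  expect_identical(nrow(tab), 1L)
  expect_identical(nrow(attr(tab, "failures")), 1L)
})

test_that("gwr and shrinkage are invariant to uniform area scaling", {
  p64 <- generate_phantom(phantom_spec(size = 64, noise_sigma = 0,
                                       void_fraction = 0.1, seed = 5))
  p128 <- generate_phantom(phantom_spec(size = 128, noise_sigma = 0,
                                        void_fraction = 0.1, seed = 5))
  f64 <- extract_features(p64$image)
  f128 <- extract_features(p128$image)
  expect_true(f64$ok && f128$ok)
  # ratio features track the constructed truth tightly at either scale ...
  expect_equal(f64$features[["gwr"]], p64$truth$gwr, tolerance = 0.01)
  expect_equal(f128$features[["gwr"]], p128$truth$gwr, tolerance = 0.01)
  # ... and are scale-free up to the carving sampling granularity
  expect_equal(f64$features[["gwr"]], f128$features[["gwr"]],
               tolerance = 0.1)
  expect_equal(f64$features[["shrinkage"]], f128$features[["shrinkage"]],
               tolerance = 0.1)
})
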