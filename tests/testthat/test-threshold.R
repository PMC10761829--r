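test_that("interior extrema detection handles simple cases and plateaus", {
  ex <- find_local_extrema(c(3, 1, 2, 0, 4))
  expect_identical(ex$minima$bin, c(1L, 3L))
  expect_identical(ex$maxima$bin, 2L)

  # monotone sequence has no interior extrema
  ex <- find_local_extrema(1:10)
  expect_identical(nrow(ex$minima), 0L)
  expect_identical(nrow(ex$maxima), 0L)

  # plateau minimum collapses to its midpoint
  ex <- find_local_extrema(c(5, 2, 2, 2, 5))
  expect_identical(ex$minima$bin, 2L)
  expect_identical(ex$minima$value, 2)

  # offset shifts reported bins
  ex <- find_local_extrema(c(3, 1, 3), offset = 100L)
  expect_identical(ex$minima$bin, 101L)
})

test_that("extrema match the brute-force oracle and alternate along the axis", {
  set.seed(99)
  for (i in 1:300) {
    v <- random_envelope()
    ex <- find_local_extrema(v)
    orc <- oracle_extrema(v)
    expect_identical(ex$minima$bin, as.integer(orc$minima))
    expect_identical(ex$maxima$bin, as.integer(orc$maxima))
    bins <- c(ex$minima$bin, ex$maxima$bin)
    kind <- rep(c(0, 1), c(nrow(ex$minima), nrow(ex$maxima)))
    o <- order(bins)
    expect_true(all(diff(bins[o]) > 0))
    if (length(bins) > 1) expect_true(all(diff(kind[o]) != 0))  # alternation
  }
})

test_that("threshold selection takes the second and last minima", {
  v <- numeric(201)
  v[c(31, 81, 141, 191)] <- c(30, 50, 100, 40)  # four separated modes
  v <- smooth_histogram(v, design_lowpass())
  ex <- find_local_extrema(v)
  expect_gte(nrow(ex$minima), 3L)
  g <- extract_thresholds(ex)
  expect_identical(g$th1, ex$minima$bin[2])
  expect_identical(g$th2, ex$minima$bin[nrow(ex$minima)])
  expect_lt(g$th1, g$th2)
  expect_identical(g$x3, which.max(v) - 1L)  # absolute maximum of envelope

  # a single minimum cannot supply two thresholds
  one_min <- find_local_extrema(c(5, 1, 5))
  expect_error(extract_thresholds(one_min), class = "thresholding_failure")
  err <- tryCatch(extract_thresholds(one_min),
                  thresholding_failure = function(e) e)
  expect_s3_class(err$extrema, "extrema_set")   # carries what was found
})

test_that("first-maximum rule is available and differs on asymmetric envelopes", {
  v <- numeric(201)
  v[c(31, 81, 141, 191)] <- c(30, 50, 100, 40)
  v <- smooth_histogram(v, design_lowpass())
  ex <- find_local_extrema(v)
  g2 <- extract_thresholds(ex, th1_rule = "first_maximum")
  expect_identical(g2$th1, ex$maxima$bin[1])
  g1 <- extract_thresholds(ex)
  expect_false(g1$th1 == g2$th1)
})

test_that("geometry slopes and distances follow the plane formulas", {
  base <- structure(
    list(x1 = 0L, y1 = 0, x2 = 3L, y2 = 4, x3 = 0L, y3 = 0,
         th1 = 0L, th2 = 3L, alpha1 = NA_real_, alpha2 = NA_real_,
         d1 = NA_real_, d2 = NA_real_, d3 = NA_real_,
         degenerate_slope = FALSE, th1_rule = "second_minimum"),
    class = "threshold_geometry")
  g <- compute_geometry(base)
  expect_identical(g$d1, 0)          # coincident with the maximum
  expect_identical(g$d3, 5)          # 3-4-5 triangle
  expect_identical(g$d2, 5)
  expect_true(g$degenerate_slope)    # x3 == x1 -> degenerate slope
  expect_true(is.nan(g$alpha1))      # coincident points: undefined
  vert <- base; vert$y3 <- 7
  g_inf <- compute_geometry(vert)
  expect_identical(g_inf$alpha1, Inf) # vertical rise: signed infinity

  base$x1 <- 10L; base$y1 <- 2; base$x3 <- 20L; base$y3 <- 12
  g <- compute_geometry(base)
  expect_equal(g$alpha1, 1)
  expect_equal(g$d1, sqrt(200))
})

test_that("triangle inequality holds for random threshold triples", {
  set.seed(3)
  for (i in 1:200) {
    pts <- matrix(runif(6, 0, 100), 3, 2)
    g <- compute_geometry(structure(
      list(x1 = pts[1, 1], y1 = pts[1, 2], x2 = pts[2, 1], y2 = pts[2, 2],
           x3 = pts[3, 1], y3 = pts[3, 2], th1 = 0L, th2 = 1L,
           alpha1 = NA_real_, alpha2 = NA_real_, d1 = NA_real_,
           d2 = NA_real_, d3 = NA_real_, degenerate_slope = FALSE,
           th1_rule = "second_minimum"),
      class = "threshold_geometry"))
    expect_lte(g$d3, g$d1 + g$d2 + 1e-9)
  }
})

test_that("thresholds ignore zero-count bins beyond the occupied range", {
  p <- quick_phantom(stage = 1, noise = 0)
  h <- compute_histogram(p$image)
  g <- adaptive_thresholds(counts = h)
  # append the histogram into a longer zero tail: geometry unchanged
  h2 <- c(h, rep(0L, 256))
  g2 <- adaptive_thresholds(counts = h2)
  for (f in c("th1", "th2", "x3", "alpha1", "alpha2", "d1", "d2", "d3"))
    expect_equal(g2[[f]], g[[f]], info = f)
})

test_that("trimodal phantom histogram yields thresholds between the tissue modes", {
  p <- quick_phantom(stage = 0, noise = 0)
  g <- adaptive_thresholds(counts = compute_histogram(p$image))
  expect_gt(g$th1, 40)    # above the CSF mode
  expect_lt(g$th1, 100)   # below the grey mode
  expect_gt(g$th2, 100)   # between grey and white modes
  expect_lt(g$th2, 200)
})
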