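#' Locate interior local extrema of a smoothed histogram
#'
#' A bin is a local minimum when its value is strictly below both flanking
#' non-plateau values; plateaus (runs of equal values) collapse to their
#' midpoint bin. The symmetric rule gives maxima. Only interior extrema are
#' reported: the first and last runs of the sequence are never extrema, so a
#' monotone tail (e.g. the decay into the top intensity bin after contrast
#' stretching) cannot masquerade as a valley.
#'
#' @param values Numeric vector (smoothed histogram, length >= 3).
#' @param offset Bin index of `values[1]` (0-based; default 0). Used when
#'   the vector is a slice of a longer histogram.
#' @return Object of class `extrema_set`: list with data frames `minima`
#'   and `maxima` (columns `bin`, `value`, sorted by bin), plus the input
#'   `values` and `offset`.
#' @export
find_local_extrema <- function(values, offset = 0L) {
  stopifnot(length(values) >= 3L)
  r <- rle(as.numeric(values))
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid_bin <- as.integer(offset + floor((starts + ends) / 2) - 1L)
  k <- length(v)
  minima <- maxima <- integer(0)
  if (k >= 3L) {
    for (i in 2:(k - 1L)) {
      if (v[i] < v[i - 1L] && v[i] < v[i + 1L]) minima <- c(minima, i)
      else if (v[i] > v[i - 1L] && v[i] > v[i + 1L]) maxima <- c(maxima, i)
    }
  }
  structure(
    list(
      minima = data.frame(bin = mid_bin[minima], value = v[minima]),
      maxima = data.frame(bin = mid_bin[maxima], value = v[maxima]),
      values = as.numeric(values),
      offset = as.integer(offset)
    ),
    class = "extrema_set"
  )
}

#' @export
print.extrema_set <- function(x, ...) {
  cat(sprintf("Extrema set: %d minima, %d maxima (bins %d..%d)\n",
              nrow(x$minima), nrow(x$maxima),
              x$offset, x$offset + length(x$values) - 1L))
  invisible(x)
}

# Condition constructor: thresholding failed, carry the extrema found.
thresholding_failure <- function(message, extrema) {
  structure(
    class = c("thresholding_failure", "error", "condition"),
    list(message = message, call = sys.call(-1), extrema = extrema)
  )
}

#' Select the two tissue thresholds from the extrema of the envelope
#'
#' Default rule: `Th1` is the bin of the *second* local minimum and `Th2`
#' the bin of the *last* local minimum of the smoothed histogram (the first
#' minimum sits immediately after the background spike and is skipped).
#' `(x3, y3)` is the absolute maximum of the envelope (smallest bin on
#' ties). The alternative rule `th1_rule = "first_maximum"` takes `Th1`
#' from the first interior local maximum instead.
#'
#' @param extrema An `extrema_set` from [find_local_extrema()].
#' @param th1_rule `"second_minimum"` (default) or `"first_maximum"`.
#' @return Object of class `threshold_geometry` with `x1, y1, x2, y2, x3,
#'   y3, th1, th2` filled and slope/distance slots `NA` (see
#'   [compute_geometry()]).
#' @seealso [adaptive_thresholds()] for the full image-to-thresholds chain.
#' @export
extract_thresholds <- function(extrema,
                               th1_rule = c("second_minimum", "first_maximum")) {
  stopifnot(inherits(extrema, "extrema_set"))
  th1_rule <- match.arg(th1_rule)
  mins <- extrema$minima
  nmin <- nrow(mins)

  if (th1_rule == "second_minimum") {
    if (nmin < 2L)
      stop(thresholding_failure(
        sprintf("need at least two local minima, found %d", nmin), extrema))
    p1 <- mins[2L, ]
  } else {
    if (nrow(extrema$maxima) < 1L || nmin < 1L)
      stop(thresholding_failure(
        "first-maximum rule needs an interior maximum and a minimum", extrema))
    p1 <- extrema$maxima[1L, ]
  }
  p2 <- mins[nmin, ]
  if (p1$bin >= p2$bin)
    stop(thresholding_failure(
      sprintf("degenerate thresholds: Th1 bin %d not below Th2 bin %d",
              p1$bin, p2$bin), extrema))

  i3 <- which.max(extrema$values)              # smallest bin wins ties
  structure(
    list(
      x1 = p1$bin, y1 = p1$value,
      x2 = p2$bin, y2 = p2$value,
      x3 = extrema$offset + i3 - 1L, y3 = extrema$values[i3],
      th1 = p1$bin, th2 = p2$bin,
      alpha1 = NA_real_, alpha2 = NA_real_,
      d1 = NA_real_, d2 = NA_real_, d3 = NA_real_,
      degenerate_slope = FALSE, th1_rule = th1_rule
    ),
    class = "threshold_geometry"
  )
}

#' Slopes and distances between the threshold points
#'
#' Completes a `threshold_geometry` with the two slopes from the absolute
#' maximum `(x3, y3)` to the threshold points and the three pairwise
#' Euclidean distances in the (bin, height) plane:
#' `alpha1 = (y3 - y1)/(x3 - x1)`, `alpha2 = (y3 - y2)/(x3 - x2)`,
#' `d1 = |(x3,y3)-(x1,y1)|`, `d2 = |(x3,y3)-(x2,y2)|`,
#' `d3 = |(x2,y2)-(x1,y1)|`.
#' If `x3` coincides with `x1` or `x2` the slope is a signed-infinity
#' sentinel and `degenerate_slope` is flagged; distances are still computed.
#'
#' @param geom A `threshold_geometry` from [extract_thresholds()].
#' @return The completed `threshold_geometry`.
#' @export
compute_geometry <- function(geom) {
  stopifnot(inherits(geom, "threshold_geometry"))
  slope <- function(dy, dx) {
    if (dx == 0) {
      geom$degenerate_slope <<- TRUE
      if (dy == 0) NaN else sign(dy) * Inf
    } else dy / dx
  }
  geom$alpha1 <- slope(geom$y3 - geom$y1, geom$x3 - geom$x1)
  geom$alpha2 <- slope(geom$y3 - geom$y2, geom$x3 - geom$x2)
  geom$d1 <- sqrt((geom$x3 - geom$x1)^2 + (geom$y3 - geom$y1)^2)
  geom$d2 <- sqrt((geom$x3 - geom$x2)^2 + (geom$y3 - geom$y2)^2)
  geom$d3 <- sqrt((geom$x2 - geom$x1)^2 + (geom$y2 - geom$y1)^2)
  geom
}

#' @export
print.threshold_geometry <- function(x, ...) {
  cat(sprintf("Thresholds: Th1 = %d, Th2 = %d (rule: %s)\n",
              x$th1, x$th2, x$th1_rule))
  cat(sprintf("  maximum (x3, y3) = (%d, %.3g)\n", x$x3, x$y3))
  if (!is.na(x$d1))
    cat(sprintf("  alpha1 = %.4g, alpha2 = %.4g; d1 = %.4g, d2 = %.4g, d3 = %.4g\n",
                x$alpha1, x$alpha2, x$d1, x$d2, x$d3))
  invisible(x)
}

#' Adaptive multi-thresholding of an intensity image or histogram
#'
#' Runs the full chain: histogram, zero-phase lowpass smoothing, extremum
#' detection, threshold selection and the slope/distance geometry. Analysis
#' is restricted to the occupied intensity range (first to last nonzero
#' count of the raw histogram), so zero-count bins beyond the occupied
#' range never influence the result. Before extremum detection, smoothed
#' values below `floor_rel` times the envelope maximum are set to zero:
#' this suppresses the filter's stopband leakage (about `10^(-atten/20)` of
#' a dominant spike), which would otherwise seed spurious valleys around
#' isolated histogram spikes.
#'
#' @param image Integer intensity matrix (ignored when `counts` is given).
#' @param counts Optional raw histogram vector (length `2^bit_depth`).
#' @param filter A `lowpass_fir`; default [design_lowpass()].
#' @param th1_rule Passed to [extract_thresholds()].
#' @param floor_rel Relative leakage floor (default 0.005).
#' @param bit_depth Bits per pixel (default 8).
#' @return A completed `threshold_geometry`; attributes `smoothed` (the
#'   full-length smoothed histogram) and `extrema` carry the intermediates.
#'   Signals a `thresholding_failure` condition when no valid threshold
#'   pair exists.
#' @export
adaptive_thresholds <- function(image = NULL, counts = NULL,
                                filter = design_lowpass(),
                                th1_rule = c("second_minimum", "first_maximum"),
                                floor_rel = 0.005, bit_depth = 8L) {
  th1_rule <- match.arg(th1_rule)
  if (is.null(counts)) {
    stopifnot(is.matrix(image))
    counts <- compute_histogram(image, bit_depth = bit_depth)
  }
  sm <- smooth_histogram(counts, filter)
  occ <- which(counts > 0)
  if (length(occ) < 2L)
    stop(thresholding_failure("histogram occupies fewer than two bins",
                              find_local_extrema(sm)))
  lo <- min(occ); hi <- max(occ)
  s <- sm[lo:hi]
  s[s < floor_rel * max(s)] <- 0
  ex <- find_local_extrema(s, offset = lo - 1L)
  geom <- extract_thresholds(ex, th1_rule = th1_rule)
  geom <- compute_geometry(geom)
  attr(geom, "smoothed") <- sm
  attr(geom, "extrema") <- ex
  geom
}
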