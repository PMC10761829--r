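# Population moments of a tissue's intensities; skewness defined as 0 for
# zero-variance tissue (a constant patch is symmetric).
.tissue_stats <- function(vals) {
  n <- length(vals)
  if (n == 0L)
    return(list(volume = 0L, mean = NA_real_, std = NA_real_,
                skew = NA_real_))
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  m3 <- mean((vals - mu)^3)
  list(volume = n, mean = mu, std = sqrt(m2),
       skew = if (m2 == 0) 0 else m3 / m2^1.5)
}

#' Grey/white matter segmentation by the two thresholds
#'
#' Applies the strict-inequality rules: grey matter where
#' `Th1 < I < Th2`, white matter where `I > Th2`. Pixels equal to a
#' threshold belong to neither tissue. Per-tissue pixel counts ("volumes"
#' of the 2-D slice), means, population standard deviations and skewness
#' are computed, along with the grey-to-white ratio and — when a brain
#' mask is supplied — the shrinkage.
#'
#' @param image Integer intensity matrix.
#' @param th1,th2 Intensity thresholds, `0 <= th1 < th2 <= 2^k - 1`.
#' @param brain_mask Optional 0/1 matrix from [compute_brain_mask()];
#'   needed for shrinkage.
#' @return Object of class `tissue_segmentation`: masks `grey_mask`,
#'   `white_mask`, `brain_mask`; per-tissue `*_volume`, `*_mean`, `*_std`,
#'   `*_skew`; `gwr`; `shrinkage` (NA without a mask); logical flags
#'   `white_empty`, `grey_empty`.
#' @export
segment_tissues <- function(image, th1, th2, brain_mask = NULL) {
  stopifnot(is.matrix(image), th1 < th2)
  grey <- image > th1 & image < th2
  white <- image > th2
  gs <- .tissue_stats(image[grey])
  ws <- .tissue_stats(image[white])
  seg <- structure(
    list(
      grey_mask = matrix(as.integer(grey), nrow(image), ncol(image)),
      white_mask = matrix(as.integer(white), nrow(image), ncol(image)),
      brain_mask = brain_mask,
      th1 = th1, th2 = th2,
      grey_volume = gs$volume, white_volume = ws$volume,
      grey_mean = gs$mean, white_mean = ws$mean,
      grey_std = gs$std, white_std = ws$std,
      grey_skew = gs$skew, white_skew = ws$skew,
      gwr = NA_real_, shrinkage = NA_real_,
      grey_empty = gs$volume == 0L, white_empty = ws$volume == 0L
    ),
    class = "tissue_segmentation"
  )
  if (!seg$white_empty) seg$gwr <- compute_gwr(seg)
  if (!is.null(brain_mask)) seg$shrinkage <- compute_shrinkage(seg)
  seg
}

#' Grey-to-white matter ratio
#'
#' `GWR = grey_volume / white_volume`. An empty grey mask gives 0; an
#' empty white mask is an error (the extraction pipeline flags the image
#' instead of aborting a batch).
#'
#' @param seg A `tissue_segmentation`.
#' @return Numeric ratio.
#' @export
compute_gwr <- function(seg) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  if (seg$white_volume == 0L)
    stop("GWR undefined: white-matter mask is empty")
  seg$grey_volume / seg$white_volume
}

#' Tissue shrinkage relative to the brain mask
#'
#' `shrinkage = (grey_volume + white_volume) / sum(brain_mask)`: the
#' fraction of the brain area still occupied by segmented tissue. Lower
#' values mean more void space, i.e. more atrophy.
#'
#' @param seg A `tissue_segmentation` with a non-null `brain_mask`.
#' @return Numeric ratio in `[0, 1]` when the tissue masks lie inside the
#'   brain mask.
#' @export
compute_shrinkage <- function(seg) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  if (is.null(seg$brain_mask)) stop("shrinkage needs a brain mask")
  denom <- sum(seg$brain_mask)
  if (denom == 0L) stop("shrinkage undefined: empty brain mask")
  (seg$grey_volume + seg$white_volume) / denom
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  cat(sprintf("Tissue segmentation (Th1 = %s, Th2 = %s)\n", x$th1, x$th2))
  cat(sprintf("  grey : volume %d, mean %.2f, sd %.2f\n",
              x$grey_volume, x$grey_mean, x$grey_std))
  cat(sprintf("  white: volume %d, mean %.2f, sd %.2f\n",
              x$white_volume, x$white_mean, x$white_std))
  cat(sprintf("  GWR %.4g, shrinkage %.4g\n", x$gwr, x$shrinkage))
  invisible(x)
}
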