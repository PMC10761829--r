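#' Extract the 17-feature vector from one MRI slice
#'
#' Runs the full per-image pipeline: linear stretch, brain mask, histogram,
#' zero-phase smoothing, adaptive thresholds, slope/distance geometry and
#' grey/white segmentation. The fixed feature order is given by
#' [feature_names()]: `th1, th2, alpha1, alpha2, d1, d2, d3, grey_volume,
#' white_volume, grey_mean, white_mean, grey_std, white_std, grey_skew,
#' white_skew, gwr, shrinkage`.
#'
#' Failures (no valid threshold pair, empty tissue masks, non-finite
#' geometry) do not raise: the returned record carries `ok = FALSE` and a
#' reason, so batch extraction can skip and log degenerate slices.
#'
#' @param image Integer intensity matrix (raw 8-bit slice).
#' @param config Pipeline configuration from [default_config()].
#' @return List of class `ad_features`: `ok`, `features` (named numeric of
#'   length 17, or NULL), `reason` (NULL on success), plus `geometry` and
#'   `segmentation` intermediates on success.
#' @export
extract_features <- function(image, config = default_config()) {
  fail <- function(reason) {
    structure(list(ok = FALSE, features = NULL, reason = reason),
              class = "ad_features")
  }
  k <- config$bit_depth
  stretched <- withCallingHandlers(
    linear_stretch(image, bit_depth = k),
    warning = function(w) invokeRestart("muffleWarning"))
  if (max(stretched) == 0L) return(fail("constant image"))

  mask <- tryCatch(
    compute_brain_mask(stretched, threshold = config$mask$threshold,
                       brush_size = config$mask$brush_size),
    error = function(e) NULL)
  if (is.null(mask)) return(fail("empty brain mask"))

  filt <- design_lowpass(config$filter$passband_edge,
                         config$filter$stopband_atten,
                         config$filter$transition_width)
  geom <- tryCatch(
    adaptive_thresholds(stretched, filter = filt,
                        th1_rule = config$threshold$th1_rule,
                        floor_rel = config$threshold$floor_rel,
                        bit_depth = k),
    thresholding_failure = function(e) e)
  if (inherits(geom, "thresholding_failure"))
    return(fail(paste0("thresholding failure: ", conditionMessage(geom))))

  seg <- segment_tissues(stretched, geom$th1, geom$th2, brain_mask = mask)
  if (seg$white_empty) return(fail("empty white-matter mask"))
  if (seg$grey_empty) return(fail("empty grey-matter mask"))

  feats <- c(
    th1 = as.numeric(geom$th1), th2 = as.numeric(geom$th2),
    alpha1 = geom$alpha1, alpha2 = geom$alpha2,
    d1 = geom$d1, d2 = geom$d2, d3 = geom$d3,
    grey_volume = as.numeric(seg$grey_volume),
    white_volume = as.numeric(seg$white_volume),
    grey_mean = seg$grey_mean, white_mean = seg$white_mean,
    grey_std = seg$grey_std, white_std = seg$white_std,
    grey_skew = seg$grey_skew, white_skew = seg$white_skew,
    gwr = seg$gwr, shrinkage = seg$shrinkage
  )
  feats <- feats[.FEATURE_NAMES]
  if (!all(is.finite(feats))) return(fail("non-finite feature value"))
  structure(list(ok = TRUE, features = feats, reason = NULL,
                 geometry = geom, segmentation = seg),
            class = "ad_features")
}

#' @export
print.ad_features <- function(x, ...) {
  if (!x$ok) {
    cat("Feature extraction FAILED:", x$reason, "\n")
  } else {
    cat("17-feature vector:\n")
    print(round(x$features, 4))
  }
  invisible(x)
}

#' Extract a feature table from a set of images
#'
#' Applies [extract_features()] to each image; failed extractions are
#' excluded from the table and recorded in the `failures` attribute
#' (`source_id`, `reason`).
#'
#' @param images List of integer intensity matrices.
#' @param labels Optional class labels (0 = non, 1 = very mild, 2 = mild,
#'   3 = moderate dementia), recycled checks apply.
#' @param ids Optional source identifiers (default `img_1, ...`).
#' @param config Pipeline configuration.
#' @return Data frame with columns `source_id`, `label`, then the 17
#'   features in fixed order; attribute `failures` is a data frame of the
#'   skipped images.
#' @export
extract_feature_table <- function(images, labels = NULL, ids = NULL,
                                  config = default_config()) {
  n <- length(images)
  if (is.null(ids)) ids <- paste0("img_", seq_len(n))
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  stopifnot(length(ids) == n, length(labels) == n)

  rows <- vector("list", n)
  fail_id <- character(0); fail_reason <- character(0)
  for (i in seq_len(n)) {
    r <- extract_features(images[[i]], config)
    if (r$ok) {
      rows[[i]] <- data.frame(source_id = ids[i], label = labels[i],
                              t(r$features))
    } else {
      fail_id <- c(fail_id, ids[i])
      fail_reason <- c(fail_reason, r$reason)
    }
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab))
    tab <- data.frame(source_id = character(0), label = integer(0))
  rownames(tab) <- NULL
  attr(tab, "failures") <- data.frame(source_id = fail_id,
                                      reason = fail_reason)
  tab
}
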