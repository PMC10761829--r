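# Stage schedules: atrophy grows (void fraction) and the brain outline
# shrinks slightly with advancing dementia stage 0..3.
.STAGE_VOID <- c(0.02, 0.08, 0.18, 0.30)
.STAGE_SCALE <- c(1.00, 0.96, 0.92, 0.87)

#' Specification of a synthetic brain phantom
#'
#' Concentric 2-D construction emulating a T1-like axial slice: pure black
#' background, a thin CSF-like rim, a grey-matter annulus and a
#' white-matter core, with stage-dependent atrophy carved as background
#' voids (a central ventricle, scattered blobs, and sulcal notches opening
#' to the background). Intensity levels 0/40/100/200 give well-separated
#' histogram modes; the rim supplies the early first histogram valley that
#' the second-minimum threshold rule skips, just as the background spike
#' does in real slices.
#'
#' @param stage Dementia stage 0-3; sets the default `void_fraction` and
#'   outline `scale` (0.02/0.08/0.18/0.30 and 1.00/0.96/0.92/0.87).
#' @param size Image side in pixels (default 128).
#' @param background_level,csf_level,grey_level,white_level Intensities
#'   (defaults 0, 40, 100, 200; must be strictly increasing).
#' @param noise_sigma Gaussian noise sd added inside the brain (default 5).
#' @param void_fraction Fraction of tissue carved into voids; default from
#'   `stage`.
#' @param grey_white_ratio Target grey:white area ratio before carving
#'   (default 1.5).
#' @param scale Outline scale factor; default from `stage`.
#' @param seed RNG seed for this phantom.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(stage = 0L, size = 128L, background_level = 0L,
                         csf_level = 40L, grey_level = 100L,
                         white_level = 200L, noise_sigma = 5,
                         void_fraction = NULL, grey_white_ratio = 1.5,
                         scale = NULL, seed = 1L) {
  stopifnot(stage %in% 0:3, size >= 32L,
            background_level < csf_level, csf_level < grey_level,
            grey_level < white_level, white_level <= 255L,
            noise_sigma >= 0, grey_white_ratio > 0)
  if (is.null(void_fraction)) void_fraction <- .STAGE_VOID[stage + 1L]
  if (is.null(scale)) scale <- .STAGE_SCALE[stage + 1L]
  stopifnot(void_fraction >= 0, void_fraction < 1, scale > 0)
  structure(
    list(stage = as.integer(stage), size = as.integer(size),
         background_level = background_level, csf_level = csf_level,
         grey_level = grey_level, white_level = white_level,
         noise_sigma = noise_sigma, void_fraction = void_fraction,
         grey_white_ratio = grey_white_ratio, scale = scale,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Elliptical mask on an n x n grid; (cy, cx) centre, (b, a) semi-axes
# (rows, cols).
.ellipse_mask <- function(n, cy, cx, b, a) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((rows - cy) / b)^2 + ((cols - cx) / a)^2 <= 1
}

#' Generate one synthetic brain phantom with ground truth
#'
#' Deterministic per seed. Labels: 0 background, 1 CSF rim, 2 grey matter,
#' 3 white matter, 4 interior void (carved tissue, imaged at background
#' level). Sulcal notches carve tissue open to the background and are
#' labelled background, so the true brain mask (labels 1-4) has the same
#' topology a hole-filling mask extractor sees.
#'
#' @param spec A `phantom_spec`.
#' @return List of class `brain_phantom`: `image` (integer matrix),
#'   `truth` (list: `grey_area`, `white_area`, `mask_area`, `gwr`,
#'   `shrinkage`, `label_map`), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    n <- spec$size
    c0 <- (n + 1) / 2
    a <- 0.44 * n * spec$scale     # column semi-axis
    b <- 0.36 * n * spec$scale     # row semi-axis
    t_csf <- max(1, round(n / 64))   # rim scales with image size
    brain <- .ellipse_mask(n, c0, c0, b, a)
    grey_outer <- .ellipse_mask(n, c0, c0, b - t_csf, a - t_csf)
    shr <- 1 / sqrt(1 + spec$grey_white_ratio)
    white <- .ellipse_mask(n, c0, c0, (b - t_csf) * shr, (a - t_csf) * shr)

    lab <- matrix(0L, n, n)
    lab[brain] <- 1L
    lab[grey_outer] <- 2L
    lab[white] <- 3L

    tissue0 <- sum(lab >= 2L)
    target <- round(spec$void_fraction * tissue0)
    carved <- 0L

    if (target > 0L) {
      # central ventricle (interior void), ~40% of the target
      va <- sqrt(0.4 * target * 1.6 / pi)
      if (va >= 1) {
        vent <- .ellipse_mask(n, c0, c0, va / 1.6, va) & lab >= 2L
        lab[vent] <- 4L
        carved <- carved + sum(vent)
      }
      # a few sulcal notches on the outline (capped so the CSF rim survives)
      notch_target <- round(0.25 * target)
      tries <- 0L
      while (carved < 0.4 * target + notch_target && tries < 8L) {
        tries <- tries + 1L
        th <- runif(1, 0, 2 * pi)
        r <- runif(1, 2, 3.5)
        ny <- c0 + (b - 1) * sin(th)
        nx <- c0 + (a - 1) * cos(th)
        disc <- .ellipse_mask(n, ny, nx, r, r) & lab >= 1L
        hit <- disc & lab >= 2L    # only tissue counts toward the target
        lab[disc] <- 0L            # open to background
        carved <- carved + sum(hit)
      }
      # scattered interior blobs for the remainder
      tries <- 0L
      while (carved < target && tries < 2000L) {
        tries <- tries + 1L
        r <- runif(1, 2, 4)
        inner <- .ellipse_mask(n, c0, c0, b - t_csf - r - 1, a - t_csf - r - 1)
        cand <- which(inner & lab >= 2L)
        if (!length(cand)) break
        ctr <- arrayInd(sample(cand, 1L), dim(lab))
        disc <- .ellipse_mask(n, ctr[1], ctr[2], r, r) & lab >= 2L
        hit <- disc & lab != 4L
        lab[disc] <- 4L
        carved <- carved + sum(hit)
      }
    }

    if (sum(lab == 2L) == 0L || sum(lab == 3L) == 0L)
      stop("void_fraction too high: a tissue class vanished")
    if (target > 0L && carved < 0.95 * target)
      stop("void_fraction too high: requested void area cannot be carved")

    levels <- c(spec$background_level, spec$csf_level, spec$grey_level,
                spec$white_level, spec$background_level)
    img <- matrix(levels[lab + 1L], n, n)
    if (spec$noise_sigma > 0) {
      inside <- lab >= 1L
      img[inside] <- img[inside] + rnorm(sum(inside), 0, spec$noise_sigma)
    }
    img <- matrix(as.integer(pmin(pmax(floor(img + 0.5), 0), 255)), n, n)

    grey_area <- sum(lab == 2L)
    white_area <- sum(lab == 3L)
    mask_area <- sum(lab >= 1L)
    structure(
      list(image = img,
           truth = list(grey_area = grey_area, white_area = white_area,
                        mask_area = mask_area,
                        gwr = grey_area / white_area,
                        shrinkage = (grey_area + white_area) / mask_area,
                        label_map = lab),
           spec = spec),
      class = "brain_phantom"
    )
  })
}

#' @export
print.brain_phantom <- function(x, ...) {
  cat(sprintf(
    "Brain phantom: %dx%d, stage %d, void %.2f, noise sd %.1f (seed %d)\n",
    x$spec$size, x$spec$size, x$spec$stage, x$spec$void_fraction,
    x$spec$noise_sigma, x$spec$seed))
  cat(sprintf("  truth: grey %d, white %d, mask %d, GWR %.3f, shrinkage %.3f\n",
              x$truth$grey_area, x$truth$white_area, x$truth$mask_area,
              x$truth$gwr, x$truth$shrinkage))
  invisible(x)
}

#' Generate a labelled phantom dataset across the four stages
#'
#' Stage `s` phantoms use an increasing void fraction and a decreasing
#' outline scale; per-phantom parameters are jittered (void fraction
#' +/- 0.01, scale +/- 0.015, grey:white ratio +/- 0.1, uniform) and each
#' phantom draws its own derived seed, so any phantom is reproducible in
#' isolation from its spec.
#'
#' @param n_per_stage Phantoms per stage (balanced mode).
#' @param seed Master seed.
#' @param noise_sigma Noise sd (default 5).
#' @param size Image side (default 128).
#' @param imbalanced If TRUE, class sizes follow the heavily imbalanced
#'   proportions typical of public dementia-staging collections
#'   (1 : 0.7 : 0.28 : 0.02 of `n_per_stage`, minimum 4).
#' @return List of class `phantom_dataset`: `images` (list), `labels`
#'   (integer 0-3), `truths` (data frame), `specs` (list).
#' @export
generate_phantom_dataset <- function(n_per_stage = 50L, seed = 1L,
                                     noise_sigma = 5, size = 128L,
                                     imbalanced = FALSE) {
  stopifnot(n_per_stage >= 1L)
  counts <- if (imbalanced)
    pmax(4L, round(n_per_stage * c(1, 0.7, 0.28, 0.02)))
  else rep(as.integer(n_per_stage), 4L)

  plan <- .with_seed(seed, {
    out <- list()
    for (s in 0:3) {
      for (i in seq_len(counts[s + 1L])) {
        out[[length(out) + 1L]] <- phantom_spec(
          stage = s, size = size, noise_sigma = noise_sigma,
          void_fraction = max(0.005, .STAGE_VOID[s + 1L] + runif(1, -0.01, 0.01)),
          scale = .STAGE_SCALE[s + 1L] + runif(1, -0.015, 0.015),
          grey_white_ratio = 1.5 + runif(1, -0.1, 0.1),
          seed = sample.int(.Machine$integer.max - 1L, 1L))
      }
    }
    out
  })

  phantoms <- lapply(plan, generate_phantom)
  truths <- do.call(rbind, lapply(phantoms, function(p)
    data.frame(stage = p$spec$stage, grey_area = p$truth$grey_area,
               white_area = p$truth$white_area, mask_area = p$truth$mask_area,
               gwr = p$truth$gwr, shrinkage = p$truth$shrinkage)))
  structure(
    list(images = lapply(phantoms, `[[`, "image"),
         labels = vapply(phantoms, function(p) p$spec$stage, 0L),
         truths = truths,
         specs = plan),
    class = "phantom_dataset"
  )
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("Phantom dataset: %d images (%s per stage 0-3)\n",
              length(x$images),
              paste(tabulate(x$labels + 1L, 4L), collapse = "/")))
  invisible(x)
}
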