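# Equal-frequency discretization into at most `bins` levels.
.discretize_ef <- function(x, bins) {
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE, type = 7))
  if (length(qs) < 2L) return(rep.int(1L, length(x)))  # constant feature
  cut(x, breaks = qs, include.lowest = TRUE, labels = FALSE)
}

# Mutual information (base-2) between two discrete vectors.
.mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  e <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

# Validate ranking inputs; returns x as a numeric matrix and y as factor.
.check_ranking_input <- function(x, y) {
  x <- as.matrix(as.data.frame(x))
  stopifnot(is.numeric(x), ncol(x) >= 2L)
  if (anyNA(x)) stop("feature table contains missing values")
  y <- factor(y)
  if (nlevels(y) < 2L) stop("ranking needs at least two classes")
  list(x = x, y = y)
}

#' MRMR (minimum redundancy, maximum relevance) feature ranking
#'
#' Greedy MRMR with the MID (difference) criterion: features are
#' discretized into equal-frequency bins; the first selection maximizes
#' mutual information with the class label (base-2 logs); each subsequent
#' selection maximizes `MI(feature; label) - mean MI(feature; selected)`.
#' Deterministic: ties are broken by column order. The reported score is
#' the greedy objective at selection time, so a sharp drop marks where
#' informative features run out.
#'
#' @param x Data frame or matrix of numeric features.
#' @param y Class labels (coercible to factor, >= 2 levels).
#' @param bins Equal-frequency bins for discretization (default 16).
#' @return Object of class `feature_ranking`: data frame `ranking`
#'   (`feature`, `score` in selection order) and `method = "mrmr"`.
#' @export
mrmr_rank <- function(x, y, bins = 16L) {
  inp <- .check_ranking_input(x, y)
  x <- inp$x; y <- inp$y
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("f", seq_len(p))
  disc <- lapply(seq_len(p), function(j) .discretize_ef(x[, j], bins))
  rel <- vapply(disc, function(d) .mutual_information(d, y), 0)

  selected <- integer(0)
  scores <- numeric(0)
  red_cache <- matrix(NA_real_, p, p)   # pairwise MI, filled lazily
  remaining <- seq_len(p)
  while (length(remaining) > 0L) {
    if (length(selected) == 0L) {
      obj <- rel[remaining]
    } else {
      obj <- vapply(remaining, function(j) {
        reds <- vapply(selected, function(s) {
          if (is.na(red_cache[j, s])) {
            mi <- .mutual_information(disc[[j]], disc[[s]])
            red_cache[j, s] <<- mi; red_cache[s, j] <<- mi
          }
          red_cache[j, s]
        }, 0)
        rel[j] - mean(reds)
      }, 0)
    }
    best <- remaining[which.max(obj)]   # which.max: first max -> col order
    selected <- c(selected, best)
    scores <- c(scores, max(obj))
    remaining <- setdiff(remaining, best)
  }
  structure(
    list(ranking = data.frame(feature = feats[selected], score = scores),
         method = "mrmr", bins = bins),
    class = "feature_ranking"
  )
}

#' Chi-square univariate feature ranking
#'
#' Each feature is discretized into equal-width bins over its observed
#' range; the chi-square statistic of the bin-by-class contingency table
#' (empty bins dropped) measures association with the label. Features are
#' ranked by descending statistic.
#'
#' @param x Data frame or matrix of numeric features.
#' @param y Class labels (>= 2 levels).
#' @param bins Equal-width bins (default 10).
#' @return Object of class `feature_ranking` with `method = "chi2"`.
#' @export
chi2_rank <- function(x, y, bins = 10L) {
  inp <- .check_ranking_input(x, y)
  x <- inp$x; y <- inp$y
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("f", seq_len(p))
  stat <- vapply(seq_len(p), function(j) {
    v <- x[, j]
    rng <- range(v)
    d <- if (rng[1] == rng[2]) rep.int(1L, length(v))
         else cut(v, breaks = seq(rng[1], rng[2], length.out = bins + 1),
                  include.lowest = TRUE, labels = FALSE)
    tab <- table(d, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) return(0)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }, 0)
  ord <- order(stat, decreasing = TRUE)
  structure(
    list(ranking = data.frame(feature = feats[ord], score = stat[ord]),
         method = "chi2", bins = bins),
    class = "feature_ranking"
  )
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("Feature ranking (%s, %d bins):\n", x$method, x$bins))
  df <- x$ranking
  df$score <- signif(df$score, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
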