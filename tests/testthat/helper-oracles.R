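# Independent brute-force oracles used to cross-check the implementation.

# Interior local extrema by direct per-position scanning (plateaus walk
# to their ends; midpoint bin reported). Independent of the rle-based
# implementation in the package.
oracle_extrema <- function(v, offset = 0L) {
  n <- length(v)
  mins <- maxs <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (i > 1L && j < n) {
      if (v[i - 1L] > v[i] && v[j + 1L] > v[i])
        mins <- c(mins, floor((i + j) / 2))
      if (v[i - 1L] < v[i] && v[j + 1L] < v[i])
        maxs <- c(maxs, floor((i + j) / 2))
    }
    i <- j + 1L
  }
  list(minima = mins - 1L + offset, maxima = maxs - 1L + offset)
}

# Seven metrics from a confusion matrix via explicit per-class loops.
oracle_metrics <- function(cm) {
  C <- nrow(cm); total <- sum(cm)
  acc <- sum(diag(cm)) / total
  rec <- spec <- prec <- f1 <- numeric(0)
  for (i in seq_len(C)) {
    if (sum(cm[i, ]) + sum(cm[, i]) == 0) next
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    s <- if (tn + fp > 0) tn / (tn + fp) else 0
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    rec <- c(rec, r); spec <- c(spec, s); prec <- c(prec, p); f1 <- c(f1, f)
  }
  pe <- 0
  for (i in seq_len(C)) pe <- pe + sum(cm[i, ]) * sum(cm[, i])
  pe <- pe / total^2
  kappa <- if (pe == 1) 0 else (acc - pe) / (1 - pe)
  # R_K numerator by the triple-sum definition, denominator by sums
  num <- 0
  for (k in seq_len(C)) for (l in seq_len(C)) for (m in seq_len(C))
    num <- num + cm[k, k] * cm[l, m] - cm[k, l] * cm[m, k]
  s2 <- total^2
  den <- sqrt(s2 - sum(colSums(cm)^2)) * sqrt(s2 - sum(rowSums(cm)^2))
  mcc <- if (den == 0) 0 else num / den
  list(accuracy = acc, recall = mean(rec), specificity = mean(spec),
       precision = mean(prec), f1 = mean(f1), mcc = mcc, kappa = kappa)
}

# Random confusion matrix (possibly with empty classes).
random_cm <- function(C = sample(2:6, 1)) {
  m <- matrix(rpois(C * C, lambda = sample(c(1, 5, 20), 1)), C, C)
  if (runif(1) < 0.2) { i <- sample(C, 1); m[i, ] <- 0; m[, i] <- 0 }
  if (sum(m) == 0) m[1, 1] <- 1
  m
}

# Random histogram-like vector with plateaus and spikes, for extrema tests.
random_envelope <- function(len = sample(16:256, 1)) {
  base <- switch(sample(3, 1),
    round(cumsum(rnorm(len)), sample(0:1, 1)),
    round(abs(rnorm(len, 10, 5)), 0),
    rep(round(abs(rnorm(ceiling(len / 4), 5, 3))), length.out = len))
  as.numeric(base)
}

# Small noiseless test phantom shared across files.
quick_phantom <- function(stage = 0, noise = 0, vf = NULL, seed = 7)
  generate_phantom(phantom_spec(stage = stage, noise_sigma = noise,
                                void_fraction = vf, seed = seed))
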