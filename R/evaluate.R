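# Train `model` on (xtr, ytr) and predict classes for xte. Features are
# assumed already standardized by the caller.
.fit_predict <- function(model, xtr, ytr, xte) {
  xtr <- as.data.frame(xtr); xte <- as.data.frame(xte)
  switch(model,
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "polynomial", degree = 2,
                        coef0 = 1, cost = 1, scale = FALSE)
      predict(fit, xte)
    },
    nn = {
      fit <- nnet::nnet(ytr ~ ., data = cbind(ytr = ytr, xtr), size = 10,
                        maxit = 1000, decay = 1e-4, trace = FALSE,
                        MaxNWts = 5000)
      factor(predict(fit, xte, type = "class"), levels = levels(ytr))
    },
    tree = {
      fit <- rpart::rpart(ytr ~ ., data = cbind(ytr = ytr, xtr),
                          method = "class")
      predict(fit, xte, type = "class")
    },
    lda = {
      fit <- MASS::lda(xtr, ytr)
      predict(fit, xte)$class
    },
    qda = {
      fit <- MASS::qda(xtr, ytr)
      predict(fit, xte)$class
    },
    nb = {
      fit <- e1071::naiveBayes(xtr, ytr)
      predict(fit, xte)
    },
    knn = class::knn(xtr, xte, ytr, k = 1),
    ensemble = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = 200)
      predict(fit, xte)
    },
    stop("unknown classifier: ", model)
  )
}

# Stratified index split into train/validation/test fractions.
.stratified_split <- function(y, fractions = c(0.6, 0.2, 0.2)) {
  idx <- list(train = integer(0), validation = integer(0), test = integer(0))
  for (lv in levels(y)) {
    pool <- sample(which(y == lv))
    n <- length(pool)
    ntr <- round(fractions[1] * n)
    nva <- round(fractions[2] * n)
    idx$train <- c(idx$train, pool[seq_len(ntr)])
    idx$validation <- c(idx$validation, pool[ntr + seq_len(nva)])
    idx$test <- c(idx$test, pool[setdiff(seq_len(n), seq_len(ntr + nva))])
  }
  idx
}

#' Train and evaluate a classifier on a feature table
#'
#' Repeated stratified hold-out evaluation: each repetition draws a
#' stratified 60/20/20 train/validation/test split (the validation
#' partition is reserved for model selection; the provided classifiers use
#' fixed hyperparameters, so it is held out untouched), trains on the
#' training partition, and scores the seven metrics on the test partition.
#' Ten repetitions with seeds derived from the master seed are averaged.
#' A stratified k-fold cross-validation mode is available via
#' `mode = "cv"`.
#'
#' Features are standardized using training-partition statistics.
#' Classifier labels follow the common kernel names of this literature:
#' `"svm"` (quadratic polynomial kernel), `"nn"` (one hidden layer of 10
#' units, up to 1000 iterations), `"tree"`, `"lda"`, `"qda"`, `"nb"`,
#' `"knn"` (k = 1), `"ensemble"` (random forest).
#'
#' @param x Data frame or matrix of numeric features.
#' @param y Class labels (>= 2 levels, >= 10 samples per class advised;
#'   fewer than 3 per class is an error).
#' @param classifier One of `"svm", "nn", "tree", "lda", "qda", "nb",
#'   "knn", "ensemble"`.
#' @param seed Master seed; all split randomness derives from it.
#' @param n_repeats Repetitions (default 10).
#' @param mode `"holdout"` (default, 60/20/20) or `"cv"` (stratified
#'   `n_repeats`-fold cross-validation).
#' @param feature_set Optional character vector of feature columns to use.
#' @return Object of class `evaluation_result`: `metrics` (per-repetition
#'   data frame), `mean`, `sd`, pooled `confusion` matrix, and the setup.
#' @export
split_and_evaluate <- function(x, y, classifier = "svm", seed = 1L,
                               n_repeats = 10L,
                               mode = c("holdout", "cv"),
                               feature_set = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(as.data.frame(x))
  y <- droplevels(factor(y))
  stopifnot(nrow(x) == length(y))
  if (nlevels(y) < 2L) stop("need at least two classes")
  if (min(table(y)) < 3L) stop("stratification error: a class has < 3 samples")
  if (!is.null(feature_set)) {
    missing <- setdiff(feature_set, colnames(x))
    if (length(missing)) stop("unknown features: ", paste(missing, collapse = ", "))
    x <- x[, feature_set, drop = FALSE]
  }

  metric_names <- c("accuracy", "recall", "specificity", "precision",
                    "f1", "mcc", "kappa")
  eval_fold <- function(tr, te) {
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- scale(x[tr, , drop = FALSE], mu, sg)
    xte <- scale(x[te, , drop = FALSE], mu, sg)
    pred <- .fit_predict(classifier, xtr, y[tr], xte)
    confusion_matrix(y[te], pred, levels = levels(y))
  }

  res <- .with_seed(seed, {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
    cms <- vector("list", n_repeats)
    if (mode == "holdout") {
      for (r in seq_len(n_repeats)) {
        set.seed(rep_seeds[r])
        sp <- .stratified_split(y)
        cms[[r]] <- eval_fold(sp$train, sp$test)
      }
    } else {
      set.seed(rep_seeds[1])
      folds <- unsplit(lapply(split(seq_along(y), y), function(i)
        sample(rep_len(seq_len(n_repeats), length(i)))), y)
      for (r in seq_len(n_repeats)) {
        te <- which(folds == r)
        cms[[r]] <- eval_fold(setdiff(seq_along(y), te), te)
      }
    }
    cms
  })

  per_rep <- t(vapply(res, function(cm) {
    m <- suppressWarnings(compute_metrics(cm))
    unlist(m[metric_names])
  }, setNames(numeric(7), metric_names)))
  pooled <- Reduce(`+`, res)
  structure(
    list(metrics = as.data.frame(per_rep),
         mean = colMeans(per_rep),
         sd = apply(per_rep, 2, sd),
         confusion = pooled,
         pooled_metrics = suppressWarnings(compute_metrics(pooled)),
         classifier = classifier, mode = mode, seed = seed,
         n_repeats = n_repeats),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("Evaluation: %s, %d x %s (seed %d)\n", x$classifier,
              x$n_repeats, x$mode, x$seed))
  cat("Mean (sd) over repetitions:\n")
  for (m in names(x$mean))
    cat(sprintf("  %-12s %.4f (%.4f)\n", m, x$mean[[m]], x$sd[[m]]))
  cat("Pooled confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}
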