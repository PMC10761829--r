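#' Build a confusion matrix
#'
#' Rows are true classes, columns predicted classes, over a fixed common
#' level set.
#'
#' @param truth True class labels.
#' @param pred Predicted class labels.
#' @param levels Optional class level set; default is the union of levels
#'   observed in `truth` and `pred`, sorted.
#' @return Integer C-by-C matrix with dimnames.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(pred))))
  t <- factor(as.character(truth), levels = levels)
  p <- factor(as.character(pred), levels = levels)
  unclass(table(true = t, predicted = p))
}

#' Seven classification metrics from a confusion matrix
#'
#' Computes accuracy, recall (sensitivity), specificity, precision, F1,
#' the multiclass Matthews correlation coefficient (the R_K statistic) and
#' Cohen's kappa from a C-by-C confusion matrix (rows = truth, columns =
#' predicted). Recall, specificity, precision and F1 are computed per
#' class one-vs-rest and macro-averaged. Classes absent from both rows and
#' columns are excluded from the macro averages with a warning; a per-class
#' value with zero denominator contributes 0.
#'
#' @param cm Square numeric matrix of counts.
#' @return Object of class `metrics_report`: named list with the seven
#'   metrics, `averaging = "macro"`, `n` (total count) and `per_class`.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  C <- nrow(cm)
  rs <- rowSums(cm); cs <- colSums(cm)

  present <- rs + cs > 0
  if (any(!present))
    warning("classes absent from both truth and prediction excluded: ",
            paste(rownames(cm)[!present], collapse = ", "))

  tp <- diag(cm)
  fn <- rs - tp
  fp <- cs - tp
  tn <- total - tp - fn - fp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  recall_c <- safe(tp, tp + fn)
  spec_c <- safe(tn, tn + fp)
  prec_c <- safe(tp, tp + fp)
  f1_c <- safe(2 * prec_c * recall_c, prec_c + recall_c)

  # multiclass MCC (R_K)
  num <- total * sum(tp) - sum(rs * cs)
  den <- sqrt(total^2 - sum(cs^2)) * sqrt(total^2 - sum(rs^2))
  mcc <- if (den == 0) 0 else num / den

  pe <- sum(rs * cs) / total^2
  po <- sum(tp) / total
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)

  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(C)),
    recall = recall_c, specificity = spec_c,
    precision = prec_c, f1 = f1_c
  )
  structure(
    list(accuracy = po,
         recall = mean(recall_c[present]),
         specificity = mean(spec_c[present]),
         precision = mean(prec_c[present]),
         f1 = mean(f1_c[present]),
         mcc = mcc, kappa = kappa,
         averaging = "macro", n = total,
         per_class = per_class[present, , drop = FALSE],
         confusion = cm),
    class = "metrics_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "Metrics (n = %d, %s-averaged):\n  accuracy %.4f  recall %.4f  specificity %.4f\n  precision %.4f  F1 %.4f  MCC %.4f  kappa %.4f\n",
    x$n, x$averaging, x$accuracy, x$recall, x$specificity,
    x$precision, x$f1, x$mcc, x$kappa))
  invisible(x)
}
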