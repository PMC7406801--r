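#' Classification performance report
#'
#' Confusion counts and the derived measures: sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), precision TP/(TP+FP), F1 (harmonic mean of
#' precision and sensitivity), balanced accuracy (the mean of sensitivity
#' and specificity, i.e. the average of the per-class proportions correct),
#' plain accuracy, and Cohen's kappa `(p0 - pc) / (1 - pc)` with the chance
#' agreement pc from the marginal products.
#'
#' @param y_true,y_pred Equal-length label vectors (factors, characters, or
#'   +1/-1); `y_true` must contain both classes.
#' @param positive The positive (disease) class label.
#' @return An object of class `eval_report` with elements `counts`
#'   (TP, FP, TN, FN), `sensitivity`, `specificity`, `precision`, `f1`,
#'   `balanced_accuracy`, `accuracy`, `kappa`.
#' @export
classification_report <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(positive)) {
    positive <- if (is.factor(y_true)) levels(droplevels(y_true))[1]
                else if (all(y_true %in% c(-1, 1))) 1
                else sort(unique(as.character(y_true)))[1]
  }
  tru <- y_true == positive
  prd <- y_pred == positive
  if (all(tru) || !any(tru)) stop("y_true must contain both classes")
  TP <- sum(tru & prd); FN <- sum(tru & !prd)
  TN <- sum(!tru & !prd); FP <- sum(!tru & prd)
  n <- TP + FP + TN + FN
  sen <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  pre <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f1 <- if (!is.na(pre) && pre + sen > 0) 2 * pre * sen / (pre + sen) else NA_real_
  p0 <- (TP + TN) / n
  pc <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
  kappa <- if (pc < 1) (p0 - pc) / (1 - pc) else 0
  structure(list(counts = c(TP = TP, FP = FP, TN = TN, FN = FN),
                 sensitivity = sen, specificity = spec, precision = pre,
                 f1 = f1, balanced_accuracy = (sen + spec) / 2,
                 accuracy = p0, kappa = kappa, positive = positive),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Classification report (positive class: %s)\n", x$positive))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  cat(sprintf("  ACC(balanced)=%.4f  accuracy=%.4f  SEN=%.4f  SPEC=%.4f\n",
              x$balanced_accuracy, x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  PRE=%.4f  F1=%.4f  kappa=%.4f\n", x$precision, x$f1, x$kappa))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' The ROC is traced over all score thresholds; the AUC is the normalized
#' Mann-Whitney statistic (concordant pairs, ties counted one half), which
#' equals the trapezoidal area under the curve.
#'
#' @param y_true Labels containing both classes.
#' @param scores Finite numeric decision scores (larger = more positive).
#' @param positive The positive-class label.
#' @return A list of class `roc_curve` with `points` (data.frame of
#'   threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(y_true, scores, positive = NULL) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (is.null(positive)) {
    positive <- if (is.factor(y_true)) levels(droplevels(y_true))[1]
                else if (all(y_true %in% c(-1, 1))) 1
                else sort(unique(as.character(y_true)))[1]
  }
  pos <- y_true == positive
  if (all(pos) || !any(pos)) stop("both classes must be present")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (length(unique(scores)) == 1L) {
    warning("constant scores; AUC set to 0.5")
    auc <- 0.5
  } else {
    r <- rank(scores, ties.method = "average")
    auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred_pos <- scores >= th
    c(fpr = sum(pred_pos & !pos) / n_neg, tpr = sum(pred_pos & pos) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  structure(list(points = data.frame(threshold = thr, fpr = pts[, "fpr"],
                                     tpr = pts[, "tpr"]),
                 auc = auc, positive = positive),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
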