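# Confusion matrices and the seven evaluation statistics: accuracy, recall
# (true positive rate), precision, F1 score, true negative rate, false
# negative rate, false positive rate. Binary tasks take the second factor
# level as the positive (palsy) class; multi-class reports trace accuracy and
# macro-averages the remaining statistics one-vs-rest.

#' Build a confusion matrix from truth and predictions
#'
#' @param truth,pred vectors of class labels (coerced to a common factor).
#' @param levels optional explicit label order; the last level is the
#'   positive class for binary metrics.
#' @return a `confusion_matrix`: a k x k count matrix, rows = truth,
#'   columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth),
                                               as.character(pred))))
  truth <- factor(as.character(truth), levels = levels)
  pred <- factor(as.character(pred), levels = levels)
  if (anyNA(truth) || anyNA(pred))
    stop("labels outside the declared level set")
  m <- table(truth = truth, pred = pred)
  structure(unclass(m), class = "confusion_matrix")
}

.binary_stats <- function(tp, tn, fp, fn) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, ": zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  c(Acc = ratio(tp + tn, tp + tn + fp + fn, "Acc"),
    Rec = ratio(tp, tp + fn, "Rec"),
    Prec = ratio(tp, tp + fp, "Prec"),
    F1s = ratio(2 * tp, 2 * tp + fp + fn, "F1s"),
    TNR = ratio(tn, tn + fp, "TNR"),
    FNR = ratio(fn, fn + tp, "FNR"),
    FPR = ratio(fp, fp + tn, "FPR"))
}

#' Compute the seven evaluation statistics from a confusion matrix
#'
#' Binary matrices give the textbook definitions directly. For k > 2 classes,
#' accuracy is the trace over the total and the other six statistics are
#' macro-averaged one-vs-rest (an extension beyond the binary formulas,
#' labelled as such in the report).
#'
#' @param cm a [confusion_matrix()].
#' @return named numeric vector `Acc, Rec, Prec, F1s, TNR, FNR, FPR` with
#'   attribute `averaging` (`"binary"` or `"macro"`). Undefined ratios are
#'   `NaN` with a warning, never silently 0.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  m <- unclass(cm)
  if (sum(m) == 0) stop("empty confusion matrix")
  k <- nrow(m)
  if (k == 2L) {
    tp <- m[2L, 2L]; tn <- m[1L, 1L]; fp <- m[1L, 2L]; fn <- m[2L, 1L]
    out <- .binary_stats(tp, tn, fp, fn)
    attr(out, "averaging") <- "binary"
  } else {
    per <- vapply(seq_len(k), function(i) {
      tp <- m[i, i]
      fn <- sum(m[i, -i])
      fp <- sum(m[-i, i])
      tn <- sum(m[-i, -i])
      .binary_stats(tp, tn, fp, fn)
    }, numeric(7L))
    out <- rowMeans(per)
    out[["Acc"]] <- sum(diag(m)) / sum(m)
    attr(out, "averaging") <- "macro"
  }
  out
}
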