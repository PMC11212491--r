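#' Classification metrics
#'
#' Binary tasks (2 classes) report ACC, F1 of the positive class (label
#' 1) and AUC computed from the fused confidence of class 1. Multiclass
#' tasks report ACC, support-weighted F1 and macro-averaged F1.
#'
#' @param y_true integer 0-based true labels.
#' @param y_pred integer 0-based predicted labels.
#' @param scores for binary tasks, the class-1 confidence per sample
#'   (vector, or a matrix whose second column is used); ignored for
#'   multiclass.
#' @return named numeric vector of metrics in `[0, 1]`.
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  stopifnot(length(y_true) == length(y_pred))
  n_classes <- max(y_true, y_pred) + 1L
  acc <- mean(y_true == y_pred)
  if (n_classes <= 2L) {
    if (length(unique(y_true)) < 2L) {
      stop("AUC undefined: only one class present in y_true", call. = FALSE)
    }
    if (is.matrix(scores)) scores <- scores[, 2L]
    if (is.null(scores)) stop("binary metrics need class-1 scores", call. = FALSE)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = y_true, predictor = scores,
      levels = c(0, 1), direction = "<", quiet = TRUE
    )))
    c(ACC = acc, F1 = f1_per_class(y_true, y_pred, n_classes)[2L], AUC = auc)
  } else {
    f1 <- f1_per_class(y_true, y_pred, n_classes)
    support <- tabulate(y_true + 1L, n_classes)
    c(ACC = acc,
      F1_weighted = sum(f1 * support) / sum(support),
      F1_macro = mean(f1))
  }
}

# per-class F1 from the confusion matrix; empty classes score 0
f1_per_class <- function(y_true, y_pred, n_classes) {
  vapply(seq_len(n_classes) - 1L, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
}
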