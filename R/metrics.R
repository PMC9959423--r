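#' Confusion matrix
#'
#' Counts with rows = actual class and columns = predicted class.
#'
#' @param predicted,actual Equal-length label vectors.
#' @param classes Class vocabulary fixing row/column order.
#' @return Integer matrix `length(classes) x length(classes)`.
#' @export
confusion_matrix <- function(predicted, actual,
                             classes = sort(unique(c(predicted, actual)))) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have equal length")
  tab <- table(factor(actual, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  m
}

#' One-vs-rest metrics for one class of a confusion matrix
#'
#' Treats `class` as positive and everything else as negative:
#' TP is the diagonal entry, FN the rest of its row, FP the rest of its
#' column, TN the remainder.  Rates are percentages (TPR, TNR, FPR,
#' FNR, PPV, NPV, ACC); by construction TPR + FNR = 100 and
#' TNR + FPR = 100.  A class absent from both rows and columns yields
#' NaN rates with a warning.
#'
#' @param cm Confusion matrix (rows = actual).
#' @param class Row/column name or index of the positive class.
#' @return Named list with counts `tp, fn, fp, tn` and raw (unrounded)
#'   percentage rates; round with [round_half_up()] for reporting.
#' @export
one_vs_rest_metrics <- function(cm, class) {
  cm <- as.matrix(cm)
  if (is.character(class)) class <- match(class, rownames(cm))
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  if (tp + fn + fp == 0) warning("class absent from the matrix")
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       tpr = 100 * tp / (tp + fn), tnr = 100 * tn / (tn + fp),
       fpr = 100 * fp / (tn + fp), fnr = 100 * fn / (tp + fn),
       ppv = 100 * tp / (tp + fp), npv = 100 * tn / (tn + fn),
       acc = 100 * (tp + tn) / sum(cm))
}

#' Per-class metrics table
#'
#' [one_vs_rest_metrics()] for every class of a confusion matrix,
#' rounded to two decimals (half-up) in the standard column order.
#'
#' @param cm Confusion matrix (rows = actual).
#' @return Data frame with one row per class: TP, FN, FP, TN, TPR, TNR,
#'   FPR, FNR, PPV, NPV, ACC.
#' @export
metrics_table <- function(cm) {
  rows <- lapply(rownames(cm), function(cl) {
    m <- one_vs_rest_metrics(cm, cl)
    data.frame(class = cl, TP = m$tp, FN = m$fn, FP = m$fp, TN = m$tn,
               TPR = round_half_up(m$tpr), TNR = round_half_up(m$tnr),
               FPR = round_half_up(m$fpr), FNR = round_half_up(m$fnr),
               PPV = round_half_up(m$ppv), NPV = round_half_up(m$npv),
               ACC = round_half_up(m$acc))
  })
  do.call(rbind, rows)
}

#' Binary mask pixel accuracy
#'
#' @param pred_mask,gt_mask Logical matrices of identical shape.
#' @return Percentage of matching pixels.
#' @export
mask_accuracy <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) stop("shape mismatch")
  100 * mean((pred_mask > 0) == (gt_mask > 0))
}

#' Three-class pixel accuracy inside the tooth area
#'
#' Accuracy of the white-yellow / opaque / brown labels over the
#' ground-truth tooth pixels only; predictions outside the ground-truth
#' tooth area are ignored.
#'
#' @param pred_map3,gt_map3 Three-class maps of identical shape.
#' @param gt_mask Ground-truth tooth mask.
#' @return Percentage.
#' @export
three_class_accuracy <- function(pred_map3, gt_map3, gt_mask) {
  if (!identical(dim(pred_map3), dim(gt_map3)) ||
      !identical(dim(pred_map3), dim(gt_mask))) stop("shape mismatch")
  sel <- gt_mask > 0
  if (!any(sel)) stop("empty ground-truth tooth area")
  100 * mean(pred_map3[sel] == gt_map3[sel])
}

#' Count-weighted average of per-class values
#'
#' \eqn{\sum_c n_c v_c / \sum_c n_c}; used to average per-class
#' accuracies over images.
#'
#' @param values Numeric vector of per-class values.
#' @param counts Numeric vector of per-class counts (same length).
#' @return Scalar weighted mean.
#' @export
weighted_class_average <- function(values, counts) {
  stopifnot(length(values) == length(counts))
  if (sum(counts) == 0) stop("zero total count")
  sum(values * counts) / sum(counts)
}
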