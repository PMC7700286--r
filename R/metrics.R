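# ---------------------------------------------------------------------------
# Segmentation and classification evaluation: pixel-level binary counts and
# rates, one-vs-rest multi-class counting from a confusion matrix, weighted
# overall accuracy, and AND-consensus ground-truth construction.
# ---------------------------------------------------------------------------

#' Pixel-level 2x2 tally between a predicted and a gold binary mask
#'
#' @param pred,gold binary masks (0/1) of identical shape.
#' @return a list of class `binary_counts` with integer fields `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
binary_counts <- function(pred, gold) {
  stopifnot_same_shape(pred, gold)
  stopifnot(is_binary_mask(pred), is_binary_mask(gold))
  tp <- sum(pred == 1 & gold == 1)
  fp <- sum(pred == 1 & gold == 0)
  fn <- sum(pred == 0 & gold == 1)
  tn <- sum(pred == 0 & gold == 0)
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn), class = "binary_counts")
}

#' Classification rates from TP/FP/FN/TN counts
#'
#' Computes accuracy, precision, sensitivity (recall), specificity, the Dice
#' similarity coefficient `2TP/(2TP+FP+FN)` and the Jaccard index
#' `TP/(TP+FP+FN)`.  A rate whose denominator is zero is reported as `NaN`
#' and flagged in `undefined`, rather than silently coerced to zero.
#'
#' @param counts a `binary_counts` object or list with TP/FP/FN/TN.
#' @return named list of rates plus an `undefined` character vector.
#' @export
binary_metrics <- function(counts) {
  rate <- function(num, den) if (den > 0) num / den else NaN
  with(counts, {
    m <- list(
      accuracy    = rate(TP + TN, TP + TN + FP + FN),
      precision   = rate(TP, TP + FP),
      sensitivity = rate(TP, TP + FN),
      specificity = rate(TN, TN + FP),
      dsc         = rate(2 * TP, 2 * TP + FP + FN),
      jaccard     = rate(TP, TP + FP + FN))
    m$undefined <- names(m)[vapply(m, is.nan, TRUE)]
    m
  })
}

#' Confusion matrix of gold vs predicted class labels
#'
#' @param gold,pred factors or vectors of equal length; `levels` fixes the
#'   class order (defaults to the sorted union).
#' @return K x K integer matrix, rows = gold, columns = predicted.
#' @export
confusion_matrix <- function(gold, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(gold),
                                               as.character(pred))))
  stopifnot(length(gold) == length(pred))
  g <- factor(as.character(gold), levels = levels)
  p <- factor(as.character(pred), levels = levels)
  unclass(table(gold = g, predicted = p))
}

#' One-vs-rest counts for one class of a multi-class confusion matrix
#'
#' For class `c`: TP is the diagonal cell; FN the rest of row `c` (gold `c`
#' predicted as any other class); FP the rest of column `c`; TN everything
#' not involving class `c`.
#'
#' @param cm K x K confusion matrix (gold rows, predicted columns).
#' @param class row/column index or dimname of the class of interest.
#' @return a `binary_counts` object.
#' @export
multiclass_counts <- function(cm, class) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  if (is.character(class)) class <- match(class, rownames(cm))
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn), class = "binary_counts")
}

#' Support-weighted overall accuracy from per-class rates
#'
#' `100 * sum(rate_c * n_c) / sum(n_c)` — the overall percentage correct when
#' per-class correct-classification rates are combined with their class sizes.
#'
#' @param per_class_rates per-class correct rates in `[0,1]`.
#' @param class_sizes matching positive class sizes.
#' @return overall accuracy as a percentage.
#' @export
weighted_overall_accuracy <- function(per_class_rates, class_sizes) {
  if (length(per_class_rates) != length(class_sizes))
    stop("rates and sizes must have equal length")
  stopifnot(all(class_sizes > 0))
  100 * sum(per_class_rates * class_sizes) / sum(class_sizes)
}

#' Consensus ground truth by pixel-wise logical AND
#'
#' A pixel is dense in the consensus mask only where both annotators marked
#' it dense.
#'
#' @param maskA,maskB binary masks of identical shape.
#' @return binary mask of the same shape.
#' @export
consensus_mask <- function(maskA, maskB) {
  stopifnot_same_shape(maskA, maskB)
  out <- (maskA == 1) * (maskB == 1)
  dim(out) <- dim(maskA)
  out
}

#' Per-class and overall segmentation report
#'
#' Computes per-image binary metrics for each (prediction, ground truth) pair,
#' averages them within each BI-RADS class and over all images.
#'
#' @param gold_masks,pred_masks lists of binary masks, pairwise same shape.
#' @param classes per-image class labels (e.g. `"I".."IV"`).
#' @return list with `per_image` (data.frame), `per_class` and `all` (rows of
#'   mean accuracy / dsc / jaccard / precision / sensitivity / specificity).
#' @export
evaluate_segmentation <- function(pred_masks, gold_masks, classes) {
  stopifnot(length(pred_masks) == length(gold_masks),
            length(classes) == length(gold_masks))
  if (any(vapply(pred_masks, is.null, TRUE)))
    stop("missing prediction for image(s): ",
         paste(which(vapply(pred_masks, is.null, TRUE)), collapse = ", "))
  rows <- lapply(seq_along(gold_masks), function(i) {
    m <- binary_metrics(binary_counts(pred_masks[[i]], gold_masks[[i]]))
    data.frame(image = i, class = as.character(classes[i]),
               accuracy = m$accuracy, dsc = m$dsc, jaccard = m$jaccard,
               precision = m$precision, sensitivity = m$sensitivity,
               specificity = m$specificity)
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_image), c("image", "class"))
  agg <- function(df) colMeans(df[metric_cols], na.rm = TRUE)
  per_class <- do.call(rbind, lapply(split(per_image, per_image$class), agg))
  list(per_image = per_image, per_class = per_class, all = agg(per_image))
}

#' Full multi-class classification report
#'
#' One-vs-rest metrics per class plus macro-averaged and support-weighted
#' aggregates (both aggregations are reported because different conventions
#' exist in the literature).
#'
#' @param gold,pred class label vectors of equal length.
#' @param levels optional class order.
#' @return list with `confusion`, `per_class` data.frame, `macro`,
#'   `weighted`, and `overall_accuracy` (percent).
#' @export
evaluate_classification <- function(gold, pred, levels = NULL) {
  cm <- confusion_matrix(gold, pred, levels)
  K <- nrow(cm)
  per <- do.call(rbind, lapply(seq_len(K), function(k) {
    m <- binary_metrics(multiclass_counts(cm, k))
    data.frame(class = rownames(cm)[k], support = sum(cm[k, ]),
               precision = m$precision, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy)
  }))
  metric_cols <- c("precision", "sensitivity", "specificity", "accuracy")
  w <- per$support / sum(per$support)
  list(confusion = cm,
       per_class = per,
       macro = colMeans(per[metric_cols], na.rm = TRUE),
       weighted = colSums(per[metric_cols] * w, na.rm = TRUE),
       overall_accuracy = 100 * sum(diag(cm)) / sum(cm))
}
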