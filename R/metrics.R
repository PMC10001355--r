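# Segmentation and classification metrics.
#
# Segmentation: Jaccard (JA), Dice (DI) and pixel-wise accuracy/sensitivity/
# specificity; dataset-level scores are means of per-image scores (the
# ISIC-2017 challenge convention). Classification: accuracy, sensitivity,
# specificity at the argmax decision and one-vs-rest AUC from the softmax
# probability of the positive class, macro-averaged over the melanoma and
# seborrheic-keratosis tasks.

#' Jaccard index between two binary masks
#'
#' `|a intersect b| / |a union b|` counted over lesion (1) pixels. Both masks
#' empty is defined as perfect agreement (1.0).
#'
#' @param a,b binary masks of identical dimensions.
#' @return a value in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_same_dims(a, b)
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(1)
  inter / uni
}

#' Dice coefficient between two binary masks
#'
#' `2 |a intersect b| / (|a| + |b|)`; the monotone transform
#' `dice = 2 ja / (1 + ja)` of the Jaccard index. Both masks empty is
#' defined as 1.0.
#'
#' @inheritParams jaccard
#' @return a value in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_dims(a, b)
  inter <- sum(a == 1 & b == 1)
  tot <- sum(a == 1) + sum(b == 1)
  if (tot == 0) return(1)
  2 * inter / tot
}

#' Pixel-wise confusion counts
#'
#' @param pred,truth binary masks of identical dimensions.
#' @return named integer vector `c(tp, fp, tn, fn)`; the four counts sum to
#'   the total number of pixels.
#' @export
pixel_confusion <- function(pred, truth) {
  check_same_dims(pred, truth)
  c(tp = sum(pred == 1 & truth == 1),
    fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0),
    fn = sum(pred == 0 & truth == 1))
}

rate_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Per-image segmentation metrics
#'
#' @inheritParams pixel_confusion
#' @return named vector `c(ja, di, pixel_ac, pixel_se, pixel_sp)`;
#'   sensitivity/specificity are `NA` when the corresponding class is absent
#'   from the ground truth.
#' @export
seg_metrics <- function(pred, truth) {
  cf <- pixel_confusion(pred, truth)
  c(ja = jaccard(pred, truth),
    di = dice(pred, truth),
    pixel_ac = (cf[["tp"]] + cf[["tn"]]) / sum(cf),
    pixel_se = rate_or_na(cf[["tp"]], cf[["tp"]] + cf[["fn"]]),
    pixel_sp = rate_or_na(cf[["tn"]], cf[["tn"]] + cf[["fp"]]))
}

#' Evaluate a list of predicted masks against ground truth
#'
#' @param preds,truths lists of binary masks of equal length.
#' @return one-row data frame with the means of the per-image
#'   `ja`, `di`, `pixel_ac`, `pixel_se`, `pixel_sp` scores.
#' @export
evaluate_segmentation <- function(preds, truths) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1L)
  per <- t(vapply(seq_along(preds),
                  function(i) seg_metrics(preds[[i]], truths[[i]]),
                  numeric(5)))
  as.data.frame(t(colMeans(per, na.rm = TRUE)))
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney rank statistic: the probability that a
#' positive outscores a negative, counting ties as one half.
#'
#' @param scores numeric scores (higher means more positive).
#' @param labels binary labels (0/1 or logical), at least one of each class.
#' @return a value in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)),
            all(is.finite(scores)))
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    stop("AUC is undefined when only one class is present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Macro-average a list of per-class classification reports
#'
#' @param per_class non-empty list of named numeric vectors (or one-row data
#'   frames) with fields `ac`, `se`, `sp`, `auc`.
#' @return the fieldwise arithmetic mean as a named vector.
#' @export
macro_average <- function(per_class) {
  if (length(per_class) < 1L) stop("cannot average an empty list of reports")
  m <- do.call(rbind, lapply(per_class, function(r) unlist(r)[c("ac", "se", "sp", "auc")]))
  colMeans(m)
}

#' Classification report from predicted probabilities
#'
#' One-vs-rest accuracy, sensitivity and specificity at the argmax decision
#' and AUC from the softmax probability, per disease class, plus an `average`
#' row macro-averaged over the melanoma and seborrheic-keratosis tasks (the
#' two diseases the reference evaluation averages over).
#'
#' @param probs n x 3 matrix of class probabilities with columns in
#'   [disease_levels] order.
#' @param truth factor of true labels with levels [disease_levels].
#' @return data frame with columns `class`, `ac`, `se`, `sp`, `auc`.
#' @export
cls_report_from_probs <- function(probs, truth) {
  stopifnot(is.matrix(probs), ncol(probs) == 3L, nrow(probs) == length(truth))
  truth <- factor(truth, levels = disease_levels)
  pred <- factor(disease_levels[max.col(probs, ties.method = "first")],
                 levels = disease_levels)
  rows <- lapply(disease_levels, function(cl) {
    is_pos <- truth == cl
    is_pred <- pred == cl
    data.frame(
      class = cl,
      ac = mean(is_pred == is_pos),
      se = rate_or_na(sum(is_pred & is_pos), sum(is_pos)),
      sp = rate_or_na(sum(!is_pred & !is_pos), sum(!is_pos)),
      auc = if (any(is_pos) && any(!is_pos))
        auc(probs[, match(cl, disease_levels)], is_pos) else NA_real_)
  })
  rep_df <- do.call(rbind, rows)
  avg_classes <- c("melanoma", "seborrheic_keratosis")
  avg <- macro_average(lapply(avg_classes, function(cl)
    rep_df[rep_df$class == cl, c("ac", "se", "sp", "auc")]))
  rbind(rep_df, data.frame(class = "average", ac = avg[["ac"]],
                           se = avg[["se"]], sp = avg[["sp"]],
                           auc = avg[["auc"]]))
}

#' Write a metrics report to CSV
#'
#' @param report data frame (e.g. from [cls_report_from_probs()] or
#'   [evaluate_segmentation()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
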