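# Mask-assisted disease classification: train and evaluate the three-class
# disease classifier on image-mask channel stacks, with masks drawn from a
# named source (none, teacher, student, or - in tests - ground truth).

#' Mask sources for disease classification
#' @export
mask_sources <- c("none", "teacher", "student", "ground_truth")

#' Predict hard lesion masks for a list of images
#'
#' Runs a trained segmenter over classification images to provide their
#' mask channel (the mask source "teacher" or "student").
#'
#' @param model a trained `seg_model`.
#' @param images list of [lesion_image]s.
#' @param threshold binarization cut.
#' @return list of hard masks.
#' @export
predict_masks <- function(model, images, threshold = 0.5) {
  lapply(images, function(im) generate_pseudo_label(model, im, threshold))
}

#' Train the disease classifier
#'
#' Three-class classifier (melanoma, nevus, seborrheic keratosis) on RGB
#' images, optionally concatenated with a lesion mask as the fourth input
#' channel. With `masks = NULL` a 3-channel baseline is trained.
#'
#' @param dli an [image_labeled_set].
#' @param masks `NULL`, or a list with one mask per image (from
#'   [predict_masks()] or ground truth in tests).
#' @param cfg a [train_config()].
#' @param class_weights passed to [train_cls()]; use `"inverse"` for
#'   imbalanced label distributions.
#' @param base_channels backbone width.
#' @return a trained C = 3 `cls_model`.
#' @export
train_disease_cn <- function(dli, masks = NULL, cfg = train_config(),
                             class_weights = NULL, base_channels = 8L) {
  stopifnot(inherits(dli, "image_labeled_set"))
  if (!is.null(masks) && length(masks) != length(dli))
    stop("need exactly one mask per classification image")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  model <- cls_model(in_channels = if (is.null(masks)) 3L else 4L,
                     n_classes = 3L, base_channels = base_channels)
  data <- lapply(seq_along(dli$items), function(i)
    list(image = dli$items[[i]]$image,
         label = as.integer(dli$items[[i]]$label),
         mask = if (!is.null(masks)) masks[[i]]))
  cfg$seed <- NULL
  train_cls(model, data, cfg, class_weights = class_weights)
}

#' Evaluate the disease classifier
#'
#' Computes per-class and macro-averaged accuracy, sensitivity, specificity
#' and one-vs-rest AUC on a labeled test set, with the same channel
#' configuration used in training. Evaluation is invariant to sample order.
#'
#' @param model a trained C = 3 `cls_model`.
#' @param test list of `list(image, label, mask = NULL)` items; masks are
#'   required exactly when the model takes 4-channel input.
#' @return data frame from [cls_report_from_probs()].
#' @export
evaluate_disease_cn <- function(model, test) {
  stopifnot(inherits(model, "cls_model"), model$arch$n_classes == 3L)
  probs <- t(vapply(test, function(it) {
    mk <- if (model$arch$in_channels == 4L) {
      if (is.null(it$mask)) stop("model requires a mask channel for every image")
      it$mask
    }
    cls_forward(model, it$image, mask_channel = mk)$probs
  }, numeric(3)))
  truth <- factor(vapply(test, function(it) as.character(it$label),
                         character(1)), levels = disease_levels)
  cls_report_from_probs(probs, truth)
}
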