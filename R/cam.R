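# Class activation maps from the disease classifier, used as localization
# priors in the student segmentation network's fusion layer.

#' Compute a class activation map
#'
#' Weights the last convolutional feature maps of the classifier by the
#' output-layer weights of the chosen class and sums over channels. The raw
#' map is ReLU-clipped, bilinearly upsampled to the image resolution, and
#' min-max normalized to \[0, 1\]. A degenerate constant map (max equals
#' min, e.g. when the class weights are all zero) yields an all-zero map
#' with a warning.
#'
#' @param model a trained `cls_model` (typically the disease classifier).
#' @param image a [lesion_image] or raster array.
#' @param mask_channel optional mask concatenated as the fourth input
#'   channel (required when the model was trained on 4-channel input).
#' @param target_class class index used for weighting; `NULL` uses the
#'   argmax prediction (unlabeled and pseudo-labeled images carry no disease
#'   label).
#' @return object of class `cam_map`: list with `values` (H x W matrix in
#'   \[0, 1\]) and `source_class`.
#' @export
compute_cam <- function(model, image, mask_channel = NULL,
                        target_class = NULL) {
  r <- cls_forward(model, image, mask_channel)
  cl <- if (is.null(target_class)) which.max(r$probs)
        else as.integer(target_class)
  stopifnot(cl >= 1L, cl <= length(r$probs))
  fm <- r$feature_maps
  hw <- dim(fm)[1] * dim(fm)[2]
  raw <- matrix(matrix(fm, hw) %*% r$class_weights[cl, ], dim(fm)[1])
  raw[raw < 0] <- 0
  px <- image_pixels(image)
  up <- resize_map(raw, dim(px)[1], dim(px)[2])
  rng <- range(up)
  if (diff(rng) < 1e-12) {
    warning("degenerate constant activation map; returning all zeros")
    vals <- matrix(0, dim(px)[1], dim(px)[2])
  } else {
    vals <- (up - rng[1]) / diff(rng)
  }
  structure(list(values = vals, source_class = cl), class = "cam_map")
}

#' Class activation maps for a student training set
#'
#' Computes one CAM per training image, feeding each image's available mask
#' (ground truth for the pixel-labeled set, pseudo-label for the screened
#' set) as the fourth input channel of the disease classifier.
#'
#' @param disease_model a trained 4-channel C = 3 `cls_model`.
#' @param data a [pixel_labeled_set], [pseudo_labeled_set], or list of
#'   `list(image, mask)` items; every item must carry a mask.
#' @return list of `cam_map` objects, one per item.
#' @export
cam_batch_for_training <- function(disease_model, data) {
  if (inherits(data, "pixel_labeled_set") || inherits(data, "pseudo_labeled_set"))
    data <- data$items
  lapply(data, function(it) {
    if (is.null(it$mask)) stop("every training image needs a mask for CAM input")
    compute_cam(disease_model, it$image, mask_channel = it$mask)
  })
}

#' Train the student segmentation network
#'
#' Trains a fusion-port segmentation network on the union of the
#' pixel-labeled set (supervised by ground truth) and the screened
#' pseudo-labeled set (supervised by pseudo-labels), feeding each image's
#' CAM to the fusion layer as a localization prior.
#'
#' @param student a [seg_model()] with `fusion = TRUE`.
#' @param dlp a [pixel_labeled_set].
#' @param dpseudo a [pseudo_labeled_set] (may be empty).
#' @param cams list of `cam_map`s (or bare matrices), one per training image
#'   in `c(dlp, dpseudo)` order.
#' @param cfg a [train_config()].
#' @param val optional validation pairs for early stopping.
#' @return the trained student `seg_model`.
#' @export
train_student <- function(student, dlp, dpseudo = NULL, cams = NULL,
                          cfg = train_config(), val = NULL) {
  stopifnot(inherits(student, "seg_model"))
  if (!student$arch$fusion) stop("student model must have a fusion port")
  data <- dlp$items
  if (!is.null(dpseudo) && length(dpseudo) > 0L)
    data <- c(data, dpseudo$items)
  if (is.null(cams) || length(cams) != length(data))
    stop("need exactly one CAM per training image (",
         length(data), " images)")
  cam_mats <- lapply(cams, function(cm)
    if (inherits(cm, "cam_map")) cm$values else cm)
  train_seg(student, data, cfg, cams = cam_mats, val = val)$model
}

#' Two-pass student inference
#'
#' Reproduces the staged inference of the framework on a test image with no
#' annotations: the teacher predicts a provisional mask, the disease
#' classifier turns image plus provisional mask into a CAM, and the student
#' segments with that CAM as its fusion prior.
#'
#' @param student trained fusion `seg_model`.
#' @param image a [lesion_image].
#' @param teacher trained teacher `seg_model`.
#' @param disease_model trained 4-channel disease `cls_model`.
#' @param threshold binarization cut for the provisional teacher mask.
#' @return soft mask (H x W matrix in \[0, 1\]).
#' @export
two_pass_forward <- function(student, image, teacher, disease_model,
                             threshold = 0.5) {
  pl <- generate_pseudo_label(teacher, image, threshold)
  cam <- suppressWarnings(compute_cam(disease_model, image, mask_channel = pl))
  seg_forward(student, image, prior = cam$values)
}
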