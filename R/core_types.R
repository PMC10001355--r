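# Shared domain types and conventions.
#
# Rasters use row-major (row, column) indexing with the origin at the top
# left; images are H x W x 3 arrays with intensities in [0, 1]; masks are
# H x W integer matrices with lesion = 1 and background = 0 (the ISIC
# ground-truth PNG convention, 255 -> 1). This is an internal contract used
# by every module.

#' Disease categories
#'
#' The three skin-disease classes, in the fixed factor-level order used by
#' every classifier and metrics report in the package.
#' @export
disease_levels <- c("melanoma", "nevus", "seborrheic_keratosis")

#' Construct a disease label
#'
#' @param value one of `"melanoma"`, `"nevus"`, `"seborrheic_keratosis"`.
#' @return a length-1 factor with levels [disease_levels].
#' @export
disease_label <- function(value) {
  if (length(value) != 1L || !value %in% disease_levels)
    stop("disease label must be exactly one of: ",
         paste(disease_levels, collapse = ", "))
  factor(value, levels = disease_levels)
}

#' Construct a dermoscopy image
#'
#' @param pixels H x W x 3 numeric array with intensities in \[0, 1\].
#' @param id character identifier.
#' @return object of class `lesion_image`.
#' @export
lesion_image <- function(pixels, id = "img") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    stop("image pixels must be an H x W x 3 array")
  if (d[1] < 16L || d[2] < 16L)
    stop("image must be at least 16 x 16")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]")
  structure(list(id = as.character(id), pixels = pixels),
            class = "lesion_image")
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf("<lesion_image '%s' %dx%d>\n", x$id,
              dim(x$pixels)[1], dim(x$pixels)[2]))
  invisible(x)
}

image_pixels <- function(img) {
  if (inherits(img, "lesion_image")) img$pixels else img
}

#' Validate a binary lesion mask
#'
#' @param m numeric or integer matrix containing only 0 and 1
#'   (lesion = 1, normal skin = 0).
#' @return an integer matrix of class `lesion_mask`.
#' @export
as_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop("mask values must be 0 or 1")
  structure(matrix(as.integer(m), nrow(m), ncol(m)), class = "lesion_mask")
}

check_same_dims <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop("spatial dimensions do not match: ",
         paste(dim(a)[1:2], collapse = "x"), " vs ",
         paste(dim(b)[1:2], collapse = "x"))
  invisible(TRUE)
}

#' Binarize a soft segmentation map
#'
#' Thresholds the sigmoid output of a segmentation head into a hard lesion
#' mask. A pixel becomes lesion (1) exactly when its score is greater than or
#' equal to `threshold`.
#'
#' @param soft numeric matrix in \[0, 1\] (a soft mask).
#' @param threshold cut point in (0, 1\]; default 0.5.
#' @return a [as_mask()] lesion mask of the same dimensions.
#' @export
binarize <- function(soft, threshold = 0.5) {
  if (!is.matrix(soft)) stop("soft mask must be a matrix")
  if (!all(is.finite(soft))) stop("soft mask contains non-finite values")
  if (min(soft) < 0 || max(soft) > 1) stop("soft mask values must be in [0, 1]")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a single value in (0, 1]")
  as_mask((soft >= threshold) * 1L)
}

# --- dataset containers -----------------------------------------------------

new_set <- function(items, class) structure(list(items = items), class = class)

#' Pixel-level labeled training set
#'
#' @param items list of `list(image = lesion_image, mask = lesion_mask)`
#'   pairs; every mask must match its image spatially.
#' @return object of class `pixel_labeled_set`.
#' @export
pixel_labeled_set <- function(items) {
  if (length(items) < 1L) stop("pixel-labeled set must be non-empty")
  for (it in items) {
    stopifnot(inherits(it$image, "lesion_image"), inherits(it$mask, "lesion_mask"))
    check_same_dims(it$image$pixels, it$mask)
  }
  new_set(items, "pixel_labeled_set")
}

#' Image-level labeled training set
#'
#' @param items list of `list(image = lesion_image, label = disease_label)`.
#' @return object of class `image_labeled_set`.
#' @export
image_labeled_set <- function(items) {
  if (length(items) < 1L) stop("image-labeled set must be non-empty")
  for (it in items) {
    stopifnot(inherits(it$image, "lesion_image"), is.factor(it$label))
  }
  new_set(items, "image_labeled_set")
}

#' Unlabeled image pool
#'
#' @param items list of [lesion_image] objects (may be empty).
#' @return object of class `unlabeled_set`.
#' @export
unlabeled_set <- function(items) {
  for (it in items) stopifnot(inherits(it, "lesion_image"))
  new_set(items, "unlabeled_set")
}

#' Pseudo-label quality-grade training set
#'
#' Holds `k * N` triples `((image, pseudo_label), quality)` built from the
#' teacher's checkpoints; pseudo-labels only, never ground truth.
#'
#' @param items list of
#'   `list(image, pseudo_label = lesion_mask, quality = 0/1, score)`.
#' @return object of class `quality_training_set`.
#' @export
quality_training_set <- function(items) {
  if (length(items) < 1L) stop("quality training set must be non-empty")
  for (it in items) {
    stopifnot(inherits(it$image, "lesion_image"),
              inherits(it$pseudo_label, "lesion_mask"),
              it$quality %in% c(0L, 1L))
  }
  new_set(items, "quality_training_set")
}

#' Screened pseudo-labeled set
#'
#' The reliable `(image, pseudo_label)` pairs retained by quality screening.
#'
#' @param items list of `list(image, mask = lesion_mask)`; may be empty.
#' @return object of class `pseudo_labeled_set`.
#' @export
pseudo_labeled_set <- function(items) {
  for (it in items) {
    stopifnot(inherits(it$image, "lesion_image"), inherits(it$mask, "lesion_mask"))
    check_same_dims(it$image$pixels, it$mask)
  }
  new_set(items, "pseudo_labeled_set")
}

#' @export
length.pixel_labeled_set <- function(x) length(x$items)
#' @export
length.image_labeled_set <- function(x) length(x$items)
#' @export
length.unlabeled_set <- function(x) length(x$items)
#' @export
length.quality_training_set <- function(x) length(x$items)
#' @export
length.pseudo_labeled_set <- function(x) length(x$items)
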