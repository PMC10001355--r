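# Reliable pseudo-label generation: train the teacher with checkpoints,
# grade checkpoint pseudo-labels by Jaccard against ground truth, train the
# binary quality-evaluation classifier on the graded set, and screen the
# unlabeled pool into a reliable pseudo-labeled set.

#' Quality threshold
#'
#' The empirical Jaccard cut above which a pseudo-label is graded reliable.
#' The default 0.8 sits above the teacher's typical mean Jaccard, so
#' "reliable" is strictly better than average.
#'
#' @param t value in (0, 1).
#' @return object of class `quality_threshold`.
#' @export
quality_threshold <- function(t = 0.8) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0, t < 1)
  structure(list(t = t), class = "quality_threshold")
}

thr_value <- function(t) if (inherits(t, "quality_threshold")) t$t else t

#' Grade a pseudo-label from its Jaccard score
#'
#' Applies the threshold rule: quality 1 (reliable) exactly when
#' `s >= t`, else 0. The boundary case `s == t` grades reliable.
#'
#' @param s Jaccard score in \[0, 1\].
#' @param t a [quality_threshold()] or a bare value in (0, 1).
#' @return integer 0 or 1.
#' @export
grade_pseudo_label <- function(s, t = quality_threshold()) {
  if (!is.numeric(s) || any(s < 0 | s > 1) || anyNA(s))
    stop("Jaccard score must lie in [0, 1]")
  as.integer(s >= thr_value(t))
}

#' Generate a pseudo-label from a model snapshot
#'
#' Runs the segmentation snapshot on the image and binarizes its soft
#' prediction.
#'
#' @param model a `seg_model` (e.g. a teacher checkpoint).
#' @param image a [lesion_image] or raster array.
#' @param threshold binarization cut (default 0.5).
#' @return a hard [as_mask()] pseudo-label.
#' @export
generate_pseudo_label <- function(model, image, threshold = 0.5) {
  binarize(seg_forward(model, image), threshold)
}

#' Build the pseudo-label quality-grade training set
#'
#' Runs every pixel-labeled image through each of the `k` teacher
#' checkpoints, grades each pseudo-label by its Jaccard score against the
#' ground-truth mask, and assembles the `k * N` graded pairs. Ground-truth
#' masks are used only to compute the grade; they never enter the entries.
#'
#' @param dlp a [pixel_labeled_set] of size N.
#' @param checkpoints a `checkpoint_set` from [train_seg()] (k >= 1
#'   snapshots).
#' @param t a [quality_threshold()].
#' @param threshold binarization cut for the pseudo-labels.
#' @return a [quality_training_set] of exactly `k * N` items, each
#'   `list(image, pseudo_label, quality, score)` (`score` is the grading
#'   Jaccard, kept for diagnostics only).
#' @export
build_quality_dataset <- function(dlp, checkpoints, t = quality_threshold(),
                                  threshold = 0.5) {
  stopifnot(inherits(dlp, "pixel_labeled_set"),
            inherits(checkpoints, "checkpoint_set"))
  if (length(checkpoints) < 1L) stop("need at least one teacher checkpoint")
  items <- list()
  for (it in dlp$items) {
    for (ck in checkpoints$items) {
      pl <- generate_pseudo_label(ck, it$image, threshold)
      s <- jaccard(it$mask, pl)
      items[[length(items) + 1L]] <- list(
        image = it$image, pseudo_label = pl,
        quality = grade_pseudo_label(s, t), score = s)
    }
  }
  quality_training_set(items)
}

#' Train the pseudo-label quality-evaluation classifier
#'
#' A binary (C = 2) classifier on 4-channel input: each image concatenated
#' with its pseudo-label along the channel dimension, optimized with
#' cross-entropy. Grade imbalance (late checkpoints are mostly reliable) is
#' handled with inverse-frequency class weights.
#'
#' @param dq a [quality_training_set].
#' @param cfg a [train_config()].
#' @param base_channels width of the classifier backbone.
#' @return a trained C = 2 `cls_model`.
#' @export
train_quality_cn <- function(dq, cfg = train_config(), base_channels = 8L) {
  stopifnot(inherits(dq, "quality_training_set"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  model <- cls_model(in_channels = 4L, n_classes = 2L,
                     base_channels = base_channels)
  data <- lapply(dq$items, function(it)
    list(image = it$image, mask = it$pseudo_label,
         label = it$quality + 1L))
  cfg$seed <- NULL  # weights drawn from the stream just seeded above
  train_cls(model, data, cfg, class_weights = "inverse")
}

#' Screen an unlabeled pool for reliable pseudo-labels
#'
#' For each pool image, the teacher's binarized pseudo-label is concatenated
#' with the image along the channel dimension and judged by the quality
#' classifier; the pair is retained exactly when the predicted quality class
#' is 1 (reliable). Screening only selects - retained masks are the
#' teacher's outputs, bit for bit.
#'
#' @param pool an [unlabeled_set] of size n.
#' @param teacher the trained teacher `seg_model`.
#' @param quality a trained C = 2 `cls_model`, or (for oracle tests) a
#'   function `(image, pseudo_label) -> 0/1`.
#' @param threshold binarization cut for pseudo-labels.
#' @return list with `set` (a [pseudo_labeled_set] of the n' retained pairs,
#'   in pool order) and `report` (data frame: `id`, `quality_prob`,
#'   `retained`, and `true_jaccard` when the pool carries hidden ground
#'   truth).
#' @export
screen_pool <- function(pool, teacher, quality, threshold = 0.5) {
  stopifnot(inherits(pool, "unlabeled_set"))
  if (inherits(quality, "cls_model") && quality$arch$n_classes != 2L)
    stop("quality classifier must have exactly two classes")
  hidden <- attr(pool, "hidden")
  retained_items <- list()
  rows <- list()
  for (i in seq_along(pool$items)) {
    img <- pool$items[[i]]
    pl <- generate_pseudo_label(teacher, img, threshold)
    if (is.function(quality)) {
      decision <- as.integer(quality(img, pl))
      prob <- as.numeric(decision)
    } else {
      probs <- cls_forward(quality, img, mask_channel = pl)$probs
      prob <- probs[2]
      decision <- as.integer(which.max(probs) == 2L)
    }
    if (decision == 1L)
      retained_items[[length(retained_items) + 1L]] <-
        list(image = img, mask = pl)
    rows[[i]] <- data.frame(
      id = img$id, quality_prob = prob, retained = decision == 1L,
      true_jaccard = if (!is.null(hidden)) jaccard(hidden$masks[[i]], pl)
                     else NA_real_)
  }
  list(set = pseudo_labeled_set(retained_items),
       report = do.call(rbind, rows))
}

#' Run the full pseudo-label self-training stage
#'
#' Composes the stage end to end: train the teacher with `k` checkpoints on
#' the pixel-labeled set, build the quality-grade training set, train the
#' quality classifier, and screen the unlabeled pool.
#'
#' @param dlp a [pixel_labeled_set].
#' @param du an [unlabeled_set] (may be empty; screening then returns an
#'   empty pseudo-labeled set but earlier stages still run).
#' @param seg_cfg,cls_cfg [train_config()]s for the teacher and the quality
#'   classifier.
#' @param t a [quality_threshold()].
#' @param k number of teacher checkpoints (default 5).
#' @param val optional validation pairs passed to [train_seg()].
#' @return list with `teacher`, `checkpoints`, `quality` (the trained
#'   classifier), `pseudo` (the [pseudo_labeled_set]) and `report` (the
#'   screening report).
#' @export
run_selftrain_stage <- function(dlp, du, seg_cfg = train_config(),
                                cls_cfg = train_config(max_epochs = 10L),
                                t = quality_threshold(), k = 5L, val = NULL) {
  stopifnot(inherits(dlp, "pixel_labeled_set"))
  if (!is.null(seg_cfg$seed)) set.seed(seg_cfg$seed)
  teacher0 <- seg_model()
  seg_cfg$seed <- NULL
  tr <- train_seg(teacher0, dlp, seg_cfg,
                  checkpoint_epochs = default_checkpoint_epochs(seg_cfg$max_epochs, k),
                  val = val)
  dq <- build_quality_dataset(dlp, tr$checkpoints, t)
  quality <- train_quality_cn(dq, cls_cfg)
  scr <- if (length(du) > 0L) screen_pool(du, tr$model, quality)
         else list(set = pseudo_labeled_set(list()), report = NULL)
  list(teacher = tr$model, checkpoints = tr$checkpoints, quality = quality,
       pseudo = scr$set, report = scr$report, history = tr$history)
}
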