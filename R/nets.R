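# Training and inference surface for the four networks: teacher and student
# segmentation networks (seg_model), and the pseudo-label quality and disease
# classifiers (cls_model). Optimization is Adam on per-image gradients with
# pixelwise binary cross-entropy plus a weighted rank loss for segmentation
# and (optionally class-weighted) cross-entropy for classification.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 0.0001, the reference
#'   setting).
#' @param max_epochs maximum training epochs. The reference setting caps
#'   training at 500 iterations; the desk-scale default is 30.
#' @param augment apply random horizontal/vertical flips and small integer
#'   translations (the desk-scale affine) to each training sample.
#' @param shift_max maximum translation in pixels when augmenting.
#' @param lambda_rank weight of the rank loss added to the pixelwise binary
#'   cross-entropy.
#' @param rank_top_k number of hardest foreground/background pixels paired by
#'   the rank loss.
#' @param rank_margin required score separation between paired hard pixels.
#' @param patience early-stopping patience in epochs on the validation
#'   Jaccard; `Inf` (the default) disables early termination. Whenever a
#'   validation set is supplied, training returns the weights of the best
#'   validation epoch regardless of `patience`.
#' @param seed RNG seed for shuffling, augmentation draws and weight
#'   initialization performed inside the training call; `NULL` uses the
#'   current RNG state.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, max_epochs = 30L,
                         augment = TRUE, shift_max = 3L,
                         lambda_rank = 0.1, rank_top_k = 30L,
                         rank_margin = 0.3, patience = Inf, seed = NULL) {
  stopifnot(learning_rate > 0, max_epochs >= 1L, shift_max >= 0L,
            lambda_rank >= 0, rank_top_k >= 1L, rank_margin > 0)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), augment = augment,
                 shift_max = as.integer(shift_max),
                 lambda_rank = lambda_rank,
                 rank_top_k = as.integer(rank_top_k),
                 rank_margin = rank_margin, patience = patience, seed = seed),
            class = "train_config")
}

#' Rank loss on hard pixel pairs
#'
#' Selects the `top_k` hardest foreground pixels (lowest predicted score
#' among truth = 1) and hardest background pixels (highest score among
#' truth = 0) and returns the mean hinge penalty
#' `max(0, margin - (s_fg - s_bg))` over the rank-paired pixels. Zero when
#' all selected pairs are separated by at least `margin`, and zero when the
#' mask lacks one of the two classes (no pairs).
#'
#' @param soft numeric matrix of predicted scores in \[0, 1\].
#' @param truth binary mask of the same dimensions.
#' @param top_k number of pairs (>= 1).
#' @param margin required separation (> 0).
#' @return a non-negative scalar.
#' @export
rank_loss <- function(soft, truth, top_k = 30L, margin = 0.3) {
  stopifnot(top_k >= 1L, margin > 0)
  check_same_dims(soft, truth)
  rank_loss_grad(soft, truth, top_k, margin)$loss
}

#' Segmentation training loss
#'
#' Pixelwise binary cross-entropy plus `lambda * rank_loss`. With
#' `lambda = 0` this is plain binary cross-entropy.
#'
#' @inheritParams rank_loss
#' @param lambda rank-loss weight.
#' @return scalar loss.
#' @export
seg_loss <- function(soft, truth, lambda = 0.1, top_k = 30L, margin = 0.3) {
  bce_loss(soft, truth) +
    if (lambda > 0) lambda * rank_loss(soft, truth, top_k, margin) else 0
}

#' Segmentation forward pass
#'
#' @param model a [seg_model()].
#' @param image a [lesion_image] or H x W x 3 array.
#' @param prior optional localization prior (class-activation map) at image
#'   resolution: a numeric matrix in \[0, 1\] or a `cam_map`. Requires a
#'   model with a fusion port; `NULL` on a fusion model feeds an all-zero
#'   prior.
#' @return soft mask: H x W numeric matrix in \[0, 1\].
#' @export
seg_forward <- function(model, image, prior = NULL) {
  stopifnot(inherits(model, "seg_model"))
  x <- image_pixels(image)
  if (dim(x)[1] %% 4 != 0 || dim(x)[2] %% 4 != 0)
    stop("segmentation input dims must be divisible by 4")
  if (!is.null(prior)) {
    if (inherits(prior, "cam_map")) prior <- prior$values
    if (!model$arch$fusion)
      stop("localization prior supplied to a model without a fusion port")
    check_same_dims(x, prior)
  }
  cam_grid <- if (model$arch$fusion) {
    if (is.null(prior)) matrix(0, dim(x)[1] / 4, dim(x)[2] / 4)
    else resize_map(prior, dim(x)[1] / 4, dim(x)[2] / 4)
  } else matrix(0, 1, 1)
  seg_infer_c(x, model$params, model$arch$fusion, cam_grid)
}

#' Classification forward pass
#'
#' @param model a [cls_model()].
#' @param image a [lesion_image] or H x W x 3 array.
#' @param mask_channel optional mask (hard or soft, values in \[0, 1\])
#'   concatenated as the fourth input channel; the model must have been
#'   built with `in_channels = 4`.
#' @return list with `probs` (softmax vector of length C summing to 1),
#'   `feature_maps` (last convolutional feature maps, h x w x c) and
#'   `class_weights` (C x c output-layer weights) for CAM computation.
#' @export
cls_forward <- function(model, image, mask_channel = NULL) {
  stopifnot(inherits(model, "cls_model"))
  x <- image_pixels(image)
  if (!is.null(mask_channel)) {
    check_same_dims(x, mask_channel)
    x <- concat_ch(x, as_cube(matrix(as.numeric(mask_channel),
                                     nrow(mask_channel))))
  }
  if (dim(x)[3] != model$arch$in_channels)
    stop(sprintf("model expects %d input channels, got %d",
                 model$arch$in_channels, dim(x)[3]))
  if (dim(x)[1] %% 8 != 0 || dim(x)[2] %% 8 != 0)
    stop("classification input dims must be divisible by 8")
  r <- cls_infer_c(x, model$params)
  list(probs = drop(r$probs), feature_maps = r$fmap,
       class_weights = model$params$fc_w)
}

# random flips + integer translation, applied identically to image, mask and
# prior; edge pixels are replicated under translation
augment_sample <- function(x, mask = NULL, cam = NULL, shift_max = 3L) {
  H <- dim(x)[1]; W <- dim(x)[2]
  hf <- runif(1) < 0.5; vf <- runif(1) < 0.5
  dr <- if (shift_max > 0L) sample(-shift_max:shift_max, 1L) else 0L
  dc <- if (shift_max > 0L) sample(-shift_max:shift_max, 1L) else 0L
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  if (vf) ri <- rev(ri)
  if (hf) ci <- rev(ci)
  list(x = x[ri, ci, , drop = FALSE],
       mask = if (!is.null(mask)) mask[ri, ci],
       cam = if (!is.null(cam)) cam[ri, ci])
}

snapshot_seg <- function(model) {
  structure(list(arch = model$arch, params = model$params), class = "seg_model")
}

#' Default checkpoint schedule
#'
#' `k` epochs evenly spaced from one fifth of training to the final epoch.
#' The window starts early enough that the first checkpoints still produce
#' partial, imperfect masks: the quality classifier must see realistic
#' mid-quality failures, not only converged output, to learn to reject the
#' marginal pseudo-labels in an unlabeled pool.
#'
#' @param max_epochs total training epochs.
#' @param k number of checkpoints (default 5, the reference setting).
#' @return integer vector of `k` epochs.
#' @export
default_checkpoint_epochs <- function(max_epochs, k = 5L) {
  stopifnot(max_epochs >= k)
  ep <- unique(round(seq(max_epochs / 5, max_epochs, length.out = k)))
  while (length(ep) < k) # tiny-budget degenerate case: pad earlier epochs
    ep <- unique(c(max(1L, min(ep) - 1L), ep))
  sort(as.integer(ep))
}

#' Train a segmentation network
#'
#' Per-image Adam training with pixelwise binary cross-entropy plus weighted
#' rank loss, optional flip/translation augmentation, parameter snapshots at
#' the requested epochs, and optional early stopping on validation Jaccard.
#'
#' @param model a [seg_model()].
#' @param data list of `list(image, mask)` training pairs, or a
#'   [pixel_labeled_set].
#' @param cfg a [train_config()].
#' @param checkpoint_epochs integer epochs at which to snapshot parameters
#'   (subset of `1:max_epochs`); `NULL` for no checkpoints.
#' @param cams optional list of localization priors (one per training item,
#'   image-resolution matrices) fed to the fusion port during training.
#' @param val optional validation list of `list(image, mask)` for early
#'   stopping when `cfg$patience` is finite.
#' @return list with `model` (final weights), `checkpoints` (a
#'   `checkpoint_set`: list of seg_model snapshots ordered by epoch) and
#'   `history` (per-epoch mean training loss and validation Jaccard).
#' @export
train_seg <- function(model, data, cfg = train_config(),
                      checkpoint_epochs = NULL, cams = NULL, val = NULL) {
  stopifnot(inherits(model, "seg_model"))
  if (inherits(data, "pixel_labeled_set") || inherits(data, "pseudo_labeled_set"))
    data <- data$items
  if (length(data) == 0L) stop("cannot train on an empty dataset")
  if (!is.null(cams) && length(cams) != length(data))
    stop("need exactly one localization prior per training image")
  if (!is.null(checkpoint_epochs))
    stopifnot(all(checkpoint_epochs >= 1L),
              all(checkpoint_epochs <= cfg$max_epochs))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  xs <- lapply(data, function(it) image_pixels(it$image))
  ys <- lapply(data, function(it) unclass(it$mask))
  flat <- params_to_flat(model)
  mstate <- numeric(length(flat)); vstate <- numeric(length(flat))
  tstep <- 0L
  cin <- model$arch$in_channels; c1 <- model$arch$channels[1]
  fusion <- model$arch$fusion
  checkpoints <- list()
  cp_epochs <- sort(unique(as.integer(checkpoint_epochs)))
  hist_loss <- numeric(0); hist_val <- numeric(0)
  best_val <- -Inf; since_best <- 0L; best_flat <- NULL
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(xs))
    total <- 0
    for (i in ord) {
      x <- xs[[i]]; y <- ys[[i]]
      cam <- if (!is.null(cams)) cams[[i]]
      if (cfg$augment) {
        a <- augment_sample(x, y, cam, cfg$shift_max)
        x <- a$x; y <- a$mask; cam <- a$cam
      }
      cam_grid <- if (fusion) {
        if (is.null(cam)) matrix(0, dim(x)[1] / 4, dim(x)[2] / 4)
        else resize_map(cam, dim(x)[1] / 4, dim(x)[2] / 4)
      } else matrix(0, 1, 1)
      tstep <- tstep + 1L
      total <- total + seg_train_step_flat(
        x, y, flat, mstate, vstate, tstep, cin, c1, fusion, cam_grid,
        cfg$learning_rate, cfg$lambda_rank, cfg$rank_top_k, cfg$rank_margin)
    }
    hist_loss[epoch] <- total / length(xs)
    if (epoch %in% cp_epochs)
      checkpoints[[length(checkpoints) + 1L]] <-
        snapshot_seg(flat_to_params(model, flat))
    if (!is.null(val) && length(val) > 0L) {
      vmodel <- flat_to_params(model, flat)
      vja <- mean(vapply(val, function(it)
        jaccard(binarize(seg_forward(vmodel, it$image)), it$mask), numeric(1)))
      hist_val[epoch] <- vja
      if (vja > best_val + 1e-6) {
        best_val <- vja; since_best <- 0L; best_flat <- c(flat)
      } else since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }
  # validation-monitored training returns the best-validation weights
  model <- flat_to_params(model, if (!is.null(best_flat)) best_flat else flat)
  list(model = model,
       checkpoints = structure(list(items = checkpoints,
                                    epochs = cp_epochs[seq_along(checkpoints)]),
                               class = "checkpoint_set"),
       history = list(loss = hist_loss, val_ja = hist_val))
}

#' @export
length.checkpoint_set <- function(x) length(x$items)

#' Train a classification network
#'
#' Per-sample Adam training with (optionally class-weighted) cross-entropy.
#' Accepts an optional mask channel per sample for mask-conditioned models.
#'
#' @param model a [cls_model()] with `n_classes` = C.
#' @param data list of `list(image, label, mask = NULL)` where `label` is an
#'   integer class index in 1..C (or a factor whose level index is used) and
#'   `mask` an optional fourth-channel raster.
#' @param cfg a [train_config()] (the rank-loss fields are ignored).
#' @param class_weights `NULL` (uniform), `"inverse"` (inverse class
#'   frequency, normalized to mean 1) or a numeric vector of length C.
#' @return the trained `cls_model`.
#' @export
train_cls <- function(model, data, cfg = train_config(),
                      class_weights = NULL) {
  stopifnot(inherits(model, "cls_model"))
  if (length(data) == 0L) stop("cannot train on an empty dataset")
  C <- model$arch$n_classes
  labels <- vapply(data, function(it) {
    li <- if (is.factor(it$label)) as.integer(it$label) else as.integer(it$label)
    li
  }, integer(1))
  if (any(labels < 1L | labels > C)) stop("label index outside 1..", C)
  if (identical(class_weights, "inverse")) {
    # square-root damped inverse frequency: full inverse weighting makes the
    # rare grade dominate the loss outright on a near-one-sided set, which
    # can flip an undertrained classifier into predicting the rare class for
    # everything
    freq <- tabulate(labels, nbins = C)
    w <- ifelse(freq > 0, 1 / sqrt(freq), 0)
    class_weights <- w / mean(w[freq > 0])
  } else if (is.null(class_weights)) {
    class_weights <- rep(1, C)
  }
  stopifnot(length(class_weights) == C)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  xs <- lapply(data, function(it) {
    x <- image_pixels(it$image)
    if (!is.null(it$mask))
      x <- concat_ch(x, as_cube(matrix(as.numeric(it$mask), nrow(it$mask))))
    if (dim(x)[3] != model$arch$in_channels)
      stop(sprintf("model expects %d input channels, got %d",
                   model$arch$in_channels, dim(x)[3]))
    x
  })
  flat <- params_to_flat(model)
  mstate <- numeric(length(flat)); vstate <- numeric(length(flat))
  tstep <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(length(xs))
    for (i in ord) {
      x <- xs[[i]]
      if (cfg$augment) {
        # flips/shifts apply to all channels jointly, mask channel included
        a <- augment_sample(x, shift_max = cfg$shift_max)
        x <- a$x
      }
      tstep <- tstep + 1L
      cls_train_step_flat(x, labels[i], class_weights[labels[i]],
                          flat, mstate, vstate, tstep,
                          model$arch$in_channels, model$arch$channels[1],
                          model$arch$n_classes, cfg$learning_rate)
    }
  }
  flat_to_params(model, flat)
}

#' Save / load model weights
#'
#' Weights are serialized with `saveRDS`; a JSON sidecar records the
#' architecture configuration so saved models are self-describing.
#'
#' @param model a `seg_model` or `cls_model`.
#' @param path output `.rds` path (the sidecar is `<path>.json`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model$arch, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
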