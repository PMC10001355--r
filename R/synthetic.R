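# Seeded generator of dermoscopy-like images with exact ground truth.
#
# Each sample is a lesion blob on a skin-toned background. The disease class
# is encoded in the lesion's boundary geometry and internal texture, mirroring
# the clinical contrast the framework exploits: nevi are near-circular with
# smooth margins, melanomas have strongly irregular asymmetric margins, and
# seborrheic keratoses have moderately irregular margins with internal
# speckle texture. Hair strokes and bright bubble rings are overlaid as
# distractors that deliberately cross lesions, and per-sample lesion/skin
# contrast varies so that segmentation difficulty is heterogeneous across a
# pool. The mask is the exact support of the rendered lesion.

#' Generator configuration
#'
#' @param image_size side length in pixels (square images, >= 32; default 64).
#' @param class_proportions length-3 probability vector over
#'   [disease_levels]; must sum to 1.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param contrast_range range of the per-sample lesion/skin contrast factor;
#'   low values yield faint, hard-to-segment lesions.
#' @param hair_max,bubble_max maximum number of hair strokes / bubble rings
#'   per image (counts are drawn uniformly from 0..max).
#' @param seed integer seed consumed by [generate_splits()] and
#'   [generate_dataset()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(image_size = 64L,
                             class_proportions = c(1, 1, 1) / 3,
                             noise_sd = 0.03,
                             contrast_range = c(0.25, 1),
                             hair_max = 4L, bubble_max = 2L,
                             seed = 1L) {
  stopifnot(image_size >= 32L, image_size %% 8 == 0,
            length(class_proportions) == 3L,
            abs(sum(class_proportions) - 1) < 1e-9,
            noise_sd >= 0, hair_max >= 0L, bubble_max >= 0L,
            length(contrast_range) == 2L, contrast_range[1] <= contrast_range[2])
  structure(list(image_size = as.integer(image_size),
                 class_proportions = class_proportions,
                 noise_sd = noise_sd, contrast_range = contrast_range,
                 hair_max = as.integer(hair_max),
                 bubble_max = as.integer(bubble_max),
                 seed = as.integer(seed)),
            class = "generator_config")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Per-class boundary-irregularity amplitude (fraction of the base radius) and
# internal texture contrast. These ranges define the class geometry contract
# that shape_rule_classifier() and the mask-assisted classifier rely on.
lesion_class_params <- function(disease) {
  switch(disease,
    melanoma = list(irr = runif(1, 0.25, 0.50), tex = runif(1, 0.10, 0.30),
                    modes = c(sample(2:3, 1L), sample(4:7, 2L))),
    nevus = list(irr = runif(1, 0.00, 0.05), tex = runif(1, 0.00, 0.10),
                 modes = sample(3:7, 3L)),
    seborrheic_keratosis = list(irr = runif(1, 0.10, 0.20),
                                tex = runif(1, 0.40, 0.80),
                                modes = sample(3:7, 3L)))
}

draw_lesion_spec <- function(cfg) {
  S <- cfg$image_size
  disease <- sample(disease_levels, 1L, prob = cfg$class_proportions)
  cls <- lesion_class_params(disease)
  skin_tone <- clamp01(c(0.87, 0.71, 0.59) + rnorm(3, 0, 0.02))
  contrast <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
  lesion_base <- clamp01(c(0.42, 0.28, 0.20) + rnorm(3, 0, 0.02))
  lesion_tone <- skin_tone + contrast * (lesion_base - skin_tone)
  center <- S / 2 + runif(2, -S / 8, S / 8)
  max_r <- min(center - 1, S - center) - 2
  base_radius <- min(runif(1, 0.16, 0.26) * S, max_r / (1 + cls$irr))
  nm <- length(cls$modes)
  amps <- runif(nm)
  amps <- amps / sum(amps) * cls$irr
  phases <- runif(nm, 0, 2 * pi)
  list(disease = disease, center = center, base_radius = base_radius,
       boundary_irregularity = cls$irr, texture_contrast = cls$tex,
       modes = cls$modes, amps = amps, phases = phases,
       lesion_tone = lesion_tone, skin_tone = skin_tone, contrast = contrast)
}

# smooth a matrix once with a 3x3 box filter (edge-replicated)
box3 <- function(m) {
  n <- nrow(m)
  sh <- function(dr, dc) {
    r <- pmin(pmax(seq_len(n) + dr, 1L), n)
    c <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
    m[r, c, drop = FALSE]
  }
  (sh(-1, -1) + sh(-1, 0) + sh(-1, 1) + sh(0, -1) + sh(0, 0) + sh(0, 1) +
     sh(1, -1) + sh(1, 0) + sh(1, 1)) / 9
}

render_lesion_mask <- function(spec, S) {
  rr <- matrix(seq_len(S), S, S) - spec$center[1]
  cc <- matrix(seq_len(S), S, S, byrow = TRUE) - spec$center[2]
  rad <- sqrt(rr^2 + cc^2)
  theta <- atan2(cc, rr)
  rho <- spec$base_radius
  pert <- 0
  for (i in seq_along(spec$modes))
    pert <- pert + spec$amps[i] * sin(spec$modes[i] * theta + spec$phases[i])
  rho <- spec$base_radius * (1 + pert)
  (rad <= rho) * 1L
}

quad_bezier <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

#' Generate one synthetic dermoscopy sample
#'
#' Draws a lesion specification and renders the image, its exact ground-truth
#' mask and the disease label from the current RNG state (seed it yourself,
#' or use [generate_dataset()] / [generate_splits()] which seed from the
#' config).
#'
#' @param cfg a [generator_config()].
#' @param id identifier for the generated image.
#' @return list with elements `image` ([lesion_image]), `mask`
#'   ([as_mask] raster), `label` ([disease_label]) and the internal `spec`.
#' @export
generate_sample <- function(cfg, id = "syn") {
  S <- cfg$image_size
  spec <- draw_lesion_spec(cfg)
  mask <- render_lesion_mask(spec, S)
  img <- array(0, c(S, S, 3))
  tex <- box3(matrix(runif(S * S, -1, 1), S, S)) * spec$texture_contrast * 0.45
  for (ch in 1:3) {
    plane <- matrix(spec$skin_tone[ch], S, S)
    lesion_vals <- spec$lesion_tone[ch] * (1 + tex)
    plane[mask == 1L] <- lesion_vals[mask == 1L]
    img[, , ch] <- plane
  }
  n_hairs <- sample(0:cfg$hair_max, 1L)
  hair_tone <- c(0.10, 0.08, 0.06)
  for (h in seq_len(n_hairs)) {
    edge_pt <- function() {
      side <- sample(1:4, 1L)
      switch(side, c(1, runif(1, 1, S)), c(S, runif(1, 1, S)),
             c(runif(1, 1, S), 1), c(runif(1, 1, S), S))
    }
    pts <- quad_bezier(edge_pt(), c(runif(1, 1, S), runif(1, 1, S)),
                       edge_pt(), 4L * S)
    shade <- runif(1, 0.7, 1)
    idx <- unique(pmin(pmax(round(pts), 1L), S))
    idx <- rbind(idx, cbind(pmin(idx[, 1] + 1L, S), idx[, 2]))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- 0.15 * plane[idx] + 0.85 * hair_tone[ch] * shade
      img[, , ch] <- plane
    }
  }
  n_bub <- sample(0:cfg$bubble_max, 1L)
  for (bz in seq_len(n_bub)) {
    bc <- runif(2, 5, S - 4)
    br <- runif(1, 3, 7)
    bb <- runif(1, 0.2, 0.4)
    rr <- matrix(seq_len(S), S, S) - bc[1]
    cc <- matrix(seq_len(S), S, S, byrow = TRUE) - bc[2]
    ring <- abs(sqrt(rr^2 + cc^2) - br) <= 0.8
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[ring] <- plane[ring] + bb * (1 - plane[ring])
      img[, , ch] <- plane
    }
  }
  if (cfg$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, cfg$noise_sd), dim(img))
  img <- clamp01(img)
  list(image = lesion_image(img, id), mask = as_mask(mask),
       label = disease_label(spec$disease), spec = spec)
}

#' Generate a seeded dataset of synthetic samples
#'
#' @param cfg a [generator_config()]; `cfg$seed` seeds the sequence.
#' @param n number of samples.
#' @param id_prefix prefix for sample identifiers.
#' @return list of samples as returned by [generate_sample()].
#' @export
generate_dataset <- function(cfg, n, id_prefix = "syn") {
  set.seed(cfg$seed)
  lapply(seq_len(n), function(i)
    generate_sample(cfg, sprintf("%s%04d", id_prefix, i)))
}

#' Generate disjoint training/evaluation splits
#'
#' Emulates the data regime of the reference setting: a pixel-level labeled
#' set, an image-level labeled set, an unlabeled pool, and a held-out test
#' set carrying both masks and disease labels. Splits are disjoint by sample
#' id. The unlabeled pool keeps its hidden ground truth as an attribute for
#' evaluation only (never consumed by training code).
#'
#' @param cfg a [generator_config()].
#' @param n_pixel_labeled,n_image_labeled,n_unlabeled,n_test split sizes
#'   (each >= 0; empty pixel/image-labeled splits are returned as `NULL`).
#' @param n_val size of an optional pixel-labeled validation split used to
#'   monitor training convergence.
#' @return list with elements `dlp` ([pixel_labeled_set]), `dli`
#'   ([image_labeled_set]), `du` ([unlabeled_set] with attribute `hidden`),
#'   `test` (list of full samples) and `val` (list of `(image, mask)`
#'   pairs; empty when `n_val = 0`).
#' @export
generate_splits <- function(cfg, n_pixel_labeled, n_image_labeled,
                            n_unlabeled, n_test, n_val = 0L) {
  total <- n_pixel_labeled + n_image_labeled + n_unlabeled + n_test + n_val
  samples <- generate_dataset(cfg, total)
  take <- function(k) {
    if (k == 0L) return(list())
    out <- samples[seq_len(k)]
    samples <<- samples[-seq_len(k)]
    out
  }
  sp <- take(n_pixel_labeled)
  si <- take(n_image_labeled)
  su <- take(n_unlabeled)
  st <- take(n_test)
  sv <- take(n_val)
  dlp <- if (length(sp))
    pixel_labeled_set(lapply(sp, function(s) list(image = s$image, mask = s$mask)))
  dli <- if (length(si))
    image_labeled_set(lapply(si, function(s) list(image = s$image, label = s$label)))
  du <- unlabeled_set(lapply(su, function(s) s$image))
  attr(du, "hidden") <- list(
    masks = lapply(su, function(s) s$mask),
    labels = lapply(su, function(s) s$label))
  list(dlp = dlp, dli = dli, du = du, test = st,
       val = lapply(sv, function(s) list(image = s$image, mask = s$mask)))
}

#' Rule-based disease call from a lesion mask
#'
#' Deterministic shape rule on boundary-irregularity statistics, used as an
#' oracle in tests: the boundary radius is profiled in angular bins around
#' the mask centroid and its coefficient of variation is thresholded. Cut
#' points (`nevus_max`, `melanoma_min`) were calibrated once on noiseless
#' generator output so the rule recovers the generating class from the mask
#' alone.
#'
#' @param m non-empty binary mask.
#' @param cuts named vector with the two cut points on the radial
#'   coefficient of variation.
#' @return a [disease_label()].
#' @export
shape_rule_classifier <- function(m,
                                  cuts = c(nevus_max = 0.0395,
                                           melanoma_min = 0.110)) {
  if (sum(m == 1L) == 0L) stop("shape rule undefined for an empty mask")
  idx <- which(m == 1L, arr.ind = TRUE)
  ctr <- colMeans(idx)
  dr <- idx[, 1] - ctr[1]
  dc <- idx[, 2] - ctr[2]
  rad <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)
  bins <- cut(theta, breaks = seq(-pi, pi, length.out = 25L),
              include.lowest = TRUE)
  prof <- tapply(rad, bins, max)
  prof <- prof[!is.na(prof)]
  cv <- sd(prof) / mean(prof)
  disease_label(
    if (cv < cuts[["nevus_max"]]) "nevus"
    else if (cv >= cuts[["melanoma_min"]]) "melanoma"
    else "seborrheic_keratosis")
}
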