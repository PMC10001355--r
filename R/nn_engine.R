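# Low-level trainable network engine.
#
# Rasters are H x W x C arrays (row, col, channel). Convolution weights are
# (k*k*cin) x cout matrices whose patch-column ordering (channel-major, then
# kernel column, then kernel row) matches the compiled im2col kernels. All
# training is per-image stochastic gradient descent with Adam, single-threaded
# and fully determined by the R RNG state.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

glorot_conv <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin + k * k * cout))
  matrix(runif(k * k * cin * cout, -lim, lim), k * k * cin, cout)
}

glorot_fc <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(runif(fin * fout, -lim, lim), fout, fin)
}

concat_ch <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

as_cube <- function(m) {
  if (length(dim(m)) == 2L) array(m, c(dim(m), 1L)) else m
}

#' Bilinear resampling of a 2-D map
#'
#' Thin wrapper around [EBImage::resize()] used to move class-activation maps
#' between image resolution and the encoder's feature-grid resolution.
#'
#' @param m numeric matrix.
#' @param out_h,out_w target dimensions.
#' @return numeric matrix of size `out_h` x `out_w`.
#' @keywords internal
resize_map <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  r <- EBImage::resize(EBImage::Image(m), w = out_h, h = out_w,
                       filter = "bilinear")
  matrix(EBImage::imageData(r), out_h, out_w)
}

# ---------------------------------------------------------------------------
# Architectures

#' Construct a segmentation network
#'
#' A three-level encoder-decoder with skip connections and a single-channel
#' sigmoid prediction head. When `fusion = TRUE` the model carries a fusion
#' port after the encoder bottleneck: the bottleneck features are concatenated
#' with a localization prior (a class-activation map resampled to the feature
#' grid), passed through a 3x3 convolution with per-channel normalization and
#' ReLU, and only then decoded.
#'
#' @param in_channels input channels (3 for RGB dermoscopy images).
#' @param base_channels width of the first encoder level; deeper levels double
#'   and quadruple it. The desk-scale default (8) gives a ~25k-parameter model.
#' @param fusion whether to include the prior-fusion port.
#' @return an object of class `seg_model`.
#' @export
seg_model <- function(in_channels = 3L, base_channels = 8L, fusion = FALSE) {
  c1 <- base_channels; c2 <- 2L * base_channels; c3 <- 4L * base_channels
  p <- list(
    conv1_w = glorot_conv(3, in_channels, c1), conv1_b = numeric(c1),
    conv2_w = glorot_conv(3, c1, c2),          conv2_b = numeric(c2),
    conv3_w = glorot_conv(3, c2, c3),          conv3_b = numeric(c3),
    conv4_w = glorot_conv(3, c3 + c2, c2),     conv4_b = numeric(c2),
    conv5_w = glorot_conv(3, c2 + c1, c1),     conv5_b = numeric(c1),
    head_w  = glorot_conv(3, c1, 1),           head_b  = numeric(1)
  )
  if (fusion) {
    p$fus_w     <- glorot_conv(3, c3 + 1L, c3)
    p$fus_b     <- numeric(c3)
    p$fus_gamma <- rep(1, c3)
    p$fus_beta  <- numeric(c3)
  }
  structure(list(arch = list(type = "seg", in_channels = in_channels,
                             channels = c(c1, c2, c3), fusion = fusion),
                 params = p),
            class = "seg_model")
}

#' Construct a classification network
#'
#' A four-block strided convolutional feature extractor followed by global
#' average pooling, a randomly initialized fully connected layer of
#' `n_classes` neurons and a softmax. The last convolutional feature maps and
#' the output-layer class weights are exposed by [cls_forward()] so that class
#' activation maps can be computed. `in_channels = 4` accepts an RGB image
#' with a lesion mask concatenated as the fourth channel.
#'
#' @param in_channels 3 (image only) or 4 (image plus mask channel).
#' @param n_classes 2 for the pseudo-label quality role, 3 for the disease
#'   role (melanoma, nevus, seborrheic keratosis).
#' @param base_channels width of the first block; the desk-scale default (8)
#'   gives a ~15k-parameter model.
#' @return an object of class `cls_model`.
#' @export
cls_model <- function(in_channels = 3L, n_classes = 3L, base_channels = 8L) {
  stopifnot(in_channels %in% c(3L, 4L), n_classes >= 2L)
  c1 <- base_channels; c2 <- 2L * base_channels; c3 <- 4L * base_channels
  p <- list(
    conv1_w = glorot_conv(3, in_channels, c1), conv1_b = numeric(c1),
    conv2_w = glorot_conv(3, c1, c2),          conv2_b = numeric(c2),
    conv3_w = glorot_conv(3, c2, c3),          conv3_b = numeric(c3),
    conv4_w = glorot_conv(3, c3, c3),          conv4_b = numeric(c3),
    fc_w    = glorot_fc(c3, n_classes),        fc_b    = numeric(n_classes)
  )
  structure(list(arch = list(type = "cls", in_channels = in_channels,
                             n_classes = n_classes, channels = c(c1, c2, c3)),
                 params = p),
            class = "cls_model")
}

# ---------------------------------------------------------------------------
# Segmentation forward / backward

norm_eps <- 1e-5

spatial_norm_fwd <- function(x, gamma, beta) {
  C <- dim(x)[3]
  xhat <- x
  mu <- numeric(C); sdv <- numeric(C)
  for (c in seq_len(C)) {
    v <- x[, , c]
    mu[c] <- mean(v)
    sdv[c] <- sqrt(mean((v - mu[c])^2) + norm_eps)
    xhat[, , c] <- (v - mu[c]) / sdv[c]
  }
  y <- xhat
  for (c in seq_len(C)) y[, , c] <- gamma[c] * xhat[, , c] + beta[c]
  list(y = y, xhat = xhat, sdv = sdv)
}

spatial_norm_bwd <- function(cache, gamma, dy) {
  C <- dim(dy)[3]
  dx <- dy
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    g <- dy[, , c]; xh <- cache$xhat[, , c]
    dgamma[c] <- sum(g * xh)
    dbeta[c] <- sum(g)
    dxhat <- g * gamma[c]
    dx[, , c] <- (dxhat - mean(dxhat) - xh * mean(dxhat * xh)) / cache$sdv[c]
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

seg_fwd <- function(model, x, cam = NULL, want_cache = FALSE) {
  p <- model$params
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H %% 4 != 0 || W %% 4 != 0)
    stop("segmentation input dims must be divisible by 4")
  e1 <- relu(conv2d_fwd(x, p$conv1_w, p$conv1_b, 3L, 1L, 1L))
  p1 <- avgpool2_fwd(e1)
  e2 <- relu(conv2d_fwd(p1, p$conv2_w, p$conv2_b, 3L, 1L, 1L))
  p2 <- avgpool2_fwd(e2)
  b <- relu(conv2d_fwd(p2, p$conv3_w, p$conv3_b, 3L, 1L, 1L))
  if (model$arch$fusion) {
    camg <- if (is.null(cam)) matrix(0, H / 4, W / 4) else
      resize_map(cam, H / 4, W / 4)
    zcat <- concat_ch(b, as_cube(camg))
    fpre <- conv2d_fwd(zcat, p$fus_w, p$fus_b, 3L, 1L, 1L)
    nrmc <- spatial_norm_fwd(fpre, p$fus_gamma, p$fus_beta)
    f <- relu(nrmc$y)
  } else {
    if (!is.null(cam))
      stop("localization prior supplied to a model without a fusion port")
    zcat <- NULL; nrmc <- NULL; f <- b
  }
  u2 <- upsample2_fwd(f)
  c2cat <- concat_ch(u2, e2)
  d2 <- relu(conv2d_fwd(c2cat, p$conv4_w, p$conv4_b, 3L, 1L, 1L))
  u1 <- upsample2_fwd(d2)
  c1cat <- concat_ch(u1, e1)
  d1 <- relu(conv2d_fwd(c1cat, p$conv5_w, p$conv5_b, 3L, 1L, 1L))
  z <- conv2d_fwd(d1, p$head_w, p$head_b, 3L, 1L, 1L)
  s <- sigmoid(z[, , 1])
  if (!want_cache) return(s)
  list(s = s, cache = list(x = x, e1 = e1, p1 = p1, e2 = e2, p2 = p2, b = b,
                           zcat = zcat, nrmc = nrmc, f = f, c2cat = c2cat,
                           d2 = d2, c1cat = c1cat, d1 = d1))
}

# dz: gradient of the loss w.r.t. the pre-sigmoid logit map (H x W).
seg_bwd <- function(model, cache, dz) {
  p <- model$params
  ch <- model$arch$channels
  g <- list()
  bw <- conv2d_bwd(cache$d1, p$head_w, as_cube(dz), 3L, 1L, 1L)
  g$head_w <- bw$dw; g$head_b <- bw$db
  dd1 <- bw$dx * (cache$d1 > 0)
  bw <- conv2d_bwd(cache$c1cat, p$conv5_w, dd1, 3L, 1L, 1L)
  g$conv5_w <- bw$dw; g$conv5_b <- bw$db
  n_u1 <- ch[2]
  du1 <- bw$dx[, , seq_len(n_u1), drop = FALSE]
  de1 <- bw$dx[, , n_u1 + seq_len(ch[1]), drop = FALSE]
  dd2 <- upsample2_bwd(du1) * (cache$d2 > 0)
  bw <- conv2d_bwd(cache$c2cat, p$conv4_w, dd2, 3L, 1L, 1L)
  g$conv4_w <- bw$dw; g$conv4_b <- bw$db
  du2 <- bw$dx[, , seq_len(ch[3]), drop = FALSE]
  de2 <- bw$dx[, , ch[3] + seq_len(ch[2]), drop = FALSE]
  df <- upsample2_bwd(du2)
  if (model$arch$fusion) {
    dfn <- df * (cache$f > 0)
    nb <- spatial_norm_bwd(cache$nrmc, p$fus_gamma, dfn)
    g$fus_gamma <- nb$dgamma; g$fus_beta <- nb$dbeta
    bw <- conv2d_bwd(cache$zcat, p$fus_w, nb$dx, 3L, 1L, 1L)
    g$fus_w <- bw$dw; g$fus_b <- bw$db
    db_ <- bw$dx[, , seq_len(ch[3]), drop = FALSE]
  } else {
    db_ <- df
  }
  db_ <- db_ * (cache$b > 0)
  bw <- conv2d_bwd(cache$p2, p$conv3_w, db_, 3L, 1L, 1L)
  g$conv3_w <- bw$dw; g$conv3_b <- bw$db
  de2 <- (de2 + avgpool2_bwd(bw$dx)) * (cache$e2 > 0)
  bw <- conv2d_bwd(cache$p1, p$conv2_w, de2, 3L, 1L, 1L)
  g$conv2_w <- bw$dw; g$conv2_b <- bw$db
  de1 <- (de1 + avgpool2_bwd(bw$dx)) * (cache$e1 > 0)
  bw <- conv2d_bwd(cache$x, p$conv1_w, de1, 3L, 1L, 1L)
  g$conv1_w <- bw$dw; g$conv1_b <- bw$db
  g
}

# ---------------------------------------------------------------------------
# Classification forward / backward

cls_fwd <- function(model, x, want_cache = FALSE) {
  p <- model$params
  if (dim(x)[1] %% 8 != 0 || dim(x)[2] %% 8 != 0)
    stop("classification input dims must be divisible by 8")
  if (dim(x)[3] != model$arch$in_channels)
    stop(sprintf("model expects %d input channels, got %d",
                 model$arch$in_channels, dim(x)[3]))
  h1 <- relu(conv2d_fwd(x, p$conv1_w, p$conv1_b, 3L, 2L, 1L))
  h2 <- relu(conv2d_fwd(h1, p$conv2_w, p$conv2_b, 3L, 2L, 1L))
  h3 <- relu(conv2d_fwd(h2, p$conv3_w, p$conv3_b, 3L, 2L, 1L))
  h4 <- relu(conv2d_fwd(h3, p$conv4_w, p$conv4_b, 3L, 1L, 1L))
  gvec <- apply(h4, 3, mean)
  logits <- drop(p$fc_w %*% gvec) + p$fc_b
  probs <- softmax_vec(logits)
  if (!want_cache) return(list(probs = probs, fmap = h4, weights = p$fc_w))
  list(probs = probs, fmap = h4, weights = p$fc_w,
       cache = list(x = x, h1 = h1, h2 = h2, h3 = h3, h4 = h4, gvec = gvec))
}

cls_bwd <- function(model, cache, dlogits) {
  p <- model$params
  g <- list()
  g$fc_w <- outer(dlogits, cache$gvec)
  g$fc_b <- dlogits
  dg <- drop(t(p$fc_w) %*% dlogits)
  hw <- dim(cache$h4)[1] * dim(cache$h4)[2]
  dh4 <- array(rep(dg / hw, each = hw), dim(cache$h4)) * (cache$h4 > 0)
  bw <- conv2d_bwd(cache$h3, p$conv4_w, dh4, 3L, 1L, 1L)
  g$conv4_w <- bw$dw; g$conv4_b <- bw$db
  dh3 <- bw$dx * (cache$h3 > 0)
  bw <- conv2d_bwd(cache$h2, p$conv3_w, dh3, 3L, 2L, 1L)
  g$conv3_w <- bw$dw; g$conv3_b <- bw$db
  dh2 <- bw$dx * (cache$h2 > 0)
  bw <- conv2d_bwd(cache$h1, p$conv2_w, dh2, 3L, 2L, 1L)
  g$conv2_w <- bw$dw; g$conv2_b <- bw$db
  dh1 <- bw$dx * (cache$h1 > 0)
  bw <- conv2d_bwd(cache$x, p$conv1_w, dh1, 3L, 2L, 1L)
  g$conv1_w <- bw$dw; g$conv1_b <- bw$db
  g
}

# ---------------------------------------------------------------------------
# Flat parameter layout (training-loop internals)
#
# The compiled training steps operate on one flat double vector per model,
# laid out in the construction order of the params list (arrays flattened
# column-major), with Adam state held in two parallel vectors mutated in
# place.

params_to_flat <- function(model) as.double(unlist(model$params,
                                                   use.names = FALSE))

flat_to_params <- function(model, flat) {
  off <- 0L
  for (nm in names(model$params)) {
    n <- length(model$params[[nm]])
    model$params[[nm]][] <- flat[off + seq_len(n)]
    off <- off + n
  }
  model
}

# ---------------------------------------------------------------------------
# Adam

adam_init <- function(model) {
  st <- lapply(model$params, function(p) list(m = p * 0, v = p * 0))
  list(state = st, t = 0L)
}

adam_step <- function(model, opt, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  b1t <- 1 - beta1^opt$t
  b2t <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    s <- opt$state[[nm]]
    s$m <- beta1 * s$m + (1 - beta1) * gmat
    s$v <- beta2 * s$v + (1 - beta2) * gmat * gmat
    model$params[[nm]] <- model$params[[nm]] -
      lr * (s$m / b1t) / (sqrt(s$v / b2t) + eps)
    opt$state[[nm]] <- s
  }
  list(model = model, opt = opt)
}

# ---------------------------------------------------------------------------
# Losses

bce_loss <- function(s, y) {
  sc <- pmin(pmax(s, 1e-7), 1 - 1e-7)
  -mean(y * log(sc) + (1 - y) * log(1 - sc))
}

# Hinge penalty on the hardest foreground/background pixel pairs, with its
# gradient w.r.t. the sigmoid scores. Returns loss 0 with zero gradient when
# the mask lacks one of the two classes.
rank_loss_grad <- function(s, y, top_k, margin) {
  ds <- s * 0
  fg <- which(y == 1)
  bg <- which(y == 0)
  if (length(fg) == 0L || length(bg) == 0L) return(list(loss = 0, ds = ds))
  kk <- min(top_k, length(fg), length(bg))
  fg_hard <- fg[order(s[fg])[seq_len(kk)]]
  bg_hard <- bg[order(s[bg], decreasing = TRUE)[seq_len(kk)]]
  gaps <- margin - (s[fg_hard] - s[bg_hard])
  act <- gaps > 0
  loss <- sum(pmax(gaps, 0)) / kk
  if (any(act)) {
    ds[fg_hard[act]] <- ds[fg_hard[act]] - 1 / kk
    ds[bg_hard[act]] <- ds[bg_hard[act]] + 1 / kk
  }
  list(loss = loss, ds = ds)
}
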