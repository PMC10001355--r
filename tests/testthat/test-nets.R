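# The training engine: analytic gradients, the fused compiled step against
# the composed reference path, forward contracts, rank loss, and small
# training smoke tests.

num_grad <- function(fn, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

test_that("segmentation backprop matches numerical gradients", {
  set.seed(2)
  m <- seg_model(base_channels = 2, fusion = TRUE)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  y <- matrix(rbinom(64, 1, 0.4), 8, 8)
  cam <- kronecker(matrix(runif(4), 2), matrix(1, 4, 4))
  loss_of <- function(model) {
    s <- pseudoseg:::seg_fwd(model, x, cam = cam)
    pseudoseg:::bce_loss(s, y)
  }
  fc <- pseudoseg:::seg_fwd(m, x, cam = cam, want_cache = TRUE)
  gr <- pseudoseg:::seg_bwd(m, fc$cache, (fc$s - y) / 64)
  for (nm in c("conv1_w", "conv3_b", "fus_w", "fus_gamma", "conv5_w",
               "head_w")) {
    f <- function(v) { mm <- m; mm$params[[nm]][] <- v; loss_of(mm) }
    expect_equal(as.numeric(gr[[nm]]),
                 num_grad(f, as.numeric(m$params[[nm]])),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("classification backprop matches numerical gradients", {
  set.seed(3)
  cm <- cls_model(in_channels = 4, n_classes = 3, base_channels = 2)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  loss_of <- function(model) {
    r <- pseudoseg:::cls_fwd(model, x)
    -log(r$probs[2])
  }
  r <- pseudoseg:::cls_fwd(cm, x, want_cache = TRUE)
  dl <- r$probs; dl[2] <- dl[2] - 1
  gr <- pseudoseg:::cls_bwd(cm, r$cache, dl)
  for (nm in c("conv1_w", "conv2_b", "conv4_w", "fc_w", "fc_b")) {
    f <- function(v) { mm <- cm; mm$params[[nm]][] <- v; loss_of(mm) }
    expect_equal(as.numeric(gr[[nm]]),
                 num_grad(f, as.numeric(cm$params[[nm]])),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("fused compiled step reproduces the composed reference path", {
  set.seed(5)
  m <- seg_model(base_channels = 4, fusion = TRUE)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  y <- matrix(rbinom(1024, 1, 0.3), 32, 32)
  cam <- matrix(runif(1024), 32, 32)
  camg <- pseudoseg:::resize_map(cam, 8, 8)
  sc <- pseudoseg:::seg_step_c(x, y, m$params, TRUE, camg, 0.1, 30L, 0.3)
  fc <- pseudoseg:::seg_fwd(m, x, cam = cam, want_cache = TRUE)
  rl <- pseudoseg:::rank_loss_grad(fc$s, y, 30, 0.3)
  dz <- (fc$s - y) / 1024 + 0.1 * rl$ds * fc$s * (1 - fc$s)
  gr <- pseudoseg:::seg_bwd(m, fc$cache, dz)
  expect_equal(sc$s, fc$s, tolerance = 1e-12)
  expect_equal(sc$loss, pseudoseg:::bce_loss(fc$s, y) + 0.1 * rl$loss,
               tolerance = 1e-12)
  for (nm in names(gr))
    expect_equal(as.numeric(sc$grads[[nm]]), as.numeric(gr[[nm]]),
                 tolerance = 1e-10)
  cm <- cls_model(in_channels = 4, n_classes = 2, base_channels = 4)
  xc <- array(runif(32 * 32 * 4), c(32, 32, 4))
  scc <- pseudoseg:::cls_step_c(xc, 2L, 1.7, cm$params)
  rc <- pseudoseg:::cls_fwd(cm, xc, want_cache = TRUE)
  dl <- rc$probs; dl[2] <- dl[2] - 1
  gc2 <- pseudoseg:::cls_bwd(cm, rc$cache, 1.7 * dl)
  expect_equal(drop(scc$probs), rc$probs, tolerance = 1e-12)
  for (nm in names(gc2))
    expect_equal(as.numeric(scc$grads[[nm]]), as.numeric(gc2[[nm]]),
                 tolerance = 1e-10)
})

test_that("the in-place flat training step equals the list-based step plus
           a separate Adam update", {
  set.seed(6)
  m <- seg_model(base_channels = 4, fusion = TRUE)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  y <- matrix(rbinom(1024, 1, 0.3), 32, 32)
  camg <- matrix(runif(64), 8, 8)
  # reference: fused list step then Adam
  sc <- pseudoseg:::seg_step_c(x, y, m$params, TRUE, camg, 0.1, 30L, 0.3)
  ref <- pseudoseg:::adam_step(m, pseudoseg:::adam_init(m), sc$grads, 1e-3)
  # flat in-place step
  flat <- pseudoseg:::params_to_flat(m)
  ms <- numeric(length(flat)); vs <- numeric(length(flat))
  loss <- pseudoseg:::seg_train_step_flat(x, y, flat, ms, vs, 1L, 3L, 4L,
                                          TRUE, camg, 1e-3, 0.1, 30L, 0.3)
  got <- pseudoseg:::flat_to_params(m, flat)
  expect_equal(loss, sc$loss, tolerance = 1e-12)
  for (nm in names(m$params))
    expect_equal(as.numeric(got$params[[nm]]),
                 as.numeric(ref$model$params[[nm]]), tolerance = 1e-12)
  cm <- cls_model(in_channels = 4, n_classes = 3, base_channels = 4)
  xc <- array(runif(32 * 32 * 4), c(32, 32, 4))
  scc <- pseudoseg:::cls_step_c(xc, 3L, 1.2, cm$params)
  refc <- pseudoseg:::adam_step(cm, pseudoseg:::adam_init(cm), scc$grads, 2e-3)
  flatc <- pseudoseg:::params_to_flat(cm)
  msc <- numeric(length(flatc)); vsc <- numeric(length(flatc))
  lc <- pseudoseg:::cls_train_step_flat(xc, 3L, 1.2, flatc, msc, vsc, 1L,
                                        4L, 4L, 3L, 2e-3)
  gotc <- pseudoseg:::flat_to_params(cm, flatc)
  expect_equal(lc, scc$loss, tolerance = 1e-12)
  for (nm in names(cm$params))
    expect_equal(as.numeric(gotc$params[[nm]]),
                 as.numeric(refc$model$params[[nm]]), tolerance = 1e-12)
})

test_that("segmentation forward is shape-preserving, bounded, deterministic", {
  set.seed(7)
  m <- seg_model()
  img <- generate_sample(tiny_gen(7))$image
  s1 <- seg_forward(m, img)
  s2 <- seg_forward(m, img)
  expect_equal(dim(s1), dim(img$pixels)[1:2])
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_identical(s1, s2)
  expect_error(seg_forward(m, img, prior = matrix(0, 32, 32)), "fusion port")
})

test_that("an all-zero prior equals an absent prior, and a fusion layer that
           ignores its prior channel is prior-invariant", {
  set.seed(8)
  mf <- seg_model(fusion = TRUE)
  img <- generate_sample(tiny_gen(8))$image
  expect_equal(seg_forward(mf, img, prior = matrix(0, 32, 32)),
               seg_forward(mf, img, prior = NULL), tolerance = 1e-12)
  # zero the fusion weights that read the prior channel (last input channel)
  c3 <- mf$arch$channels[3]
  prior_rows <- c3 * 9 + 1:9
  mf$params$fus_w[prior_rows, ] <- 0
  expect_equal(seg_forward(mf, img, prior = matrix(runif(1024), 32, 32)),
               seg_forward(mf, img, prior = NULL), tolerance = 1e-12)
})

test_that("classifier forward yields normalized probabilities at C = 2 and 3", {
  set.seed(9)
  img <- generate_sample(tiny_gen(9))$image
  msk <- matrix(0, 32, 32); msk[10:20, 10:20] <- 1
  m2 <- cls_model(in_channels = 4, n_classes = 2)
  r2 <- cls_forward(m2, img, mask_channel = msk)
  expect_length(r2$probs, 2)
  expect_equal(sum(r2$probs), 1, tolerance = 1e-6)
  m3 <- cls_model(in_channels = 3, n_classes = 3)
  r3 <- cls_forward(m3, img)
  expect_length(r3$probs, 3)
  expect_equal(sum(r3$probs), 1, tolerance = 1e-6)
  expect_equal(dim(r3$class_weights), c(3L, m3$arch$channels[3]))
  expect_error(cls_forward(m3, img, mask_channel = msk), "channels")
  expect_error(cls_forward(m2, img), "channels")
})

test_that("rank loss closed forms and selection invariance", {
  y <- matrix(c(rep(1, 8), rep(0, 8)), 4)
  expect_equal(rank_loss(matrix(as.numeric(y), 4), y, 30, 0.3), 0)
  expect_equal(rank_loss(matrix(0.5, 4, 4), y, 30, 0.3), 0.3)
  expect_equal(rank_loss(matrix(c(0.2, 0.6), 1), mk_mask(c(1, 0), 1),
                         30, 0.3), 0.7)
  expect_equal(rank_loss(matrix(0.5, 2, 2), mk_mask(rep(1, 4), 2)), 0)
  # pixels outside the selected top-k pairs do not affect the loss
  set.seed(11)
  s <- matrix(runif(64), 8)
  yy <- matrix(rbinom(64, 1, 0.5), 8)
  base <- rank_loss(s, yy, top_k = 3, margin = 0.3)
  fg <- which(yy == 1)
  easy_fg <- fg[order(s[fg], decreasing = TRUE)][1]  # easiest foreground
  s2 <- s; s2[easy_fg] <- min(1, s2[easy_fg] + 0.0001)
  expect_identical(rank_loss(s2, yy, top_k = 3, margin = 0.3), base)
  expect_gte(base, 0)
})

test_that("lambda = 0 reduces the training loss to binary cross-entropy", {
  set.seed(12)
  s <- matrix(runif(64), 8)
  y <- matrix(rbinom(64, 1, 0.5), 8)
  expect_identical(seg_loss(s, y, lambda = 0), pseudoseg:::bce_loss(s, y))
  expect_equal(seg_loss(s, y, lambda = 0.1),
               pseudoseg:::bce_loss(s, y) + 0.1 * rank_loss(s, y))
})

test_that("segmentation training learns the lesions and snapshots checkpoints", {
  cfg <- tiny_gen(14)
  sp <- generate_splits(cfg, 20, 0, 0, 0)
  set.seed(1)
  m <- seg_model()
  r <- train_seg(m, sp$dlp, train_config(learning_rate = 1e-3,
                                         max_epochs = 10, seed = 2),
                 checkpoint_epochs = default_checkpoint_epochs(10, 5))
  expect_length(r$checkpoints, 5)
  expect_equal(r$checkpoints$epochs, c(2L, 4L, 6L, 8L, 10L))
  ja <- mean(vapply(sp$dlp$items, function(it)
    jaccard(binarize(seg_forward(r$model, it$image)), it$mask), numeric(1)))
  expect_gt(ja, 0.8)
  expect_error(train_seg(m, list(), train_config()), "empty")
  expect_error(train_seg(m, sp$dlp, train_config(), cams = list(1)), "per training image")
})

test_that("training is reproducible bit for bit under a fixed seed", {
  cfg <- tiny_gen(15)
  sp <- generate_splits(cfg, 5, 0, 0, 0)
  run <- function() {
    set.seed(4)
    m <- seg_model(base_channels = 4)
    train_seg(m, sp$dlp, train_config(max_epochs = 2, seed = 6))$model
  }
  expect_identical(run()$params, run()$params)
  cdata <- lapply(sp$dlp$items, function(it)
    list(image = it$image, label = sample(1:3, 1)))
  run_cls <- function() {
    set.seed(4)
    m <- cls_model(in_channels = 3, n_classes = 3, base_channels = 4)
    train_cls(m, cdata, train_config(max_epochs = 2, seed = 6))
  }
  expect_identical(run_cls()$params, run_cls()$params)
})

test_that("classifier training reaches full accuracy on a separable fixture", {
  # bright-center images vs dark-center images
  set.seed(16)
  mkimg <- function(bright) {
    px <- array(runif(32 * 32 * 3, 0.4, 0.6), c(32, 32, 3))
    px[12:20, 12:20, ] <- if (bright) 0.95 else 0.05
    lesion_image(px, paste0("t", bright, runif(1)))
  }
  data <- c(lapply(1:10, function(i) list(image = mkimg(TRUE), label = 1L)),
            lapply(1:10, function(i) list(image = mkimg(FALSE), label = 2L)))
  set.seed(2)
  m <- cls_model(in_channels = 3, n_classes = 2)
  tm <- train_cls(m, data, train_config(learning_rate = 1e-3, max_epochs = 8,
                                        seed = 3))
  acc <- mean(vapply(data, function(it)
    which.max(cls_forward(tm, it$image)$probs) == it$label, logical(1)))
  expect_equal(acc, 1)
  expect_error(train_cls(m, list(), train_config()), "empty")
  expect_error(train_cls(m, list(list(image = data[[1]]$image, label = 5L)),
                         train_config()), "label index")
})

test_that("model weights save and load with a JSON sidecar", {
  set.seed(17)
  m <- seg_model(base_channels = 2)
  p <- withr::local_tempfile(fileext = ".rds")
  save_model(m, p)
  expect_identical(load_model(p)$params, m$params)
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$type, "seg")
})
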