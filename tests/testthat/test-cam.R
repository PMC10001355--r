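test_that("class activation maps match the explicit weighted-sum oracle", {
  set.seed(30)
  for (i in 1:8) {
    m <- cls_model(in_channels = 4, n_classes = 3, base_channels = 1)  # c = 4
    s <- generate_sample(tiny_gen(30 + i, size = 64L))
    r <- cls_forward(m, s$image, mask_channel = s$mask)
    cl <- sample(1:3, 1)
    # oracle: weight the 8x8 feature maps by the class weights, sum channels,
    # clip, upsample, min-max normalize (degenerate constant maps are covered
    # by a dedicated test below)
    fm <- r$feature_maps
    raw <- matrix(0, dim(fm)[1], dim(fm)[2])
    for (j in seq_len(dim(fm)[3]))
      raw <- raw + r$class_weights[cl, j] * fm[, , j]
    raw[raw < 0] <- 0
    up <- pseudoseg:::resize_map(raw, 64, 64)
    if (diff(range(up)) < 1e-12) next
    got <- compute_cam(m, s$image, mask_channel = s$mask, target_class = cl)
    expected <- (up - min(up)) / (max(up) - min(up))
    expect_equal(got$values, expected, tolerance = 1e-6)
    expect_identical(got$source_class, cl)
    expect_true(all(got$values >= 0 & got$values <= 1))
  }
})

test_that("degenerate activation maps collapse to zero with a warning", {
  set.seed(31)
  s <- generate_sample(tiny_gen(31, size = 64L))
  m <- cls_model(in_channels = 3, n_classes = 3, base_channels = 1)
  m$params$fc_w[] <- 0  # zero class weights -> constant raw map
  expect_warning(cam <- compute_cam(m, s$image, target_class = 1), "degenerate")
  expect_true(all(cam$values == 0))
  # constant feature maps (zeroed extractor with constant head bias) likewise
  m2 <- cls_model(in_channels = 3, n_classes = 3, base_channels = 1)
  m2$params$conv4_w[] <- 0
  m2$params$conv4_b[] <- 1
  expect_warning(cam2 <- compute_cam(m2, s$image, target_class = 1),
                 "degenerate")
  expect_true(all(cam2$values == 0))
})

test_that("maps are invariant to positive rescaling of the class weights", {
  set.seed(32)
  s <- generate_sample(tiny_gen(32, size = 64L))
  m <- cls_model(in_channels = 3, n_classes = 3, base_channels = 2)
  a <- compute_cam(m, s$image, target_class = 2)
  m$params$fc_w <- 7.3 * m$params$fc_w
  b <- compute_cam(m, s$image, target_class = 2)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("batch CAM computation covers the union training set", {
  set.seed(33)
  cfg <- tiny_gen(33)
  sp <- generate_splits(cfg, 3, 0, 2, 0)
  m <- cls_model(in_channels = 4, n_classes = 3, base_channels = 2)
  pseudo <- pseudo_labeled_set(lapply(sp$du$items, function(im)
    list(image = im, mask = as_mask(matrix(rbinom(1024, 1, 0.2), 32)))))
  cams <- cam_batch_for_training(m, c(sp$dlp$items, pseudo$items))
  expect_length(cams, 5)
  expect_true(all(vapply(cams, inherits, logical(1), "cam_map")))
  cams2 <- cam_batch_for_training(m, c(sp$dlp$items, pseudo$items))
  expect_identical(cams, cams2)
  expect_length(cam_batch_for_training(m, list()), 0)
  expect_error(cam_batch_for_training(m, list(list(image = sp$du$items[[1]]))),
               "mask")
})

test_that("student training requires a fusion port and matched CAMs", {
  set.seed(34)
  cfg <- tiny_gen(34)
  sp <- generate_splits(cfg, 4, 0, 0, 0)
  plain <- seg_model(base_channels = 4)
  expect_error(train_student(plain, sp$dlp), "fusion port")
  stud <- seg_model(base_channels = 4, fusion = TRUE)
  expect_error(train_student(stud, sp$dlp, cams = list(matrix(0, 32, 32))),
               "one CAM per")
  cams <- lapply(sp$dlp$items, function(it) matrix(0.5, 32, 32))
  out <- train_student(stud, sp$dlp, NULL, cams,
                       train_config(max_epochs = 2, seed = 5))
  expect_s3_class(out, "seg_model")
})

test_that("two-pass inference produces a valid soft mask", {
  set.seed(35)
  s <- generate_sample(tiny_gen(35, size = 64L))
  teacher <- seg_model(base_channels = 4)
  student <- seg_model(base_channels = 4, fusion = TRUE)
  disease <- cls_model(in_channels = 4, n_classes = 3, base_channels = 2)
  soft <- two_pass_forward(student, s$image, teacher, disease)
  expect_equal(dim(soft), c(64L, 64L))
  expect_true(all(soft >= 0 & soft <= 1))
  expect_identical(soft, two_pass_forward(student, s$image, teacher, disease))
})
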