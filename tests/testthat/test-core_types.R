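test_that("binarize thresholds with >= and preserves shape", {
  soft <- matrix(c(0.5, 0.51, 0.49, 0.0), 2)
  expect_equal(unclass(binarize(soft, 0.5)), matrix(c(1L, 1L, 0L, 0L), 2))
  expect_equal(sum(binarize(matrix(0, 3, 4), 0.5)), 0L)
  expect_equal(sum(binarize(matrix(1, 3, 4), 0.5)), 12L)
  expect_equal(dim(binarize(soft)), dim(soft))
})

test_that("binarize rejects bad input", {
  expect_error(binarize(matrix(c(0.1, NaN), 1)), "non-finite")
  expect_error(binarize(matrix(0.5, 2, 2), 0), "threshold")
  expect_error(binarize(matrix(0.5, 2, 2), 1.5), "threshold")
  expect_error(binarize(matrix(2, 2, 2)), "0, 1")
})

test_that("binarize is idempotent on binary input and monotone in threshold", {
  set.seed(41)
  for (i in 1:20) {
    soft <- matrix(runif(64), 8)
    t1 <- runif(1, 0.05, 0.5)
    t2 <- runif(1, t1, 0.95)
    m1 <- binarize(soft, t1)
    m2 <- binarize(soft, t2)
    expect_true(all(m1 >= m2))  # lower threshold is a superset
    for (t in c(t1, t2, 1)) # idempotence incl. threshold 1
      expect_equal(unclass(binarize(matrix(as.numeric(m1), 8), t)),
                   unclass(m1))
  }
})

test_that("image and mask constructors enforce invariants", {
  px <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_s3_class(lesion_image(px, "a"), "lesion_image")
  expect_error(lesion_image(px * 2), "\\[0, 1\\]")
  expect_error(lesion_image(array(0.5, c(8, 24, 3))), "16")
  expect_error(lesion_image(px[, , 1:2]), "H x W x 3")
  expect_error(as_mask(matrix(c(0, 2), 1)), "0 or 1")
  expect_error(pixel_labeled_set(list(list(
    image = lesion_image(px), mask = as_mask(matrix(0L, 16, 16))))),
    "dimensions")
  expect_error(pixel_labeled_set(list()), "non-empty")
})

test_that("disease labels are one of the three categories", {
  expect_equal(levels(disease_label("nevus")), disease_levels)
  expect_error(disease_label("wart"), "one of")
  expect_error(disease_label(c("nevus", "melanoma")))
})

test_that("ISIC directory layout round-trips images, masks and labels", {
  cfg <- tiny_gen(3, noise_sd = 0.02, hair_max = 2L, bubble_max = 1L)
  samples <- generate_dataset(cfg, 4)
  dir <- withr::local_tempdir()
  write_isic_dir(lapply(samples, function(s)
    list(image = s$image, mask = s$mask, label = s$label)), dir)
  expect_true(file.exists(file.path(dir, "masks",
                                    paste0(samples[[1]]$image$id,
                                           "_segmentation.png"))))
  back <- read_isic_dir(dir)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_equal(back[[i]]$image$id, samples[[i]]$image$id)
    # PNG is 8-bit: intensities survive to within one quantization step
    expect_lt(max(abs(back[[i]]$image$pixels - samples[[i]]$image$pixels)),
              1 / 255)
    expect_equal(unclass(back[[i]]$mask), unclass(samples[[i]]$mask))
    expect_equal(as.character(back[[i]]$label),
                 as.character(samples[[i]]$label))
  }
  # nevus rows are encoded as melanoma = 0, seborrheic_keratosis = 0
  lab <- read.csv(file.path(dir, "labels.csv"))
  nev <- vapply(samples, function(s) s$label == "nevus", logical(1))
  expect_equal(lab$melanoma[nev] + lab$seborrheic_keratosis[nev],
               rep(0L, sum(nev)))
})
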