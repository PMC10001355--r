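test_that("jaccard and dice match hand-counted overlaps", {
  # |a| = 6, |b| = 4, overlap 3 on a 4x4 grid
  a <- mk_mask(c(1, 1, 1, 1, 1, 1, rep(0, 10)), 4)
  b <- mk_mask(c(1, 1, 1, 0, 0, 0, 1, rep(0, 9)), 4)
  expect_equal(jaccard(a, b), 3 / 7)
  expect_equal(dice(a, b), 6 / 10)
  expect_equal(dice(a, b), 2 * jaccard(a, b) / (1 + jaccard(a, b)))
  expect_equal(jaccard(a, a), 1)
  expect_equal(dice(a, a), 1)
  disj <- mk_mask(c(rep(0, 8), 1, 1, rep(0, 6)), 4)
  expect_equal(jaccard(b, disj), 0)
  expect_equal(dice(b, disj), 0)
  empty <- mk_mask(rep(0, 16), 4)
  expect_equal(jaccard(empty, empty), 1)
  expect_equal(dice(empty, empty), 1)
  expect_error(jaccard(a, mk_mask(rep(0, 4), 2)), "dimensions")
})

test_that("pixel confusion enumerates the four counts", {
  pred <- mk_mask(c(1, 0, 0, 0), 2)
  truth <- mk_mask(c(1, 0, 1, 0), 2)
  expect_equal(pixel_confusion(pred, truth),
               c(tp = 1L, fp = 0L, tn = 2L, fn = 1L))
  expect_equal(sum(pixel_confusion(pred, truth)), 4L)
  m <- seg_metrics(truth, truth)
  expect_equal(unname(m[c("pixel_ac", "pixel_se", "pixel_sp")]), c(1, 1, 1))
  comp <- as_mask(1L - unclass(truth))
  cf <- pixel_confusion(comp, truth)
  expect_equal(unname(cf[c("tp", "tn")]), c(0L, 0L))
})

test_that("jaccard/dice identity, symmetry and bounds hold on random masks", {
  set.seed(77)
  for (i in 1:300) {
    a <- as_mask(matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16))
    b <- as_mask(matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16))
    ja <- jaccard(a, b); di <- dice(a, b)
    expect_equal(di, 2 * ja / (1 + ja), tolerance = 1e-12)
    expect_identical(ja, jaccard(b, a))
    expect_true(ja >= 0 && ja <= 1 && di >= 0 && di <= 1)
  }
})

test_that("auc equals the Mann-Whitney pair count", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_error(auc(c(1, 2), c(1, 1)), "one class")
  set.seed(13)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    sc <- round(runif(n), 2)  # rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_equal(auc(sc, lb), auc_bruteforce(sc, lb))
    if (!any(duplicated(sc)))
      expect_equal(auc(sc, lb) + auc(sc, 1 - lb), 1)
  }
})

test_that("auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:10) {
    sc <- runif(40)
    lb <- rbinom(40, 1, 0.5)
    if (length(unique(lb)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("macro average is the fieldwise mean", {
  r1 <- c(ac = 0.9, se = 0.8, sp = 0.7, auc = 0.9)
  r2 <- c(ac = 0.7, se = 0.6, sp = 0.9, auc = 0.7)
  expect_equal(macro_average(list(r1)), r1)
  expect_equal(macro_average(list(r1, r2))[["auc"]], 0.8)
  expect_equal(macro_average(list(r1, r1, r1)), r1)
  expect_error(macro_average(list()), "empty")
})

test_that("classification report behaves at the extremes", {
  truth <- factor(rep(disease_levels, each = 10), levels = disease_levels)
  perfect <- t(vapply(as.integer(truth), function(i) {
    p <- c(0.01, 0.01, 0.01); p[i] <- 0.98; p
  }, numeric(3)))
  rp <- cls_report_from_probs(perfect, truth)
  expect_equal(rp[rp$class == "average", c("ac", "se", "sp", "auc")],
               data.frame(ac = 1, se = 1, sp = 1, auc = 1),
               ignore_attr = TRUE)
  flat <- matrix(1 / 3, 30, 3)
  rf <- cls_report_from_probs(flat, truth)
  expect_equal(rf$auc[rf$class == "average"], 0.5)  # all-tied scores
  expect_true(all(rf[, c("ac", "se", "sp", "auc")] >= 0 &
                    rf[, c("ac", "se", "sp", "auc")] <= 1))
  # averages are over the melanoma and seborrheic keratosis tasks
  expect_equal(rp$auc[rp$class == "average"],
               mean(rp$auc[rp$class %in% c("melanoma",
                                           "seborrheic_keratosis")]))
})
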