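test_that("grading applies the >= threshold rule including the boundary", {
  t <- quality_threshold(0.8)
  expect_identical(grade_pseudo_label(0.8, t), 1L)   # s == t is reliable
  expect_identical(grade_pseudo_label(0.7999999, t), 0L)
  expect_identical(grade_pseudo_label(0, t), 0L)
  expect_identical(grade_pseudo_label(1, quality_threshold(0.99)), 1L)
  expect_error(grade_pseudo_label(1.2, t), "\\[0, 1\\]")
  expect_error(quality_threshold(0), "t > 0")
  expect_error(quality_threshold(1))
})

test_that("quality dataset has exactly k * N graded entries", {
  cfg <- tiny_gen(20)
  sp <- generate_splits(cfg, 4, 0, 0, 0)
  set.seed(1)
  tr <- train_seg(seg_model(base_channels = 4), sp$dlp,
                  train_config(max_epochs = 5, seed = 2),
                  checkpoint_epochs = 1:5)
  dq <- build_quality_dataset(sp$dlp, tr$checkpoints, quality_threshold(0.5))
  expect_length(dq, 20)  # k = 5 checkpoints x N = 4 images
  for (it in dq$items) {
    expect_s3_class(it$pseudo_label, "lesion_mask")
    expect_identical(it$quality, grade_pseudo_label(it$score,
                                                    quality_threshold(0.5)))
  }
})

test_that("identical checkpoints grade identically; a degenerate all-background
           predictor grades zero everywhere", {
  cfg <- tiny_gen(21)
  sp <- generate_splits(cfg, 3, 0, 0, 0)
  set.seed(2)
  m <- seg_model(base_channels = 4)
  same <- structure(list(items = list(m, m, m), epochs = 1:3),
                    class = "checkpoint_set")
  dq <- build_quality_dataset(sp$dlp, same, quality_threshold(0.5))
  grades <- matrix(vapply(dq$items, function(it) it$quality, integer(1)),
                   nrow = 3)
  expect_true(all(apply(grades, 2, function(g) length(unique(g)) == 1L)))
  # head bias at -10 forces sigmoid below 0.5 everywhere
  m$params$head_b[] <- -10
  pl <- generate_pseudo_label(m, sp$dlp$items[[1]]$image)
  expect_equal(sum(pl), 0L)
  dz <- build_quality_dataset(sp$dlp, structure(
    list(items = list(m), epochs = 1L), class = "checkpoint_set"),
    quality_threshold(0.5))
  expect_true(all(vapply(dz$items, function(it) it$quality, integer(1)) == 0L))
  # pseudo-labels are deterministic
  expect_identical(pl, generate_pseudo_label(m, sp$dlp$items[[1]]$image))
})

test_that("hard-wired quality decisions retain all or nothing", {
  cfg <- tiny_gen(22)
  sp <- generate_splits(cfg, 2, 0, 10, 0)
  set.seed(3)
  teacher <- seg_model(base_channels = 4)
  all1 <- screen_pool(sp$du, teacher, function(img, pl) 1L)
  expect_length(all1$set, 10)
  expect_true(all(all1$report$retained))
  all0 <- screen_pool(sp$du, teacher, function(img, pl) 0L)
  expect_length(all0$set, 0)
  # screening selects, never edits: retained masks are the teacher's outputs
  for (i in seq_along(all1$set$items))
    expect_identical(all1$set$items[[i]]$mask,
                     generate_pseudo_label(teacher, sp$du$items[[i]]))
})

test_that("screening with a Jaccard oracle equals the brute-force filter", {
  for (seed in 1:5) {
    cfg <- generator_config(seed = 100 + seed)
    sp <- generate_splits(cfg, 2, 0, 50, 0)
    set.seed(seed)
    teacher <- seg_model()  # arbitrary weights; oracle equivalence is exact
    hidden <- attr(sp$du, "hidden")$masks
    ids <- vapply(sp$du$items, function(im) im$id, character(1))
    oracle <- function(img, pl)
      grade_pseudo_label(jaccard(hidden[[match(img$id, ids)]], pl),
                         quality_threshold(0.3))
    scr <- screen_pool(sp$du, teacher, oracle)
    keep <- vapply(seq_along(ids), function(i)
      jaccard(hidden[[i]], generate_pseudo_label(teacher, sp$du$items[[i]]))
      >= 0.3, logical(1))
    expect_identical(scr$report$retained, keep)
    expect_length(scr$set, sum(keep))
    kept_ids <- vapply(scr$set$items, function(it) it$image$id, character(1))
    expect_identical(kept_ids, ids[keep])  # pool order preserved
    expect_equal(scr$report$true_jaccard,
                 vapply(seq_along(ids), function(i)
                   jaccard(hidden[[i]],
                           generate_pseudo_label(teacher, sp$du$items[[i]])),
                   numeric(1)))
  }
})

test_that("the self-training stage composes end to end", {
  cfg <- tiny_gen(24, noise_sd = 0.02, hair_max = 2L)
  sp <- generate_splits(cfg, 8, 0, 6, 0)
  run <- function(du) run_selftrain_stage(
    sp$dlp, du,
    seg_cfg = train_config(learning_rate = 1e-3, max_epochs = 5, seed = 31),
    cls_cfg = train_config(learning_rate = 1e-3, max_epochs = 2, seed = 32),
    t = quality_threshold(0.6), k = 3L)
  st <- run(sp$du)
  expect_s3_class(st$teacher, "seg_model")
  expect_length(st$checkpoints, 3)
  expect_equal(st$quality$arch$n_classes, 2L)
  expect_lte(length(st$pseudo), 6)
  expect_equal(nrow(st$report), 6)
  # empty pool: earlier stages still complete, screening yields nothing
  empty <- run(unlabeled_set(list()))
  expect_length(empty$pseudo, 0)
  expect_s3_class(empty$quality, "cls_model")
  # fixed seeds reproduce the same retained count
  expect_identical(length(run(sp$du)$pseudo), length(st$pseudo))
})
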