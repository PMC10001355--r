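# Shared fixtures built in code at test time.

mk_mask <- function(v, nr) as_mask(matrix(v, nr))

# a quick low-resolution generator configuration for training smoke tests
tiny_gen <- function(seed, noise_sd = 0, hair_max = 0L, bubble_max = 0L,
                     size = 32L) {
  generator_config(image_size = size, noise_sd = noise_sd,
                   hair_max = hair_max, bubble_max = bubble_max, seed = seed)
}

# brute-force AUC: count all positive-negative pairs, ties as one half
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# a tiny run configuration for pipeline tests (32x32, small splits)
tiny_run_config <- function(seed) {
  run_config(
    generator = generator_config(image_size = 32L, seed = 1L),
    n_pixel_labeled = 10L, n_image_labeled = 10L, n_unlabeled = 8L,
    n_test = 6L,
    seg_cfg = train_config(learning_rate = 1e-3, max_epochs = 4L),
    quality_cfg = train_config(learning_rate = 1e-3, max_epochs = 2L),
    disease_cfg = train_config(learning_rate = 1e-3, max_epochs = 2L),
    k = 3L, seed = seed)
}

artifact_md5 <- function(dir) {
  fs <- sort(list.files(dir, pattern = "\\.rds$", full.names = TRUE))
  hs <- tools::md5sum(fs)
  names(hs) <- basename(names(hs))
  hs
}
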