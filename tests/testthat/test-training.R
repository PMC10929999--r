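test_that("soft Dice matches closed forms and the hard-mask metric", {
  lab <- array(sample(0:4, 4 * 6 * 6, TRUE), c(4, 6, 6))
  oh <- one_hot(lab, 5)

  # perfect one-hot prediction -> similarity 1 (within smooth tolerance)
  expect_equal(soft_dice(oh, oh, smooth = 1e-8), 1, tolerance = 1e-6)

  # probability mass entirely on the wrong class -> 0
  wrong <- one_hot((lab + 1L) %% 5L, 5)
  expect_lt(soft_dice(wrong, oh, smooth = 1e-8), 1e-6)

  # uniform 0.2 prediction: per class 2*0.2*|G| / (0.2*N + |G|)
  unif <- array(0.2, dim(oh))
  n <- length(lab)
  want <- sapply(1:4, function(cl) {
    g <- sum(lab == cl)
    (2 * 0.2 * g + 1e-5) / (0.2 * n + g + 1e-5)
  })
  expect_equal(unname(soft_dice(unif, oh, per_class = TRUE)), want,
               tolerance = 1e-12)

  # cross-module consistency: on hard inputs soft_dice == dsc per class
  pred <- array(sample(0:4, 4 * 6 * 6, TRUE), c(4, 6, 6))
  sd_pc <- soft_dice(one_hot(pred, 5), oh, smooth = 1e-12, per_class = TRUE)
  for (cl in 1:4) {
    expect_equal(sd_pc[cl], dsc(pred == cl, lab == cl), tolerance = 1e-6)
  }

  expect_error(soft_dice(oh, oh[, 1:2, , ]), "shapes differ")
})

test_that("cross-entropy matches closed forms and a per-voxel loop", {
  lab <- array(sample(0:4, 3 * 4 * 4, TRUE), c(3, 4, 4))
  oh <- one_hot(lab, 5)

  # perfect (clipped) prediction is ~0
  expect_lt(cross_entropy(oh, oh), 1e-5)

  # uniform prediction costs log(5) per voxel
  unif <- array(0.2, dim(oh))
  expect_equal(cross_entropy(unif, oh), log(5), tolerance = 1e-12)

  # random probabilities vs an explicit double loop
  set.seed(5)
  raw <- array(runif(length(oh)), dim(oh))
  pm <- matrix(raw, nrow = 5)
  pm <- sweep(pm, 2, colSums(pm), "/")
  probs <- array(pm, dim(oh))
  loop <- 0
  for (v in seq_len(length(lab))) {
    for (cl in 0:4) {
      y <- as.integer(lab[v] == cl)
      loop <- loop - y * log(max(min(pm[cl + 1, v], 1 - 1e-7), 1e-7))
    }
  }
  expect_equal(cross_entropy(probs, oh), loop / length(lab), tolerance = 1e-9)

  # binary (two-term) form coincides with the categorical one at 2 classes
  lab2 <- array(sample(0:1, 16, TRUE), c(1, 4, 4))
  oh2 <- one_hot(lab2, 2)
  p2 <- array(runif(32, 0.05, 0.95), dim(oh2))
  p2m <- matrix(p2, nrow = 2)
  p2m <- sweep(p2m, 2, colSums(p2m), "/")
  p2 <- array(p2m, dim(oh2))
  expect_equal(cross_entropy(p2, oh2, form = "binary"),
               cross_entropy(p2, oh2, form = "categorical"),
               tolerance = 1e-9)
})

test_that("composite loss reduces to its parts and is a convex combination", {
  lab <- array(sample(0:4, 2 * 8 * 8, TRUE), c(2, 8, 8))
  oh <- one_hot(lab, 5)
  set.seed(6)
  pm <- matrix(runif(5 * length(lab)), nrow = 5)
  pm <- sweep(pm, 2, colSums(pm), "/")
  probs <- array(pm, dim(oh))

  ld <- 1 - soft_dice(probs, oh)
  lc <- cross_entropy(probs, oh)
  expect_equal(composite_loss(probs, oh, loss_config(a = 1)), ld)
  expect_equal(composite_loss(probs, oh, loss_config(a = 0)), lc)
  for (a in c(0.1, 0.3, 0.5, 0.8)) {
    l <- composite_loss(probs, oh, loss_config(a = a))
    expect_gte(l, min(ld, lc) - 1e-12)
    expect_lte(l, max(ld, lc) + 1e-12)
    expect_equal(l, a * ld + (1 - a) * lc, tolerance = 1e-12)
  }

  # perfect prediction: loss ~ 0 for any a
  expect_lt(composite_loss(oh, oh, loss_config(a = 0.5)), 1e-3)

  expect_error(loss_config(a = 1.2), "\\[0, 1\\]")
  expect_error(loss_config(smooth = 0), "positive")
})

test_that("fold construction partitions cases with balanced sizes", {
  ids <- sprintf("case_%03d", 1:50)
  fs <- make_folds(ids, k = 5, seed = 1)
  expect_equal(unname(table(fs$assignment)), rep(10L, 5), ignore_attr = TRUE)
  expect_setequal(names(fs$assignment), ids)

  # 11 cases in 5 folds: sizes 3,2,2,2,2
  fs11 <- make_folds(sprintf("c%02d", 1:11), k = 5, seed = 2)
  expect_equal(sort(unname(table(fs11$assignment)), decreasing = TRUE),
               c(3L, 2L, 2L, 2L, 2L), ignore_attr = TRUE)

  # determinism and coverage: every case in exactly one validation fold
  fs2 <- make_folds(ids, k = 5, seed = 1)
  expect_identical(fs$assignment, fs2$assignment)
  seen <- unlist(lapply(1:5, function(f) names(fs$assignment)[fs$assignment == f]))
  expect_setequal(seen, ids)
  expect_equal(length(seen), 50)

  expect_error(make_folds(ids[1:3], k = 5), "at least k")
})

test_that("training reduces the loss on a learnable task and reproduces", {
  cases <- phantom_cases(4, seed = 21, grid = c(8L, 32L, 32L))
  nc <- unet_config(dims = 2, n_stages_xy = 2, base_channels = 4,
                    max_channels = 8)
  tc <- train_config(epochs = 4, batches_per_epoch = 8, batch_size = 2,
                     patch_size = c(1, 16, 16), val_patches = 4, seed = 3)
  fit <- train_model(cases[1:3], cases[4], nc, tc)
  expect_equal(nrow(fit$history), 4)
  expect_lt(fit$history$loss[4], fit$history$loss[1])

  # same seed twice: identical first-epoch loss
  fit2 <- train_model(cases[1:3], cases[4], nc, tc)
  expect_equal(fit2$history$loss[1], fit$history$loss[1], tolerance = 1e-12)

  # one case, one epoch: completes and writes a checkpoint
  ckpt <- withr::local_tempfile(fileext = ".rds")
  tc1 <- train_config(epochs = 1, batches_per_epoch = 2, batch_size = 1,
                      patch_size = c(1, 16, 16), val_patches = 0, seed = 4)
  fit1 <- train_model(cases[1], list(), nc, tc1, checkpoint_path = ckpt)
  expect_true(file.exists(ckpt))
  expect_s3_class(load_model(ckpt), "unet_model")

  expect_error(train_model(list(), list(), nc, tc), "at least one")
})
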