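test_that("stage arithmetic: bottleneck extents follow the stride plan", {
  # full 2D preset: six in-plane halvings take 256x256 to 4x4
  s2 <- unet_shapes(unet_preset("2d_full"), c(256, 256))
  expect_equal(s2$bottleneck, c(1, 4, 4))

  # full 3D preset: z halved twice (32 -> 8), plane six times (256 -> 4)
  s3 <- unet_shapes(unet_preset("3d_full"), c(32, 256, 256))
  expect_equal(s3$bottleneck, c(8, 4, 4))

  # indivisible input is a configuration error before any training
  expect_error(unet_shapes(unet_preset("2d_full"), c(250, 250)),
               "configuration error")
  tc <- train_config(patch_size = c(1, 50, 50))
  expect_error(
    train_model(list(list(image = array(0, c(1, 50, 50)),
                          labels = array(0L, c(1, 50, 50)))),
                list(), unet_preset("2d_test"), tc),
    "divisible")
})

test_that("a real forward pass lands on the predicted bottleneck and 5-channel softmax", {
  # 2D test preset at full-slice size
  cfg2 <- unet_preset("2d_test")
  m2 <- build_unet(cfg2, seed = 1)
  fw <- selfseg:::unet_forward(m2, array(rnorm(64^2), c(1, 1, 64, 64)))
  expect_equal(fw$bottleneck_shape,
               unet_shapes(cfg2, c(64, 64))$bottleneck)
  expect_equal(dim(fw$logits), c(5, 1, 64, 64))
  p <- selfseg:::softmax_channels(fw$logits)
  expect_lt(max(abs(colSums(matrix(p, nrow = 5)) - 1)), 1e-5)
  expect_true(all(p > 0))

  # 3D test preset: z 8 with 2 z-stages -> bottleneck z = 2
  cfg3 <- unet_preset("3d_test")
  m3 <- build_unet(cfg3, seed = 1)
  fw3 <- selfseg:::unet_forward(m3, array(rnorm(8 * 16 * 16), c(1, 8, 16, 16)))
  expect_equal(fw3$bottleneck_shape,
               unet_shapes(cfg3, c(8, 16, 16))$bottleneck)
  expect_equal(fw3$bottleneck_shape[1], 2)
  expect_equal(dim(fw3$logits), c(5, 8, 16, 16))
})

test_that("channel widths realize base * growth^stage capped at max", {
  cfg <- unet_config(dims = 2, n_stages_xy = 5, base_channels = 8,
                     channel_growth = 2, max_channels = 100)
  expect_equal(selfseg:::unet_channels(cfg), c(8, 16, 32, 64, 100, 100))
  m <- build_unet(cfg, seed = 3)
  for (i in 1:6) {
    blk <- m$params[[paste0("enc_b_", i)]]
    expect_equal(blk$conv$out_ch, selfseg:::unet_channels(cfg)[i])
  }
})

test_that("model construction is deterministic in (config, seed)", {
  cfg <- unet_preset("2d_test")
  m1 <- build_unet(cfg, seed = 5)
  m2 <- build_unet(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_equal(parameter_count(m1), parameter_count(m2))
  m3 <- build_unet(cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))
})

test_that("backpropagation matches finite differences", {
  cfg <- unet_config(dims = 2, n_stages_xy = 2, base_channels = 3,
                     max_channels = 6)
  gm <- build_unet(cfg, seed = 2)
  xx <- array(rnorm(16 * 16), c(1, 1, 16, 16))
  oh <- one_hot(array(sample(0:4, 256, TRUE), c(1, 16, 16)), 5)
  lc <- loss_config(a = 0.5)
  fw <- selfseg:::unet_forward(gm, xx, cache = TRUE)
  lg <- selfseg:::loss_and_grad(fw$logits, oh, lc)
  gr <- selfseg:::unet_backward(gm, fw$caches, lg$dlogits)

  loss_at <- function(params) {
    gm2 <- gm
    gm2$params <- params
    selfseg:::loss_and_grad(selfseg:::unet_forward(gm2, xx)$logits, oh, lc)$loss
  }
  set.seed(99)
  paths <- list(c("enc_a_1", "conv", "W"), c("enc_b_2", "norm", "gamma"),
                c("up_1", "W"), c("dec_a_2", "conv", "W"),
                c("final", "W"), c("dec_b_1", "norm", "beta"))
  for (path in paths) {
    leaf <- gm$params[[path]]
    i <- sample(length(leaf), 1)
    eps <- 1e-5
    pp <- gm$params; pp[[path]][i] <- pp[[path]][i] + eps
    pm <- gm$params; pm[[path]][i] <- pm[[path]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    an <- gr[[path]][i]
    expect_equal(an, num, tolerance = 1e-4)
  }
})

test_that("sliding-window inference honors its contracts", {
  cfg <- unet_config(dims = 2, n_stages_xy = 2, base_channels = 4,
                     max_channels = 8)
  m <- build_unet(cfg, seed = 4)

  # volume smaller than the window: padded, cropped back to input shape
  v <- volume(array(rnorm(3 * 10 * 10), c(3, 10, 10)), spacing = c(6.5, 1, 1))
  pm <- predict_probabilities(m, v, window = c(1, 16, 16))
  expect_equal(dim(pm$data), c(5, 3, 10, 10))
  expect_lt(max(abs(colSums(matrix(pm$data, nrow = 5)) - 1)), 1e-5)

  # constant-weight model: overlap 0 and 0.5 give the same constant field
  mc <- m
  zero_leaves <- function(x) {
    for (nm in names(x)) {
      if (nm %in% c("W", "b", "gamma", "beta")) x[[nm]] <- x[[nm]] * 0
      else if (is.list(x[[nm]])) x[[nm]] <- zero_leaves(x[[nm]])
    }
    x
  }
  mc$params <- zero_leaves(mc$params)
  v2 <- volume(array(rnorm(2 * 24 * 24), c(2, 24, 24)), spacing = c(6.5, 1, 1))
  p0 <- predict_probabilities(mc, v2, window = c(1, 8, 8), overlap = 0)
  p5 <- predict_probabilities(mc, v2, window = c(1, 8, 8), overlap = 0.5)
  expect_equal(p0$data, p5$data, tolerance = 1e-12)
  expect_equal(max(abs(p0$data - 0.2)), 0, tolerance = 1e-12)

  # argmax defined everywhere
  lab <- labels_from_probabilities(pm)
  expect_true(all(lab$data %in% 0:4))
})

test_that("checkpoints round-trip with the config embedded", {
  cfg <- unet_preset("3d_test")
  m <- build_unet(cfg, seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".yaml")))
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  expect_error(load_model(tempfile()), "no such file")
})
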