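test_that("NIfTI round trip preserves data and rejects bad inputs", {
  v <- volume(array(rnorm(6 * 10 * 12), c(6, 10, 12)),
              spacing = c(6.5, 0.664, 0.664), case_id = "rt")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_identical(back$data, v$data)
  expect_equal(back$spacing, v$spacing, tolerance = 1e-6)

  # a 2D image on disk is a dimensionality error
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(16), 4, 4)), p2)
  expect_error(read_volume(p2), "3D")

  # labels with an out-of-range value fail labelmap validation
  p3 <- withr::local_tempfile(fileext = ".nii.gz")
  bad <- volume(array(5, c(4, 4, 4)), spacing = c(1, 1, 1))
  write_volume(bad, p3)
  expect_error(read_labelmap(p3), "0..4")

  expect_error(read_volume(tempfile()), "no such file")
})

test_that("z-score normalization matches its contract", {
  v <- volume(array(rnorm(5 * 8 * 8, mean = 40, sd = 7), c(5, 8, 8)),
              spacing = c(1, 1, 1))
  nv <- zscore_normalize(v)
  expect_lt(abs(mean(nv$data)), 1e-6)
  pop_sd <- sqrt(mean((nv$data - mean(nv$data))^2))
  expect_lt(abs(pop_sd - 1), 1e-6)

  # constant volume maps to zeros
  cv <- zscore_normalize(volume(array(42, c(4, 4, 4)), spacing = c(1, 1, 1)))
  expect_true(all(cv$data == 0))

  # affine invariance: normalize(a x + b) == normalize(x)
  v2 <- volume(3.7 * v$data + 11, spacing = v$spacing)
  expect_equal(zscore_normalize(v2)$data, nv$data, tolerance = 1e-9)

  # idempotence
  expect_equal(zscore_normalize(nv)$data, nv$data, tolerance = 1e-6)
})

test_that("resampling follows the shape rule and interpolation contracts", {
  v <- volume(array(rnorm(8 * 12 * 12), c(8, 12, 12)),
              spacing = c(6.5, 2, 2))
  # identity at equal spacing
  expect_identical(resample(v, c(6.5, 2, 2))$data, v$data)

  # shape rule: round(shape * spacing / target), half away from zero
  r <- resample(v, c(3.25, 1, 1))
  expect_identical(dim(r$data), c(16L, 24L, 24L))
  r2 <- resample(v, c(6.5, 3.2, 3.2))  # 12*2/3.2 = 7.5 -> 8
  expect_identical(dim(r2$data)[2:3], c(8L, 8L))

  # constant volume stays constant under any target spacing
  cv <- volume(array(3.5, c(6, 6, 6)), spacing = c(2, 2, 2))
  rc <- resample(cv, c(1.3, 0.7, 2.9))
  expect_equal(range(rc$data), c(3.5, 3.5))

  # labels: nearest only, codomain preserved
  lab <- labelmap(array(sample(c(0L, 2L), 8 * 12 * 12, TRUE), c(8, 12, 12)),
                  spacing = c(6.5, 2, 2))
  rl <- resample(lab, c(3.25, 1.5, 1.5))
  expect_true(all(rl$data %in% c(0L, 2L)))
  expect_error(resample(lab, c(3.25, 1.5, 1.5), mode = "linear"), "nearest")
})

test_that("resampling a smooth volume down and back is accurate", {
  d <- c(6, 24, 24)
  gy <- array(rep(seq(0, 1, length.out = d[2]), each = d[1]), d)
  gx <- array(rep(seq(0, 1, length.out = d[3]), each = d[1] * d[2]), d)
  smooth <- sin(2 * pi * gy) * cos(2 * pi * gx)
  v <- volume(smooth, spacing = c(6.5, 2, 2))
  up <- resample(v, c(6.5, 1, 1))
  back <- resample(up, c(6.5, 2, 2))
  expect_identical(dim(back$data), dim(v$data))
  expect_lt(max(abs(back$data - v$data)), 0.05)
})

test_that("patch extraction pads, centers, and oversamples as configured", {
  img <- array(rnorm(4 * 16 * 16), c(4, 16, 16))
  lab <- array(0L, c(4, 16, 16))
  lab[2:3, 6:10, 6:10] <- 1L

  # patch equal to the full volume is the identity
  set.seed(1)
  p <- extract_patch(img, lab, c(4, 16, 16))
  expect_identical(p$image, img)
  expect_identical(p$labels, lab)

  # smaller source is zero-padded with the original centered
  small <- array(1, c(4, 16, 16))
  p2 <- extract_patch(small, NULL, c(4, 32, 32))
  expect_identical(dim(p2$image), c(4L, 32L, 32L))
  expect_equal(sum(p2$image), 4 * 16 * 16)
  expect_equal(p2$image[1, 9:24, 9:24], matrix(1, 16, 16))

  # foreground oversampling: fg-draw frequency matches the configured share
  set.seed(42)
  n <- 1500
  fgd <- logical(n)
  centered_fg <- logical(n)
  for (i in seq_len(n)) {
    pp <- extract_patch(img, lab, c(1, 8, 8), fg_fraction = 0.5)
    fgd[i] <- pp$provenance$fg_draw
    if (fgd[i]) {
      ctr <- (c(1, 8, 8) %/% 2) + 1
      centered_fg[i] <- pp$labels[ctr[1], ctr[2], ctr[3]] > 0
    }
  }
  expect_gt(mean(fgd), 0.45)
  expect_lt(mean(fgd), 0.55)
  expect_true(all(centered_fg[fgd]))
})

test_that("augmentation preserves shape and label codomain", {
  cases <- phantom_cases(1, seed = 2, grid = c(8L, 32L, 32L))
  set.seed(7)
  p <- extract_patch(cases[[1]]$image, cases[[1]]$labels, c(1, 24, 24),
                     fg_fraction = 1)

  # explicit zero rotation and jitter is the identity
  id <- augment_patch(p, rotation_deg = 0, jitter_vox = c(0, 0))
  expect_identical(id$image, p$image)
  expect_identical(id$labels, p$labels)

  # 90-degree rotation is lattice-exact: voxel count preserved per class
  bar <- p
  bar$labels <- array(0L, dim(p$labels))
  bar$labels[1, 10:14, 5:20] <- 3L
  r90 <- augment_patch(bar, rotation_deg = 90, jitter_vox = c(0, 0))
  expect_equal(sum(r90$labels == 3L), sum(bar$labels == 3L))
  # the bar is transposed in plane: y-extent and x-extent swap
  yext <- range(which(apply(r90$labels == 3L, 2, any)))
  expect_equal(diff(yext), 15)

  # arbitrary rotations keep shape and codomain
  set.seed(8)
  for (i in 1:5) {
    a <- augment_patch(p)
    expect_identical(dim(a$image), dim(p$image))
    expect_true(all(a$labels %in% 0:4))
  }
})

test_that("randomized preprocessing is reproducible under a fixed seed", {
  cases <- phantom_cases(1, seed = 3, grid = c(8L, 32L, 32L))
  draw <- function() {
    set.seed(123)
    a <- extract_patch(cases[[1]]$image, cases[[1]]$labels, c(1, 16, 16),
                       fg_fraction = 0.5)
    augment_patch(a)
  }
  d1 <- draw()
  d2 <- draw()
  expect_identical(d1$image, d2$image)
  expect_identical(d1$labels, d2$labels)
})
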