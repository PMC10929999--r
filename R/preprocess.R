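#' Z-score intensity normalization
#'
#' Subtracts the mean and divides by the population standard deviation,
#' per image. A constant image maps to all zeros, which keeps the operation
#' total and idempotent on degenerate input.
#'
#' @param vol A [volume()].
#' @return A normalized [volume()].
#' @export
zscore_normalize <- function(vol) {
  stopifnot(inherits(vol, "seg_volume"))
  x <- vol$data
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  out <- if (s < 1e-12) array(0, dim(x)) else (x - m) / s
  volume(out, spacing = vol$spacing, origin = vol$origin, case_id = vol$case_id)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Resample a volume or label map to a target spacing
#'
#' The output grid shape per axis is `round(shape * spacing / target)`
#' (half rounded away from zero, minimum 1). Voxel centers are aligned so
#' the physical field of view is preserved; values are interpolated
#' linearly for images and by nearest neighbor for labels (labels must use
#' nearest mode, which preserves the label codomain).
#'
#' @param obj A [volume()] or [labelmap()].
#' @param target_spacing_mm Numeric length-3 target spacing (z, y, x), mm.
#' @param mode `"linear"` or `"nearest"`. Defaults to linear for volumes and
#'   nearest for label maps.
#' @return An object of the same class on the new grid.
#' @export
resample <- function(obj, target_spacing_mm,
                     mode = if (inherits(obj, "seg_labelmap")) "nearest" else "linear") {
  is_lab <- inherits(obj, "seg_labelmap")
  if (!is_lab && !inherits(obj, "seg_volume"))
    stop("resample expects a seg_volume or seg_labelmap", call. = FALSE)
  mode <- match.arg(mode, c("linear", "nearest"))
  if (is_lab && mode == "linear")
    stop("label maps must be resampled with mode = 'nearest'", call. = FALSE)
  tgt <- as.numeric(target_spacing_mm)
  if (length(tgt) != 3L || any(tgt <= 0))
    stop("target spacing must be 3 positive values", call. = FALSE)
  shape <- dim(obj$data)
  new_shape <- pmax(1L, as.integer(round_half_away(shape * obj$spacing / tgt)))
  if (identical(new_shape, shape) && max(abs(tgt - obj$spacing)) < 1e-12)
    return(obj)
  # output voxel i center maps to input index coordinate (1-based centers)
  coord <- function(ax) (seq_len(new_shape[ax]) - 0.5) * tgt[ax] / obj$spacing[ax] + 0.5
  if (mode == "nearest") {
    idx <- lapply(1:3, function(ax) pmin(pmax(floor(coord(ax) + 0.5), 1), shape[ax]))
    out <- obj$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  } else {
    lo <- list(); hi <- list(); w <- list()
    for (ax in 1:3) {
      u <- coord(ax)
      l <- floor(u)
      f <- u - l
      lo[[ax]] <- pmin(pmax(l, 1), shape[ax])
      hi[[ax]] <- pmin(pmax(l + 1, 1), shape[ax])
      w[[ax]] <- f
    }
    out <- array(0, new_shape)
    for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
      wz <- if (bz == 0) 1 - w[[1]] else w[[1]]
      wy <- if (by == 0) 1 - w[[2]] else w[[2]]
      wx <- if (bx == 0) 1 - w[[3]] else w[[3]]
      iz <- if (bz == 0) lo[[1]] else hi[[1]]
      iy <- if (by == 0) lo[[2]] else hi[[2]]
      ix <- if (bx == 0) lo[[3]] else hi[[3]]
      wt <- array(wz, new_shape) *
        array(rep(wy, each = new_shape[1]), new_shape) *
        array(rep(wx, each = new_shape[1] * new_shape[2]), new_shape)
      out <- out + wt * obj$data[iz, iy, ix, drop = FALSE]
    }
  }
  if (is_lab)
    labelmap(out, spacing = tgt, origin = obj$origin, case_id = obj$case_id,
             n_classes = obj$n_classes)
  else
    volume(out, spacing = tgt, origin = obj$origin, case_id = obj$case_id)
}

pad_to <- function(arr, size, fill) {
  d <- dim(arr)
  if (all(d >= size)) return(arr)
  nd <- pmax(d, size)
  out <- array(fill, nd)
  lo <- floor((nd - d) / 2)
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3])] <- arr
  out
}

#' Extract an image/label training patch
#'
#' Samples a patch corner uniformly from all valid corners; if the source is
#' smaller than the patch along an axis it is first symmetrically padded
#' (zeros for the image, background for labels) with the original data
#' centered. With `fg_fraction > 0`, that fraction of draws instead centers
#' the patch on a random foreground voxel (falling back to a uniform draw if
#' no foreground fits). Sampling uses the current RNG state, so a seed set
#' by the caller makes draws reproducible.
#'
#' @param image 3D image array (z, y, x); a 2D slice is passed as z-size 1.
#' @param labels Optional aligned integer label array.
#' @param patch_size Integer length-3 patch shape (z, y, x).
#' @param fg_fraction Probability of a foreground-centered draw.
#' @param fg_balanced For foreground draws, first pick a present foreground
#'   class uniformly, then a voxel of that class; balances patch exposure of
#'   small structures (femoral heads, intestine lobes) against large ones.
#' @return A list `image`, `labels`, `provenance` (corner, fg_draw flag).
#' @export
extract_patch <- function(image, labels = NULL, patch_size,
                          fg_fraction = 0, fg_balanced = FALSE) {
  patch_size <- as.integer(patch_size)
  stopifnot(length(patch_size) == 3L, all(patch_size >= 1L))
  image <- pad_to(image, patch_size, 0)
  if (!is.null(labels)) labels <- pad_to(labels, patch_size, 0L)
  d <- dim(image)
  fg_draw <- FALSE
  corner <- integer(3)
  half <- patch_size %/% 2L
  if (!is.null(labels) && fg_fraction > 0 && runif(1) < fg_fraction) {
    clo <- half + 1L
    chi <- d - (patch_size - half - 1L)
    fg <- which(labels > 0L)
    if (fg_balanced && length(fg)) {
      cls <- sample(unique(labels[fg]), 1L)
      fg <- fg[labels[fg] == cls]
    }
    if (length(fg)) {
      ci <- arrayInd(fg, d)
      ok <- ci[, 1] >= clo[1] & ci[, 1] <= chi[1] &
        ci[, 2] >= clo[2] & ci[, 2] <= chi[2] &
        ci[, 3] >= clo[3] & ci[, 3] <= chi[3]
      if (any(ok)) {
        pick <- which(ok)[sample.int(sum(ok), 1L)]
        corner <- as.integer(ci[pick, ] - half)
        fg_draw <- TRUE
      }
    }
  }
  if (!fg_draw) {
    nvalid <- d - patch_size + 1L
    corner <- vapply(1:3, function(ax) sample.int(nvalid[ax], 1L), integer(1))
  }
  iz <- corner[1] + seq_len(patch_size[1]) - 1L
  iy <- corner[2] + seq_len(patch_size[2]) - 1L
  ix <- corner[3] + seq_len(patch_size[3]) - 1L
  list(image = image[iz, iy, ix, drop = FALSE],
       labels = if (is.null(labels)) NULL else labels[iz, iy, ix, drop = FALSE],
       provenance = list(corner = corner, fg_draw = fg_draw))
}

rot90_plane <- function(arr, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(arr)
  for (i in seq_len(k)) {
    d <- dim(arr)
    # 90 deg rotation in the (y, x) plane, z kept
    arr <- aperm(arr[, rev(seq_len(d[2])), , drop = FALSE], c(1, 3, 2))
  }
  arr
}

rotate_inplane <- function(arr, angle_deg, interp = c("linear", "nearest"),
                           fill = 0) {
  interp <- match.arg(interp)
  if (abs(angle_deg) < 1e-12) return(arr)
  d <- dim(arr)
  if (angle_deg %% 90 == 0 && (d[2] == d[3] || angle_deg %% 180 == 0))
    return(rot90_plane(arr, as.integer(round(angle_deg / 90))))
  th <- angle_deg * pi / 180
  cy <- (d[2] + 1) / 2; cx <- (d[3] + 1) / 2
  gy <- rep(seq_len(d[2]), times = d[3]) - cy
  gx <- rep(seq_len(d[3]), each = d[2]) - cx
  # inverse map: source = R(-theta) %*% target
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  out <- array(fill, d)
  if (interp == "nearest") {
    ry <- floor(sy + 0.5); rx <- floor(sx + 0.5)
    ok <- ry >= 1 & ry <= d[2] & rx >= 1 & rx <= d[3]
    src <- cbind(ry[ok], rx[ok])
    for (z in seq_len(d[1])) {
      sl <- matrix(fill, d[2], d[3])
      sl[cbind(gy[ok] + cy, gx[ok] + cx)] <- arr[z, , ][src]
      out[z, , ] <- sl
    }
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    ok <- y0 >= 1 & y0 + 1 <= d[2] & x0 >= 1 & x0 + 1 <= d[3]
    ti <- cbind(gy[ok] + cy, gx[ok] + cx)
    for (z in seq_len(d[1])) {
      sl <- arr[z, , ]
      v <- (1 - fy[ok]) * (1 - fx[ok]) * sl[cbind(y0[ok], x0[ok])] +
        (1 - fy[ok]) * fx[ok] * sl[cbind(y0[ok], x0[ok] + 1)] +
        fy[ok] * (1 - fx[ok]) * sl[cbind(y0[ok] + 1, x0[ok])] +
        fy[ok] * fx[ok] * sl[cbind(y0[ok] + 1, x0[ok] + 1)]
      o <- matrix(fill, d[2], d[3])
      o[ti] <- v
      out[z, , ] <- o
    }
  }
  out
}

#' Augment a training patch
#'
#' Applies (i) a random in-plane rotation (image interpolated bilinearly,
#' labels by nearest neighbor; exact lattice rotation at multiples of 90
#' degrees) and (ii) a random crop-then-pad translation jitter. Output shape
#' and label codomain are unchanged. Passing explicit `rotation_deg = 0` and
#' `jitter_vox = c(0, 0)` gives the identity.
#'
#' @param pair A patch pair from [extract_patch()].
#' @param max_rotation_deg Rotation sampled uniformly in +/- this range.
#' @param max_jitter_vox In-plane translation sampled in +/- this range.
#' @param rotation_deg,jitter_vox Override the random draws (for tests).
#' @return An augmented patch pair.
#' @export
augment_patch <- function(pair, max_rotation_deg = 15, max_jitter_vox = 2,
                          rotation_deg = NULL, jitter_vox = NULL) {
  if (is.null(rotation_deg))
    rotation_deg <- runif(1, -max_rotation_deg, max_rotation_deg)
  if (is.null(jitter_vox))
    jitter_vox <- c(sample(-max_jitter_vox:max_jitter_vox, 1L),
                    sample(-max_jitter_vox:max_jitter_vox, 1L))
  img <- rotate_inplane(pair$image, rotation_deg, "linear", fill = 0)
  lab <- if (!is.null(pair$labels))
    rotate_inplane(pair$labels, rotation_deg, "nearest", fill = 0L)
  if (any(jitter_vox != 0)) {
    img <- shift_num_array(img, jitter_vox[1], jitter_vox[2], 0)
    if (!is.null(lab)) lab <- shift_num_array(lab, jitter_vox[1], jitter_vox[2], 0L)
  }
  if (!is.null(lab)) storage.mode(lab) <- "integer"
  list(image = img, labels = lab,
       provenance = c(pair$provenance,
                      list(rotation_deg = rotation_deg, jitter_vox = jitter_vox)))
}

# in-plane integer translation with constant fill (crop-then-pad jitter)
shift_num_array <- function(arr, dy, dx, fill) {
  d <- dim(arr)
  out <- array(fill, d)
  sy <- max(1, 1 - dy):min(d[2], d[2] - dy)
  sx <- max(1, 1 - dx):min(d[3], d[3] - dx)
  if (length(sy) < 1 || length(sx) < 1) return(out)
  out[, sy + dy, sx + dx] <- arr[, sy, sx]
  out
}
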