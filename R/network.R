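#' U-Net architecture configuration
#'
#' Encoder-decoder with skip connections. Every computational block is
#' convolution + instance normalization + leaky ReLU; down-sampling uses
#' strided convolutions, up-sampling transposed convolutions, and a final
#' 1x1(x1) convolution maps to `out_channels` class scores (softmax applied
#' at the loss / inference side). For the 3D variant, the z axis is
#' down-sampled only in the first `n_stages_z` stages (stride 2,2,2), later
#' stages use stride (1,2,2), so a z extent of 32 reaches 8 at the
#' bottleneck while 6 in-plane stages take 256 to 4. Channel widths grow as
#' `base_channels * channel_growth^stage`, capped at `max_channels`.
#'
#' @param dims 2 or 3.
#' @param in_channels Input image channels (1).
#' @param out_channels Output classes (5: background + 4 organs).
#' @param n_stages_xy Number of in-plane down-sampling stages.
#' @param n_stages_z Number of z down-sampling stages (3D only).
#' @param kernel Convolution kernel size per spatial axis (3).
#' @param base_channels First-stage width.
#' @param channel_growth Width multiplier per stage.
#' @param max_channels Width cap.
#' @param negative_slope Leaky-ReLU slope.
#' @return A `unet_config`.
#' @export
unet_config <- function(dims = 2L, in_channels = 1L, out_channels = 5L,
                        n_stages_xy = 6L, n_stages_z = 2L, kernel = 3L,
                        base_channels = 32L, channel_growth = 2,
                        max_channels = 320L, negative_slope = 0.01) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3", call. = FALSE)
  if (dims == 3L && n_stages_z > n_stages_xy)
    stop("n_stages_z cannot exceed n_stages_xy", call. = FALSE)
  structure(list(dims = dims, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 n_stages_xy = as.integer(n_stages_xy),
                 n_stages_z = as.integer(n_stages_z),
                 kernel = as.integer(kernel),
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 max_channels = as.integer(max_channels),
                 negative_slope = negative_slope),
            class = "unet_config")
}

#' @rdname unet_config
#' @param name One of `"2d_full"`, `"3d_full"` (full-resolution widths) or
#'   `"2d_test"`, `"3d_test"` (CPU-cheap widths for desk-scale runs).
#' @export
unet_preset <- function(name = c("2d_full", "3d_full", "2d_test", "3d_test")) {
  switch(match.arg(name),
         "2d_full" = unet_config(dims = 2, n_stages_xy = 6, base_channels = 32),
         "3d_full" = unet_config(dims = 3, n_stages_xy = 6, n_stages_z = 2,
                                 base_channels = 32),
         "2d_test" = unet_config(dims = 2, n_stages_xy = 3, base_channels = 8,
                                 max_channels = 32),
         "3d_test" = unet_config(dims = 3, n_stages_xy = 3, n_stages_z = 2,
                                 base_channels = 4, max_channels = 16))
}

# realized channel width per stage (stage 1 = full resolution)
unet_channels <- function(config) {
  s <- 0:config$n_stages_xy
  pmin(as.integer(round(config$base_channels * config$channel_growth^s)),
       config$max_channels)
}

# per down-step stride as (z, y, x); step i takes level i to level i+1
unet_strides <- function(config) {
  lapply(seq_len(config$n_stages_xy), function(i) {
    if (config$dims == 3L)
      c(if (i <= config$n_stages_z) 2L else 1L, 2L, 2L)
    else c(1L, 2L, 2L)
  })
}

unet_kernel <- function(config) {
  if (config$dims == 3L) rep(config$kernel, 3L) else c(1L, config$kernel, config$kernel)
}

# Spatial extent at every resolution level for a given input, computed
# analytically from the strides; level 1 is the input, the last level the
# bottleneck. Errors if the input is not divisible by the cumulative stride.
#' @rdname unet_config
#' @param config A `unet_config`.
#' @param input_shape Spatial input shape; length 2 `(y, x)` for 2D, length
#'   3 `(z, y, x)` for 3D.
#' @export
unet_shapes <- function(config, input_shape) {
  sp <- if (config$dims == 2L) c(1L, as.integer(input_shape))
  else as.integer(input_shape)
  if (length(sp) != 3L) stop("input_shape has wrong length", call. = FALSE)
  strides <- unet_strides(config)
  levels <- vector("list", config$n_stages_xy + 1L)
  levels[[1]] <- sp
  for (i in seq_along(strides)) {
    s <- strides[[i]]
    if (any(sp %% s != 0))
      stop("configuration error: input extent (",
           paste(sp, collapse = "x"), ") not divisible by stride at stage ",
           i, "; choose a patch size divisible by the cumulative ",
           "down-sampling factor", call. = FALSE)
    sp <- sp %/% s
    levels[[i + 1]] <- sp
  }
  list(levels = levels, bottleneck = levels[[length(levels)]])
}

#' Build a U-Net with deterministic initialization
#'
#' @param config A [unet_config()].
#' @param seed Seed for He-normal weight initialization; the same
#'   `(config, seed)` builds bit-identical parameters.
#' @return A `unet_model` (parameters + config).
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  ch <- unet_channels(config)
  strides <- unet_strides(config)
  k <- unet_kernel(config)
  S <- config$n_stages_xy
  with_seed(seed, {
    params <- list()
    for (i in seq_len(S + 1L)) {
      in_a <- if (i == 1L) config$in_channels else ch[i - 1L]
      st_a <- if (i == 1L) c(1L, 1L, 1L) else strides[[i - 1L]]
      params[[paste0("enc_a_", i)]] <-
        list(conv = conv_param(in_a, ch[i], k, st_a), norm = inorm_param(ch[i]))
      params[[paste0("enc_b_", i)]] <-
        list(conv = conv_param(ch[i], ch[i], k, c(1L, 1L, 1L)),
             norm = inorm_param(ch[i]))
    }
    for (j in rev(seq_len(S))) {
      params[[paste0("up_", j)]] <- tconv_param(ch[j + 1L], ch[j], strides[[j]])
      params[[paste0("dec_a_", j)]] <-
        list(conv = conv_param(2L * ch[j], ch[j], k, c(1L, 1L, 1L)),
             norm = inorm_param(ch[j]))
      params[[paste0("dec_b_", j)]] <-
        list(conv = conv_param(ch[j], ch[j], k, c(1L, 1L, 1L)),
             norm = inorm_param(ch[j]))
    }
    params[["final"]] <- conv_param(ch[1], config$out_channels,
                                    c(1L, 1L, 1L), c(1L, 1L, 1L),
                                    pad = c(0L, 0L, 0L))
    structure(list(config = config, params = params), class = "unet_model")
  })
}

#' @rdname build_unet
#' @param model A `unet_model`.
#' @export
parameter_count <- function(model) {
  count <- 0
  walk <- function(x) {
    for (nm in names(x)) {
      if (nm %in% c("W", "b", "gamma", "beta")) count <<- count + length(x[[nm]])
      else if (is.list(x[[nm]])) walk(x[[nm]])
    }
  }
  walk(model$params)
  count
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model> ", x$config$dims, "D, stages ", x$config$n_stages_xy,
      ", channels [", paste(unet_channels(x$config), collapse = ", "),
      "], ", format(parameter_count(x), big.mark = ","), " parameters\n",
      sep = "")
  invisible(x)
}

# Forward pass. x: (in_channels, Z, Y, X). Returns logits (out_channels,
# Z, Y, X) and, with cache = TRUE, everything the backward pass needs.
unet_forward <- function(model, x, cache = FALSE) {
  cfg <- model$config
  slope <- cfg$negative_slope
  S <- cfg$n_stages_xy
  P <- model$params
  # 2D nets: per-slice instance-norm statistics (slices are independent)
  zg <- if (cfg$dims == 2L) dim(x)[2] else 1L
  caches <- if (cache) list() else NULL
  enc_out <- vector("list", S + 1L)
  h <- x
  for (i in seq_len(S + 1L)) {
    a <- block_fwd(h, P[[paste0("enc_a_", i)]], slope, zg)
    b <- block_fwd(a$y, P[[paste0("enc_b_", i)]], slope, zg)
    if (cache) {
      caches[[paste0("enc_a_", i)]] <- a$cache
      caches[[paste0("enc_b_", i)]] <- b$cache
    }
    h <- b$y
    enc_out[[i]] <- h
  }
  for (j in rev(seq_len(S))) {
    up <- tconv_fwd(h, P[[paste0("up_", j)]])
    cat_in <- concat_channels(up$y, enc_out[[j]])
    a <- block_fwd(cat_in, P[[paste0("dec_a_", j)]], slope, zg)
    b <- block_fwd(a$y, P[[paste0("dec_b_", j)]], slope, zg)
    if (cache) {
      caches[[paste0("up_", j)]] <- up$cache
      caches[[paste0("dec_a_", j)]] <- a$cache
      caches[[paste0("dec_b_", j)]] <- b$cache
    }
    h <- b$y
  }
  fin <- conv_fwd(h, P[["final"]])
  if (cache) caches[["final"]] <- fin$cache
  list(logits = fin$y, caches = caches,
       bottleneck_shape = dim(enc_out[[S + 1L]])[2:4])
}

# Backward pass from d(logits); returns gradients in the params structure.
unet_backward <- function(model, caches, dlogits) {
  cfg <- model$config
  slope <- cfg$negative_slope
  S <- cfg$n_stages_xy
  P <- model$params
  grads <- list()
  fin <- conv_bwd(dlogits, caches[["final"]], P[["final"]])
  grads[["final"]] <- fin$grads
  g <- fin$dx
  d_skip <- vector("list", S + 1L)
  for (j in seq_len(S)) {
    b <- block_bwd(g, caches[[paste0("dec_b_", j)]], P[[paste0("dec_b_", j)]], slope)
    grads[[paste0("dec_b_", j)]] <- b$grads
    a <- block_bwd(b$dx, caches[[paste0("dec_a_", j)]], P[[paste0("dec_a_", j)]], slope)
    grads[[paste0("dec_a_", j)]] <- a$grads
    cu <- P[[paste0("up_", j)]]$out_ch
    d_cat <- a$dx
    d_up <- d_cat[seq_len(cu), , , , drop = FALSE]
    d_skip[[j]] <- d_cat[cu + seq_len(dim(d_cat)[1] - cu), , , , drop = FALSE]
    up <- tconv_bwd(d_up, caches[[paste0("up_", j)]], P[[paste0("up_", j)]])
    grads[[paste0("up_", j)]] <- up$grads
    g <- up$dx
  }
  for (i in rev(seq_len(S + 1L))) {
    if (i <= S) g <- g + d_skip[[i]]
    b <- block_bwd(g, caches[[paste0("enc_b_", i)]], P[[paste0("enc_b_", i)]], slope)
    grads[[paste0("enc_b_", i)]] <- b$grads
    a <- block_bwd(b$dx, caches[[paste0("enc_a_", i)]], P[[paste0("enc_a_", i)]], slope)
    grads[[paste0("enc_a_", i)]] <- a$grads
    g <- a$dx
  }
  grads
}

as_net_input <- function(arr) {
  d <- dim(arr)
  if (length(d) == 3L) array(arr, c(1L, d)) else arr
}

#' Full-volume inference by sliding windows
#'
#' Runs the model over a (normalized, resampled) volume with overlapping
#' windows whose predictions are blended by uniform averaging; a volume
#' smaller than the window is zero-padded and the output cropped back.
#' Per-voxel class probabilities sum to 1.
#'
#' @param model A trained `unet_model`.
#' @param vol A [volume()], already z-score normalized and resampled to the
#'   spacing the model was trained at.
#' @param window Window shape (z, y, x); defaults to the whole volume,
#'   rounded up per axis to the model's down-sampling divisor (one slice
#'   per window for 2D models, matching their per-slice training regime).
#' @param overlap Fractional window overlap in (0, 1).
#' @return A `seg_probmap`: `data` of shape (5, z, y, x) plus spacing.
#' @export
predict_probabilities <- function(model, vol, window = NULL, overlap = 0.5) {
  stopifnot(inherits(model, "unet_model"), inherits(vol, "seg_volume"))
  cfg <- model$config
  sp <- dim(vol$data)
  mult <- Reduce(function(a, s) a * s, unet_strides(cfg), c(1L, 1L, 1L))
  if (is.null(window)) {
    # 2D models take all slices in one window: instance-norm statistics are
    # per slice, so the batched pass equals slice-by-slice processing
    window <- as.integer(ceiling(sp / mult) * mult)
  }
  window <- as.integer(window)
  window <- as.integer(ceiling(window / mult) * mult)
  padded_shape <- pmax(sp, window)
  arr <- pad_to(vol$data, window, 0)
  padded_shape <- dim(arr)
  step <- pmax(1L, as.integer(round(window * (1 - overlap))))
  corners <- lapply(1:3, function(ax) {
    last <- padded_shape[ax] - window[ax] + 1L
    unique(c(seq.int(1L, last, by = step[ax]), last))
  })
  nc <- cfg$out_channels
  acc <- array(0, c(nc, padded_shape))
  cnt <- array(0, padded_shape)
  for (cz in corners[[1]]) for (cy in corners[[2]]) for (cx in corners[[3]]) {
    iz <- cz + seq_len(window[1]) - 1L
    iy <- cy + seq_len(window[2]) - 1L
    ix <- cx + seq_len(window[3]) - 1L
    xin <- as_net_input(arr[iz, iy, ix, drop = FALSE])
    p <- softmax_channels(unet_forward(model, xin)$logits)
    if (any(!is.finite(p))) stop("numeric error: NaN in network output", call. = FALSE)
    acc[, iz, iy, ix] <- acc[, iz, iy, ix, drop = FALSE] + p
    cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1
  }
  prob <- acc / rep(cnt, each = nc)
  prob <- prob[, seq_len(sp[1]), seq_len(sp[2]), seq_len(sp[3]), drop = FALSE]
  structure(list(data = prob, spacing = vol$spacing, case_id = vol$case_id),
            class = "seg_probmap")
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture configuration; a human-readable
#' YAML sidecar of the configuration is written next to it.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_model <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  yaml::write_yaml(unclass(model$config), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path))
    stop("cannot load model '", path, "': no such file", call. = FALSE)
  m <- readRDS(path)
  if (!inherits(m, "unet_model"))
    stop("'", path, "' is not a unet_model checkpoint", call. = FALSE)
  m
}
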