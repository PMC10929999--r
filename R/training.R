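#' Loss configuration
#'
#' The training loss is the convex combination
#' `a * (1 - soft Dice) + (1 - a) * cross-entropy`. The Dice similarity is
#' turned into a loss as `1 - Dice` so the composite decreases during
#' training; `a` defaults to 0.5 (equal weighting).
#'
#' @param a Dice-term weight in `[0, 1]`.
#' @param smooth Dice stabilizer (> 0), added to numerator and denominator.
#' @param eps Probability clipping floor for the cross-entropy.
#' @param class_weights Optional per-class cross-entropy weights (length 5).
#' @export
loss_config <- function(a = 0.5, smooth = 1e-5, eps = 1e-7,
                        class_weights = NULL) {
  if (a < 0 || a > 1) stop("a must lie in [0, 1]", call. = FALSE)
  if (smooth <= 0) stop("smooth must be positive", call. = FALSE)
  structure(list(a = a, smooth = smooth, eps = eps,
                 class_weights = class_weights), class = "loss_config")
}

#' One-hot encode a label grid
#'
#' @param labels Integer array with values in `0:(n_classes-1)`.
#' @param n_classes Number of classes.
#' @return Array of shape `(n_classes, dim(labels))` with exactly one 1 per
#'   voxel across channels.
#' @export
one_hot <- function(labels, n_classes = 5L) {
  d <- dim(labels)
  if (is.null(d)) d <- length(labels)
  oh <- array(0, c(n_classes, d))
  oh[(seq_along(labels) - 1L) * n_classes + as.integer(labels) + 1L] <- 1
  oh
}

#' Soft Dice similarity
#'
#' Per foreground class `c`: `(2 * sum(p_c * y_c) + smooth) /
#' (sum(p_c) + sum(y_c) + smooth)`, averaged over the foreground classes
#' (channel 1 is background). Equals 1 for a perfect one-hot prediction as
#' `smooth -> 0`; on hard 0/1 inputs it coincides with the evaluation
#' module's [dsc()].
#'
#' @param probs Array `(n_classes, ...)` of class probabilities.
#' @param target One-hot array of the same shape.
#' @param smooth Stabilizer.
#' @param per_class Return the per-class vector instead of the mean.
#' @return Similarity in `[0, 1]` (scalar, or per foreground class).
#' @export
soft_dice <- function(probs, target, smooth = 1e-5, per_class = FALSE) {
  if (!identical(dim(probs), dim(target)))
    stop("probs and target shapes differ", call. = FALSE)
  nc <- dim(probs)[1]
  pm <- matrix(probs, nrow = nc)
  ym <- matrix(target, nrow = nc)
  num <- 2 * rowSums(pm * ym) + smooth
  den <- rowSums(pm) + rowSums(ym) + smooth
  d <- (num / den)[-1]
  if (per_class) d else mean(d)
}

#' Cross-entropy loss
#'
#' The categorical form (default) is the mean over voxels of
#' `-sum_c w_c * y_c * log(p_c)`: zero (up to clipping) iff the prediction
#' equals the target, `log(5)` per voxel for a uniform 5-class prediction.
#' The `"binary"` form is the printed two-term expression
#' `-mean[y log p + (1-y) log(1-p)]` taken over all one-hot entries; in the
#' two-class limit the two forms coincide.
#'
#' @inheritParams soft_dice
#' @param class_weights Optional per-class weights (categorical form).
#' @param eps Clipping floor.
#' @param form `"categorical"` or `"binary"`.
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(probs, target, class_weights = NULL, eps = 1e-7,
                          form = c("categorical", "binary")) {
  form <- match.arg(form)
  if (!identical(dim(probs), dim(target)))
    stop("probs and target shapes differ", call. = FALSE)
  nc <- dim(probs)[1]
  pm <- pmin(pmax(matrix(probs, nrow = nc), eps), 1 - eps)
  ym <- matrix(target, nrow = nc)
  out <- if (form == "categorical") {
    w <- if (is.null(class_weights)) rep(1, nc) else class_weights
    mean(colSums(-w * ym * log(pm)))
  } else {
    -mean(ym * log(pm) + (1 - ym) * log(1 - pm))
  }
  if (!is.finite(out)) stop("numeric error: cross-entropy is not finite", call. = FALSE)
  out
}

#' Composite segmentation loss
#'
#' `a * (1 - soft_dice) + (1 - a) * cross_entropy`. Reduces exactly to the
#' Dice loss at `a = 1` and to the cross-entropy at `a = 0`; non-negative
#' and minimized at the perfect prediction.
#'
#' @inheritParams soft_dice
#' @param config A [loss_config()].
#' @export
composite_loss <- function(probs, target, config = loss_config()) {
  stopifnot(inherits(config, "loss_config"))
  ld <- 1 - soft_dice(probs, target, config$smooth)
  lc <- cross_entropy(probs, target, config$class_weights, config$eps)
  config$a * ld + (1 - config$a) * lc
}

# Loss + gradient w.r.t. logits, for the training loop.
loss_and_grad <- function(logits, target, config) {
  nc <- dim(logits)[1]
  p <- softmax_channels(logits)
  pm <- matrix(p, nrow = nc)
  ym <- matrix(target, nrow = nc)
  L <- ncol(pm)
  s <- config$smooth
  num <- 2 * rowSums(pm * ym) + s
  den <- rowSums(pm) + rowSums(ym) + s
  nfg <- nc - 1L
  loss_dice <- 1 - mean((num / den)[-1])
  # d(1 - mean dice)/dp per class; background channel contributes nothing
  gd <- -(2 * ym * den - num) / (den^2 * nfg)
  gd[1, ] <- 0
  eps <- config$eps
  pc <- pmin(pmax(pm, eps), 1 - eps)
  w <- if (is.null(config$class_weights)) rep(1, nc) else config$class_weights
  loss_ce <- mean(colSums(-w * ym * log(pc)))
  gc <- -(w * ym) / (pc * L)
  a <- config$a
  g <- a * gd + (1 - a) * gc
  gp <- colSums(g * pm)
  dz <- pm * (g - rep(gp, each = nc))
  dim(dz) <- dim(logits)
  list(loss = a * loss_dice + (1 - a) * loss_ce, dlogits = dz,
       loss_dice = loss_dice, loss_ce = loss_ce)
}

#' Build cross-validation folds
#'
#' Random permutation followed by round-robin assignment: folds partition
#' the cases with sizes differing by at most one; deterministic under
#' `seed`. Each case serves in exactly one validation fold across the `k`
#' training runs.
#'
#' @param case_ids Character vector of case identifiers.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return A `fold_split`: list with `k`, named integer `assignment`, `seed`.
#' @examples
#' fs <- make_folds(sprintf("case_%02d", 1:50), k = 5, seed = 1)
#' table(fs$assignment)
#' @export
make_folds <- function(case_ids, k = 5L, seed = 1L) {
  n <- length(case_ids)
  if (n < k)
    stop("need at least k = ", k, " cases, got ", n, call. = FALSE)
  if (anyDuplicated(case_ids)) stop("case_ids must be unique", call. = FALSE)
  with_seed(seed, {
    perm <- sample(case_ids)
    assignment <- rep_len(seq_len(k), n)
    names(assignment) <- perm
    assignment <- assignment[case_ids]
    structure(list(k = as.integer(k), assignment = assignment,
                   seed = as.integer(seed)), class = "fold_split")
  })
}

#' Training configuration
#'
#' @param epochs Number of epochs (>= 1).
#' @param learning_rate Initial Adam learning rate (> 0).
#' @param batch_size Patches per optimizer step.
#' @param batches_per_epoch Optimizer steps per epoch; `NULL` (default)
#'   scales with the training-set size as `max(40, 3 * n_cases)` (capped at
#'   120) so larger training sets are not silently under-trained by a
#'   fixed step count.
#' @param patch_size Patch shape (z, y, x); z = 1 for 2D training.
#' @param fg_fraction Fraction of patch draws centered on foreground.
#' @param fg_balanced Class-balanced foreground draws (see
#'   [extract_patch()]).
#' @param augment Apply random rotation + translation jitter.
#' @param max_rotation_deg,max_jitter_vox Augmentation ranges.
#' @param lr_schedule `"poly"` (`lr * (1 - epoch/epochs)^0.9`) or
#'   `"constant"`.
#' @param balance_class_weights If the loss config carries no explicit
#'   class weights, derive cross-entropy weights from the training labels
#'   as `1/sqrt(class frequency)` (normalized to background = 1). Guards
#'   rare classes (femoral heads, intestine lobes occupy well under 1% of
#'   voxels) against dead-class collapse under the softmax.
#' @param val_patches Patches drawn from the validation cases to score each
#'   epoch's mean foreground Dice (used for best-checkpoint selection).
#' @param seed RNG seed for the whole run (init, sampling, augmentation).
#' @export
train_config <- function(epochs = 10L, learning_rate = 0.01, batch_size = 4L,
                         batches_per_epoch = NULL, patch_size = c(1L, 32L, 32L),
                         fg_fraction = 0.5, fg_balanced = TRUE,
                         augment = TRUE,
                         max_rotation_deg = 15, max_jitter_vox = 2,
                         lr_schedule = c("poly", "constant"),
                         balance_class_weights = TRUE,
                         val_patches = 16L, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 optimizer = "adam", batch_size = as.integer(batch_size),
                 batches_per_epoch = if (is.null(batches_per_epoch)) NULL
                 else as.integer(batches_per_epoch),
                 patch_size = as.integer(patch_size),
                 fg_fraction = fg_fraction, fg_balanced = isTRUE(fg_balanced),
                 augment = isTRUE(augment),
                 max_rotation_deg = max_rotation_deg,
                 max_jitter_vox = max_jitter_vox,
                 lr_schedule = match.arg(lr_schedule),
                 balance_class_weights = isTRUE(balance_class_weights),
                 val_patches = as.integer(val_patches),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' @rdname train_config
#' @param name `"test"` (desk-scale), `"2d_full"` or `"3d_full"` (the
#'   full-resolution hyperparameters: 250 epochs, initial learning rate
#'   0.01, Adam; batch 12 at 512x512 for 2D, batch 2 at 32x256x256 for 3D).
#' @export
train_preset <- function(name = c("test", "2d_full", "3d_full")) {
  switch(match.arg(name),
         "test" = train_config(),
         "2d_full" = train_config(epochs = 250L, learning_rate = 0.01,
                                  batch_size = 12L, batches_per_epoch = 250L,
                                  patch_size = c(1L, 512L, 512L)),
         "3d_full" = train_config(epochs = 250L, learning_rate = 0.01,
                                  batch_size = 2L, batches_per_epoch = 250L,
                                  patch_size = c(32L, 256L, 256L)))
}

# --- Adam over the nested parameter/gradient structure ------------------

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) add_grads(a[[nm]], b[[nm]])
    else a[[nm]] + b[[nm]]
  }
  a
}

scale_grads <- function(g, f) rapply(g, function(x) x * f, how = "replace")

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) {
        res <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- res$p
        s[[nm]] <- res$s
      } else {
        m <- beta1 * s[[nm]]$m + (1 - beta1) * g[[nm]]
        v <- beta2 * s[[nm]]$v + (1 - beta2) * g[[nm]]^2
        mhat <- m / (1 - beta1^t)
        vhat <- v / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        s[[nm]] <- list(m = m, v = v)
      }
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

init_adam_state <- function(grads)
  rapply(grads, function(x) list(m = x * 0, v = x * 0), how = "replace")

# hard mean foreground Dice of argmax predictions on sampled patches
validation_dice <- function(model, cases, tc) {
  if (length(cases) == 0L || tc$val_patches == 0L) return(NA_real_)
  scores <- numeric(0)
  for (i in seq_len(tc$val_patches)) {
    cs <- cases[[((i - 1L) %% length(cases)) + 1L]]
    pt <- extract_patch(cs$image, cs$labels, tc$patch_size,
                        fg_fraction = 0.75, fg_balanced = TRUE)
    logits <- unet_forward(model, as_net_input(pt$image))$logits
    pred <- apply_argmax(softmax_channels(logits))
    present <- sort(unique(c(pt$labels)))
    present <- present[present > 0L]
    if (length(present) == 0L) next
    d <- vapply(present, function(cl)
      dsc(pred == cl, pt$labels == cl), numeric(1))
    scores <- c(scores, mean(d))
  }
  if (length(scores) == 0L) NA_real_ else mean(scores)
}

apply_argmax <- function(prob) {
  nc <- dim(prob)[1]
  m <- matrix(prob, nrow = nc)
  lab <- max.col(t(m), ties.method = "first") - 1L
  array(as.integer(lab), dim(prob)[-1])
}

#' Train a segmentation model
#'
#' Runs the epoch loop: random patch sampling with foreground oversampling
#' and augmentation, composite-loss backpropagation, Adam updates with the
#' configured learning-rate schedule, per-epoch training-loss and
#' validation-Dice logging, and best-validation checkpoint selection. Fixed
#' seeds reproduce the run.
#'
#' @param train_cases List of cases, each a list with `image` (normalized
#'   3D array) and `labels` (integer 3D array).
#' @param val_cases Like `train_cases`; may be empty (best checkpoint then
#'   falls back to lowest training loss).
#' @param net_config A [unet_config()].
#' @param tc A [train_config()].
#' @param lc A [loss_config()].
#' @param checkpoint_path Optional path; the best model is saved there.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint), `history` (data frame of
#'   epoch, loss, val_dsc, lr), and `best_epoch`.
#' @export
train_model <- function(train_cases, val_cases = list(), net_config,
                        tc = train_config(), lc = loss_config(),
                        checkpoint_path = NULL, verbose = FALSE) {
  if (length(train_cases) < 1L) stop("need at least one training case", call. = FALSE)
  unet_shapes(net_config, if (net_config$dims == 2L) tc$patch_size[2:3]
              else tc$patch_size)  # fail early on indivisible patch
  if (is.null(tc$batches_per_epoch))
    tc$batches_per_epoch <- min(120L, max(40L, 3L * length(train_cases)))
  if (isTRUE(tc$balance_class_weights) && is.null(lc$class_weights)) {
    freq <- rep(0, net_config$out_channels)
    for (cs in train_cases)
      freq <- freq + tabulate(cs$labels + 1L, net_config$out_channels)
    w <- 1 / sqrt(pmax(freq, 1) / sum(freq))
    # normalize to mean 1 so weighting rebalances classes without
    # inflating the overall cross-entropy gradient scale
    lc$class_weights <- w / mean(w)
  }
  with_seed(stable_hash(tc$seed, "train"), {
    model <- build_unet(net_config, seed = stable_hash(tc$seed, "init"))
    state <- NULL
    t <- 0L
    history <- data.frame(epoch = integer(), loss = numeric(),
                          val_dsc = numeric(), lr = numeric())
    best <- list(score = -Inf, loss = Inf, params = model$params, epoch = 0L)
    for (epoch in seq_len(tc$epochs)) {
      lr_e <- if (tc$lr_schedule == "poly")
        tc$learning_rate * (1 - (epoch - 1) / tc$epochs)^0.9
      else tc$learning_rate
      ep_losses <- numeric(tc$batches_per_epoch)
      nc_out <- net_config$out_channels
      # 2D nets process the whole batch in one pass by stacking patches
      # along z (slices are independent and instance norm is per slice, so
      # this is exactly equivalent to per-patch passes, just faster)
      stack_z <- net_config$dims == 2L && tc$patch_size[1] == 1L
      for (b in seq_len(tc$batches_per_epoch)) {
        pts <- lapply(seq_len(tc$batch_size), function(i) {
          cs <- train_cases[[sample.int(length(train_cases), 1L)]]
          pt <- extract_patch(cs$image, cs$labels, tc$patch_size,
                              fg_fraction = tc$fg_fraction,
                              fg_balanced = tc$fg_balanced)
          if (tc$augment)
            pt <- augment_patch(pt, tc$max_rotation_deg, tc$max_jitter_vox)
          pt
        })
        B <- tc$batch_size
        if (stack_z) {
          py <- tc$patch_size[2]; px <- tc$patch_size[3]
          x <- array(0, c(1L, B, py, px))
          for (i in seq_len(B)) x[1L, i, , ] <- pts[[i]]$image[1L, , ]
          fw <- unet_forward(model, x, cache = TRUE)
          dl <- array(0, dim(fw$logits))
          lsum <- 0
          for (i in seq_len(B)) {
            lg <- loss_and_grad(fw$logits[, i, , , drop = FALSE],
                                one_hot(pts[[i]]$labels, nc_out), lc)
            if (!is.finite(lg$loss))
              stop("training diverged: non-finite loss at epoch ", epoch,
                   ", batch ", b, call. = FALSE)
            lsum <- lsum + lg$loss
            dl[, i, , ] <- lg$dlogits
          }
          gbar <- unet_backward(model, fw$caches, dl / B)
        } else {
          gsum <- NULL
          lsum <- 0
          for (i in seq_len(B)) {
            fw <- unet_forward(model, as_net_input(pts[[i]]$image),
                               cache = TRUE)
            lg <- loss_and_grad(fw$logits, one_hot(pts[[i]]$labels, nc_out),
                                lc)
            if (!is.finite(lg$loss))
              stop("training diverged: non-finite loss at epoch ", epoch,
                   ", batch ", b, call. = FALSE)
            lsum <- lsum + lg$loss
            gsum <- add_grads(gsum, unet_backward(model, fw$caches,
                                                  lg$dlogits))
          }
          gbar <- scale_grads(gsum, 1 / B)
        }
        if (is.null(state)) state <- init_adam_state(gbar)
        t <- t + 1L
        upd <- adam_step(model$params, gbar, state, lr_e, t)
        model$params <- upd$p
        state <- upd$s
        ep_losses[b] <- lsum / B
      }
      vd <- validation_dice(model, val_cases, tc)
      mloss <- mean(ep_losses)
      history <- rbind(history, data.frame(epoch = epoch, loss = mloss,
                                           val_dsc = vd, lr = lr_e))
      improved <- if (is.na(vd)) mloss < best$loss else vd >= best$score
      if (improved) {
        best <- list(score = if (is.na(vd)) -Inf else vd, loss = mloss,
                     params = model$params, epoch = epoch)
      }
      if (verbose)
        message(sprintf("epoch %d/%d loss %.4f val_dsc %s", epoch, tc$epochs,
                        mloss, ifelse(is.na(vd), "NA", sprintf("%.3f", vd))))
    }
    model$params <- best$params
    if (!is.null(checkpoint_path)) save_model(model, checkpoint_path)
    list(model = model, history = history, best_epoch = best$epoch)
  })
}
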