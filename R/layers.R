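# Layer primitives for the U-Nets. Feature maps are (C, Z, Y, X) arrays;
# a 2D network is the z-size-1, kernel-z-1 special case, so one code path
# serves both dimensionalities. Convolutions go through im2col + BLAS
# matmul; transposed convolutions (kernel == stride) through the adjoint
# fold, which is overlap-free. All backward passes are exercised by
# finite-difference gradient checks in the test suite.

conv_param <- function(in_ch, out_ch, kernel, stride, pad = (kernel - 1L) %/% 2L) {
  fan_in <- in_ch * prod(kernel)
  list(W = matrix(rnorm(out_ch * fan_in, 0, sqrt(2 / fan_in)), out_ch, fan_in),
       b = numeric(out_ch),
       kernel = as.integer(kernel), stride = as.integer(stride),
       pad = as.integer(pad), in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch))
}

tconv_param <- function(in_ch, out_ch, stride) {
  k <- prod(stride)
  fan_in <- in_ch
  list(W = matrix(rnorm(in_ch * out_ch * k, 0, sqrt(2 / fan_in)),
                  in_ch, out_ch * k),
       b = numeric(out_ch),
       stride = as.integer(stride), in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch))
}

inorm_param <- function(ch) list(gamma = rep(1, ch), beta = numeric(ch))

conv_fwd <- function(x, p) {
  din <- dim(x)
  cols <- im2col_cpp(x, din, p$kernel, p$stride, p$pad)
  out_sp <- (din[2:4] + 2L * p$pad - p$kernel) %/% p$stride + 1L
  z <- p$W %*% cols + p$b
  dim(z) <- c(p$out_ch, out_sp)
  list(y = z, cache = list(cols = cols, din = din))
}

conv_bwd <- function(dy, cache, p) {
  dy_m <- matrix(dy, nrow = p$out_ch)
  dW <- tcrossprod(dy_m, cache$cols)
  db <- rowSums(dy_m)
  dcols <- crossprod(p$W, dy_m)
  dx <- col2im_cpp(dcols, cache$din, p$kernel, p$stride, p$pad)
  list(dx = dx, grads = list(W = dW, b = db))
}

tconv_fwd <- function(x, p) {
  din <- dim(x)
  out_sp <- din[2:4] * p$stride
  x_m <- matrix(x, nrow = p$in_ch)
  ycols <- crossprod(p$W, x_m)
  y <- col2im_cpp(ycols, c(p$out_ch, out_sp), p$stride, p$stride,
                  c(0L, 0L, 0L))
  y_m <- matrix(y, nrow = p$out_ch) + p$b
  dim(y_m) <- c(p$out_ch, out_sp)
  list(y = y_m, cache = list(x_m = x_m, din = din, out_sp = out_sp))
}

tconv_bwd <- function(dy, cache, p) {
  dy_m <- matrix(dy, nrow = p$out_ch)
  db <- rowSums(dy_m)
  dim(dy) <- c(p$out_ch, cache$out_sp)
  dycols <- im2col_cpp(dy, c(p$out_ch, cache$out_sp), p$stride, p$stride,
                       c(0L, 0L, 0L))
  dW <- tcrossprod(cache$x_m, dycols)
  dx_m <- p$W %*% dycols
  dim(dx_m) <- cache$din
  list(dx = dx_m, grads = list(W = dW, b = db))
}

# Instance norm + leaky ReLU live in C++ (inorm_lrelu_fwd_cpp /
# inorm_lrelu_bwd_cpp). For 2D networks the z axis is never convolved, so
# slices are independent end to end; statistics per (channel, slice)
# (zgroups = Z) make a z-stacked pass bit-identical to per-slice passes,
# which is how whole volumes and patch batches go through the 2D network
# in one call. 3D networks use zgroups = 1 (full spatial statistics).
IN_EPS <- 1e-5

# conv -> instance norm -> leaky ReLU (norm + activation fused in C++)
block_fwd <- function(x, p, slope, zgroups = 1L) {
  cv <- conv_fwd(x, p$conv)
  d <- dim(cv$y)
  nm <- inorm_lrelu_fwd_cpp(cv$y, d, p$norm$gamma, p$norm$beta,
                            zgroups, slope, IN_EPS)
  list(y = nm$y, cache = list(conv = cv$cache, xhat = nm$xhat,
                              istd = nm$istd, d = d, zgroups = zgroups))
}

block_bwd <- function(dy, cache, p, slope) {
  nb <- inorm_lrelu_bwd_cpp(dy, cache$xhat, cache$istd, cache$d,
                            p$norm$gamma, p$norm$beta, cache$zgroups, slope)
  cb <- conv_bwd(nb$dx, cache$conv, p$conv)
  list(dx = cb$dx,
       grads = list(conv = cb$grads,
                    norm = list(gamma = nb$dgamma, beta = nb$dbeta)))
}

softmax_channels <- function(z) {
  d <- dim(z)
  nc <- d[1]
  zm <- matrix(z, nrow = nc)
  mx <- zm[1, ]
  for (i in seq_len(nc)[-1]) mx <- pmax(mx, zm[i, ])
  zm <- exp(zm - rep(mx, each = nc))
  p <- zm / rep(colSums(zm), each = nc)
  dim(p) <- d
  p
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2:4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}
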