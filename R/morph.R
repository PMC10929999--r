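# Shift-based binary morphology on (z, y, x) logical arrays. Structuring
# element = discrete ball of integer offsets with dz^2+dy^2+dx^2 <= r^2,
# in voxel units (index space, not mm).

ball_offsets <- function(radius) {
  r <- as.integer(radius)
  if (r <= 0L) return(matrix(0L, 1, 3))
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g <- g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

shift_array <- function(mask, dz, dy, dx, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, d)
  lo <- pmax(1, 1 - c(dz, dy, dx))
  hi <- pmin(d, d - c(dz, dy, dx))
  if (any(lo > hi)) return(out)
  src_z <- lo[1]:hi[1]; src_y <- lo[2]:hi[2]; src_x <- lo[3]:hi[3]
  out[src_z + dz, src_y + dy, src_x + dx] <- mask[src_z, src_y, src_x]
  out
}

# in-plane (dz = 0) disk offsets, for slice-wise operations
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  if (r <= 0L) return(matrix(0L, 1, 3))
  g <- expand.grid(dz = 0L, dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

erode_offsets <- function(mask, offs) {
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_array(mask, -offs[i, 1], -offs[i, 2], -offs[i, 3],
                             fill = FALSE)
  out & mask
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  offs <- ball_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_array(mask, offs[i, 1], offs[i, 2], offs[i, 3])
  out
}

binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !binary_dilate(!mask, radius)
}

# Connected components; connectivity "face" (6) or "full" (26, default).
label_components <- function(mask, connectivity = 26L) {
  cc_label_cpp(as.logical(mask), as.integer(dim(mask)), as.integer(connectivity))
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash used to derive per-case sub-seeds.
stable_hash <- function(...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "|")) else as.numeric(p)
  }))
  h <- 104729
  for (v in parts) h <- (h * 31 + (v %% 65521)) %% 2147483563
  as.integer(h %% 2147483562) + 1L
}
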