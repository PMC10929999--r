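# Independent pure-R oracles used to validate the package's implementations.
# Deliberately naive (BFS queues, outer-product distance matrices, explicit
# loops): correctness over speed, kept independent of the package internals.

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  g <- g[m > 0 & (connectivity == 26 | m == 1), , drop = FALSE]
  as.matrix(g)
}

# connected-component labelling by plain BFS
oracle_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(mask)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(cur, d)
      for (r in seq_len(nrow(offs))) {
        nb <- ci + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        j <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# background voxels reachable from the grid border by face steps
oracle_border_reachable <- function(mask) {
  d <- dim(mask)
  bg <- oracle_components(!mask, connectivity = 6)
  on_border <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                        bg[, , 1], bg[, , d[3]]))
  array(bg > 0 & bg %in% on_border[on_border > 0], d)
}

# enclosed cavities = background not reachable from the border
oracle_cavities <- function(mask) {
  (!mask) & !oracle_border_reachable(mask)
}

# brute-force surface points: explicit 6-neighbor scan per foreground voxel
oracle_surface_points <- function(mask, spacing) {
  d <- dim(mask)
  pts <- NULL
  offs <- neighbor_offsets(6)
  for (i in which(mask != 0)) {
    ci <- arrayInd(i, d)
    boundary <- FALSE
    for (r in seq_len(nrow(offs))) {
      nb <- ci + offs[r, ]
      if (any(nb < 1) || any(nb > d) || !mask[nb[1], nb[2], nb[3]]) {
        boundary <- TRUE
        break
      }
    }
    if (boundary) pts <- rbind(pts, (ci - 1) * spacing)
  }
  pts
}

oracle_pairwise_dists <- function(a, b) {
  # n x m Euclidean distances, one row at a time with direct differences
  t(vapply(seq_len(nrow(a)), function(i)
    sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2),
    numeric(nrow(b))))
}

oracle_surface_metrics <- function(p_mask, g_mask, spacing) {
  sp <- oracle_surface_points(p_mask, spacing)
  sg <- oracle_surface_points(g_mask, spacing)
  dmat <- oracle_pairwise_dists(sp, sg)
  d_pg <- apply(dmat, 1, min)
  d_gp <- apply(dmat, 2, min)
  list(hd = max(max(d_pg), max(d_gp)),
       hd95 = unname(quantile(c(d_pg, d_gp), 0.95, type = 7)),
       asd = (sum(d_pg) + sum(d_gp)) / (length(d_pg) + length(d_gp)))
}

# random blobby mask: union of a few random balls, possibly empty-safe
random_mask <- function(shape, n_balls = 3, r_range = c(1, 3)) {
  m <- array(FALSE, shape)
  ax <- lapply(shape, seq_len)
  gz <- array(ax[[1]], shape)
  gy <- array(rep(ax[[2]], each = shape[1]), shape)
  gx <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  for (b in seq_len(n_balls)) {
    c0 <- sapply(shape, function(n) sample.int(n, 1))
    r <- runif(1, r_range[1], r_range[2])
    m <- m | ((gz - c0[1])^2 + (gy - c0[2])^2 + (gx - c0[3])^2 <= r^2)
  }
  m
}

tiny_phantom_config <- function(seed = 1, grid = c(8L, 32L, 32L))
  phantom_config(grid_shape = grid, seed = seed)

# small in-memory training cases from phantoms
phantom_cases <- function(n, seed = 1, grid = c(12L, 48L, 48L)) {
  cfg <- phantom_config(grid_shape = grid, seed = seed)
  lapply(seq_len(n), function(i) {
    ph <- generate_phantom(cfg, sprintf("hc_%02d", i))
    list(image = zscore_normalize(ph$image)$data, labels = ph$labels$data,
         phantom = ph)
  })
}
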