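#' Synthetic anisotropic pelvic phantom configuration
#'
#' The phantom emulates the geometry of a pelvic T2-weighted acquisition:
#' thick slices (z) with fine in-plane resolution, and four non-overlapping
#' organ-like structures labeled 1-4 (bladder, femoral heads, rectum, small
#' intestine). Geometry is parameterized in fractions of the physical grid
#' extent so the same configuration scales from desk-size test grids to
#' full-resolution grids.
#'
#' Organ shapes: the bladder is a superellipsoid; the femoral heads are two
#' laterally placed spheres (always two connected components); the rectum is
#' a curved tube running along z; the small intestine is a union of 3-8
#' overlapping blobs superior/anterior to the bladder. Intensities are
#' class-dependent Gaussians modulated by a smooth multiplicative bias field
#' plus global Gaussian noise.
#'
#' @param grid_shape Integer length-3 voxel counts (z, y, x), each >= 8.
#' @param spacing_mm Numeric length-3 voxel size in mm (z, y, x). The default
#'   keeps the 6.5 mm slice spacing of the emulated acquisition with in-plane
#'   spacing coarsened 4x (2.656 mm) for desk-scale grids.
#' @param organ_params Per-class shape parameter list; see Details in the
#'   package vignette. Defaults produce feasible, variable anatomy.
#' @param intensity_params List with `means` (length 5: background + 4
#'   classes), `class_sd`, `noise_sd`, `bias_amp`.
#' @param seed Integer master seed; per-case seeds are derived from it.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(24L, 96L, 96L),
                           spacing_mm = c(6.5, 2.656, 2.656),
                           organ_params = default_organ_params(),
                           intensity_params = default_intensity_params(),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be 3 integers, each >= 8", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive values", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 organ_params = organ_params,
                 intensity_params = intensity_params,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_organ_params <- function() {
  list(
    bladder = list(center = c(0.48, 0.60, 0.50), jitter = c(0.08, 0.06, 0.05),
                   radii_lo = c(0.14, 0.10, 0.10), radii_hi = c(0.24, 0.20, 0.20),
                   exponent = 2.5),
    femoral_heads = list(center = c(0.50, 0.38, 0.18), jitter = c(0.06, 0.05, 0.04),
                         radius = c(0.08, 0.14)),
    rectum = list(center_yx = c(0.28, 0.50), jitter = c(0.05, 0.05),
                  span_z = c(0.12, 0.88), radius = c(0.04, 0.075),
                  curve_amp = c(0.03, 0.09)),
    small_intestine = list(center = c(0.24, 0.74, 0.50), jitter = c(0.08, 0.05, 0.10),
                           blob_count = c(3L, 8L), blob_radius = c(0.05, 0.11),
                           blob_scatter = 0.12)
  )
}

#' @rdname phantom_config
#' @export
default_intensity_params <- function() {
  list(means = c(0.15, 0.90, 0.70, 0.40, 0.55),
       class_sd = 0.03, noise_sd = 0.08, bias_amp = 0.20)
}

# Fractional voxel-center coordinate grids (each a 3D array).
frac_grids <- function(shape, spacing) {
  ext <- shape * spacing
  fz <- ((seq_len(shape[1]) - 0.5) * spacing[1]) / ext[1]
  fy <- ((seq_len(shape[2]) - 0.5) * spacing[2]) / ext[2]
  fx <- ((seq_len(shape[3]) - 0.5) * spacing[3]) / ext[3]
  list(z = array(fz, shape),
       y = array(rep(fy, each = shape[1]), shape),
       x = array(rep(fx, each = shape[1] * shape[2]), shape),
       extent = ext)
}

check_placement <- function(organ, center, radius_frac) {
  if (any(center - radius_frac < 0.01) || any(center + radius_frac > 0.99))
    stop("phantom configuration error: ", organ,
         " placement infeasible for this grid (center ",
         paste(signif(center, 3), collapse = ", "), ", radius fraction ",
         paste(signif(radius_frac, 3), collapse = ", "), ")", call. = FALSE)
  invisible(TRUE)
}

runif1 <- function(lo, hi) lo + (hi - lo) * runif(1)

#' Generate one synthetic phantom case
#'
#' Deterministic in `(config, case_id)`: the case RNG seed is a stable hash
#' of `config$seed` and `case_id`, so identical inputs give bit-identical
#' volumes and labels while different case ids vary in shape, position and
#' intensity.
#'
#' @param config A [phantom_config()].
#' @param case_id Character identifier for the case.
#' @return A list with elements `image` ([volume()]) and `labels`
#'   ([labelmap()]), sharing shape and spacing.
#' @examples
#' ph <- generate_phantom(phantom_config(grid_shape = c(8, 32, 32)), "demo")
#' table(ph$labels$data)
#' @export
generate_phantom <- function(config, case_id = "phantom") {
  stopifnot(inherits(config, "phantom_config"))
  seed <- stable_hash(config$seed, case_id)
  with_seed(seed, {
    shape <- config$grid_shape
    sp <- config$spacing_mm
    g <- frac_grids(shape, sp)
    ext <- g$extent
    minext <- min(ext)
    op <- config$organ_params
    labels <- array(0L, shape)

    place <- function(mask, class_idx, organ, center_frac) {
      free <- mask & labels == 0L
      if (!any(free)) {
        idx <- round(center_frac * shape + 0.5)
        idx <- pmin(pmax(idx, 1), shape)
        if (labels[idx[1], idx[2], idx[3]] != 0L)
          stop("phantom configuration error: ", organ,
               " placement infeasible (no free voxel)", call. = FALSE)
        labels[idx[1], idx[2], idx[3]] <<- class_idx
      } else {
        labels[free] <<- class_idx
      }
    }

    # bladder: superellipsoid
    p <- op$bladder
    ctr <- p$center + (2 * runif(3) - 1) * p$jitter
    rad <- p$radii_lo + runif(3) * (p$radii_hi - p$radii_lo)
    check_placement("bladder", ctr, rad)
    e <- p$exponent
    m <- (abs(g$z - ctr[1]) / rad[1])^e + (abs(g$y - ctr[2]) / rad[2])^e +
      (abs(g$x - ctr[3]) / rad[3])^e
    place(m <= 1, 1L, "bladder", ctr)

    # femoral heads: two lateral spheres (mm radius, fraction of min extent)
    p <- op$femoral_heads
    r_mm <- runif1(p$radius[1], p$radius[2]) * minext
    jit <- (2 * runif(3) - 1) * p$jitter
    for (side in c(-1, 1)) {
      cx <- if (side < 0) p$center[3] else 1 - p$center[3]
      ctr <- c(p$center[1] + jit[1], p$center[2] + jit[2], cx + side * jit[3])
      check_placement("femoral_heads", ctr, r_mm / ext)
      d2 <- ((g$z - ctr[1]) * ext[1])^2 + ((g$y - ctr[2]) * ext[2])^2 +
        ((g$x - ctr[3]) * ext[3])^2
      place(d2 <= r_mm^2, 2L, "femoral_heads", ctr)
    }

    # rectum: curved tube along z
    p <- op$rectum
    cyx <- p$center_yx + (2 * runif(2) - 1) * p$jitter
    r_mm <- runif1(p$radius[1], p$radius[2]) * min(ext[2], ext[3])
    amp <- runif1(p$curve_amp[1], p$curve_amp[2])
    phase <- runif(2, 0, 2 * pi)
    check_placement("rectum", c(0.5, cyx),
                    c(0, amp + r_mm / ext[2], amp + r_mm / ext[3]))
    t <- (g$z - p$span_z[1]) / (p$span_z[2] - p$span_z[1])
    cy <- cyx[1] + amp * sin(pi * t + phase[1]) * 0.8
    cx <- cyx[2] + amp * sin(2 * pi * t + phase[2])
    d2 <- ((g$y - cy) * ext[2])^2 + ((g$x - cx) * ext[3])^2
    inz <- g$z >= p$span_z[1] & g$z <= p$span_z[2]
    place(d2 <= r_mm^2 & inz, 3L, "rectum", c(0.5, cyx))

    # small intestine: union of overlapping blobs
    p <- op$small_intestine
    ctr <- p$center + (2 * runif(3) - 1) * p$jitter
    nb <- sample(p$blob_count[1]:p$blob_count[2], 1)
    m <- array(FALSE, shape)
    for (b in seq_len(nb)) {
      bc <- ctr + (2 * runif(3) - 1) * p$blob_scatter
      br <- runif1(p$blob_radius[1], p$blob_radius[2]) * minext
      # clamp scattered blobs into the feasible band so cluster jitter can
      # never push a lobe out of the field of view
      bc <- pmin(pmax(bc, 0.012 + br / ext), 0.988 - br / ext)
      check_placement("small_intestine", bc, br / ext)
      d2 <- ((g$z - bc[1]) * ext[1])^2 + ((g$y - bc[2]) * ext[2])^2 +
        ((g$x - bc[3]) * ext[3])^2
      m <- m | (d2 <= br^2)
    }
    place(m, 4L, "small_intestine", ctr)

    # intensities: class mean + texture, x smooth bias field, + global noise
    ip <- config$intensity_params
    n <- prod(shape)
    img <- ip$means[labels + 1L] + rnorm(n, 0, ip$class_sd)
    co <- runif(6, -1, 1)
    zc <- g$z - 0.5; yc <- g$y - 0.5; xc <- g$x - 0.5
    field <- co[1] * zc + co[2] * yc + co[3] * xc +
      co[4] * zc * yc + co[5] * yc * xc + co[6] * zc * xc
    field <- field / max(abs(field))
    img <- img * (1 + ip$bias_amp * c(field)) + rnorm(n, 0, ip$noise_sd)
    img <- array(img, shape)

    list(image = volume(img, spacing = sp, case_id = case_id),
         labels = labelmap(labels, spacing = sp, case_id = case_id))
  })
}

#' Generate a phantom cohort on disk
#'
#' Writes NIfTI images for `n_labeled` labeled, `n_unlabeled` unlabeled and
#' `n_test` held-out test cases, each generated from a distinct per-case
#' sub-seed derived deterministically from `config$seed`. Labeled and test
#' cases get a `labels/` file; unlabeled cases keep their ground truth in a
#' separate `truth/` directory (available for evaluating pseudo-label
#' quality, never presented as an annotation). A JSON manifest lists every
#' case with its role, paths and sub-seed.
#'
#' @param config A [phantom_config()].
#' @param n_labeled Number of labeled training cases (>= 1).
#' @param n_unlabeled Number of unlabeled cases.
#' @param n_test Number of held-out labeled test cases.
#' @param dir Output directory.
#' @return The cohort manifest (class `seg_cohort`), invisibly also written
#'   to `file.path(dir, "manifest.json")`.
#' @export
generate_cohort <- function(config, n_labeled, n_unlabeled = 0L, n_test = 0L,
                            dir = tempfile("cohort")) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_labeled < 1L) stop("n_labeled must be >= 1", call. = FALSE)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), showWarnings = FALSE)
  if (n_unlabeled > 0)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  roles <- rep(c("labeled", "unlabeled", "test"),
               c(n_labeled, n_unlabeled, n_test))
  n <- length(roles)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    case_id <- sprintf("case_%03d", i)
    sub_seed <- stable_hash(config$seed, i)
    cfg_i <- config
    cfg_i$seed <- sub_seed
    ph <- generate_phantom(cfg_i, case_id)
    img_path <- file.path(dir, "images", paste0(case_id, ".nii.gz"))
    write_volume(ph$image, img_path)
    lab_path <- NA_character_
    truth_path <- NA_character_
    if (roles[i] %in% c("labeled", "test")) {
      lab_path <- file.path(dir, "labels", paste0(case_id, ".nii.gz"))
      write_volume(ph$labels, lab_path)
    } else {
      truth_path <- file.path(dir, "truth", paste0(case_id, ".nii.gz"))
      write_volume(ph$labels, truth_path)
    }
    rows[[i]] <- data.frame(case_id = case_id, role = roles[i],
                            seed = sub_seed, image = img_path,
                            label = lab_path, truth = truth_path,
                            stringsAsFactors = FALSE)
  }
  manifest <- structure(list(
    seed = config$seed,
    grid_shape = config$grid_shape,
    spacing_mm = config$spacing_mm,
    cases = do.call(rbind, rows)
  ), class = "seg_cohort")
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

#' @rdname generate_cohort
#' @param path Path to a cohort `manifest.json`.
#' @export
read_cohort <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$cases$label <- as.character(m$cases$label)
  m$cases$truth <- if (is.null(m$cases$truth)) NA_character_ else as.character(m$cases$truth)
  structure(m, class = "seg_cohort")
}

#' Controlled label corruptions
#'
#' Emulates the error modes of raw model predictions that post-processing is
#' designed to remove: interior cavities (holes), small spurious components
#' in the background (fragments), and in-plane boundary jitter. A zero
#' configuration is the identity. Corruption only ever touches the label
#' grid, never an intensity volume.
#'
#' @param hole_count Holes carved per organ class.
#' @param hole_radius_vox Hole ball radius, voxels.
#' @param fragment_count Spurious components added per organ class.
#' @param fragment_radius_vox Fragment ball radius, voxels.
#' @param boundary_jitter_vox Max in-plane shift applied per class, voxels.
#' @param classes Foreground classes to corrupt.
#' @param seed RNG seed.
#' @export
corruption_config <- function(hole_count = 0L, hole_radius_vox = 1L,
                              fragment_count = 0L, fragment_radius_vox = 1L,
                              boundary_jitter_vox = 0L, classes = 1:4,
                              seed = 1L) {
  stopifnot(hole_count >= 0, fragment_count >= 0, boundary_jitter_vox >= 0,
            hole_radius_vox >= 1, fragment_radius_vox >= 1)
  structure(list(hole_count = as.integer(hole_count),
                 hole_radius_vox = as.integer(hole_radius_vox),
                 fragment_count = as.integer(fragment_count),
                 fragment_radius_vox = as.integer(fragment_radius_vox),
                 boundary_jitter_vox = as.integer(boundary_jitter_vox),
                 classes = as.integer(classes), seed = as.integer(seed)),
            class = "corruption_config")
}

#' @rdname corruption_config
#' @param labels A [labelmap()].
#' @param config A [corruption_config()].
#' @return A corrupted [labelmap()] of the same shape.
#' @export
corrupt_labels <- function(labels, config) {
  stopifnot(inherits(labels, "seg_labelmap"),
            inherits(config, "corruption_config"))
  if (config$hole_count == 0L && config$fragment_count == 0L &&
      config$boundary_jitter_vox == 0L)
    return(labels)
  with_seed(config$seed, {
    lab <- labels$data
    shape <- dim(lab)
    present <- intersect(config$classes, sort(unique(c(lab))))
    present <- setdiff(present, 0L)

    if (config$hole_count > 0L) {
      r <- config$hole_radius_vox
      offs <- disk_offsets(r)
      for (cl in present) {
        mask <- lab == cl
        # holes are carved slice-wise (anisotropic voxels): an in-plane disk
        # whose ring and both z-caps stay inside the organ, so the cavity is
        # fully enclosed and recoverable by hole filling
        capped <- mask & shift_array(mask, 1L, 0L, 0L) &
          shift_array(mask, -1L, 0L, 0L)
        cand <- which(erode_offsets(capped, disk_offsets(r + 1L)))
        if (length(cand) == 0L)
          stop("degenerate corruption: hole radius ", r,
               " does not fit inside class ", cl, call. = FALSE)
        centers <- cand[sample.int(length(cand),
                                   min(config$hole_count, length(cand)))]
        for (cv in centers) {
          idx <- arrayInd(cv, shape)
          pts <- sweep(offs, 2, as.integer(idx), "+")
          lab[pts] <- 0L
        }
      }
    }

    if (config$fragment_count > 0L) {
      r <- config$fragment_radius_vox
      offs <- ball_offsets(r)
      occupied <- binary_dilate(lab > 0L, r + 2L)
      # keep fragments clear of the grid border so they are well-formed balls
      margin <- array(TRUE, shape)
      m <- r + 1L
      margin[(m + 1):(shape[1] - m), (m + 1):(shape[2] - m),
             (m + 1):(shape[3] - m)] <- FALSE
      for (cl in present) {
        for (f in seq_len(config$fragment_count)) {
          cand <- which(!occupied & !margin)
          if (length(cand) == 0L)
            stop("degenerate corruption: no room for fragment of radius ", r,
                 call. = FALSE)
          cv <- cand[sample.int(length(cand), 1L)]
          idx <- arrayInd(cv, shape)
          pts <- sweep(offs, 2, as.integer(idx), "+")
          lab[pts] <- cl
          ball <- array(FALSE, shape)
          ball[pts] <- TRUE
          occupied <- occupied | binary_dilate(ball, r + 2L)
        }
      }
    }

    if (config$boundary_jitter_vox > 0L) {
      j <- config$boundary_jitter_vox
      out <- array(0L, shape)
      for (cl in present) {
        dy <- sample(-j:j, 1L); dx <- sample(-j:j, 1L)
        m <- shift_array(lab == cl, 0L, dy, dx)
        out[m & out == 0L] <- cl
      }
      # fragments/holes of other classes already embedded in lab; retain any
      # class not listed for corruption as-is
      keep <- !(lab %in% present) & lab > 0L
      out[keep & out == 0L] <- lab[keep & out == 0L]
      lab <- out
    }

    labelmap(lab, spacing = labels$spacing, origin = labels$origin,
             case_id = labels$case_id, n_classes = labels$n_classes)
  })
}
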