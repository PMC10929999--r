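#' Binary mask repair operations
#'
#' `fill_holes` sets every background component not connected to the grid
#' border to foreground (background connectivity: faces), removing interior
#' cavities; `keep_largest_components` retains the `k` largest connected
#' components by voxel count (ties broken by earliest scan-order voxel);
#' `morphological_smooth` is a binary closing with a ball structuring
#' element (radius 0 = identity), computed in a background-padded domain so
#' that grid borders behave like open space: a solid mask is a fixed point
#' and masks touching the field-of-view edge are not eroded. All three are
#' idempotent;
#' `fill_holes` only adds voxels, `keep_largest_components` only removes.
#'
#' @param mask Logical 3D array.
#' @return Logical array of the same shape.
#' @export
fill_holes <- function(mask) {
  mask <- mask != 0
  bg <- label_components(!mask, connectivity = 6L)
  d <- dim(bg)
  border <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                     bg[, , 1], bg[, , d[3]]))
  border <- border[border > 0L]
  mask | (bg > 0L & !(bg %in% border))
}

#' @rdname fill_holes
#' @param k Number of components to keep (>= 1, or `Inf` for all).
#' @param connectivity `"full"` (faces+edges+corners, 26-neighborhood,
#'   default) or `"face"` (6-neighborhood).
#' @export
keep_largest_components <- function(mask, k = 1, connectivity = c("full", "face")) {
  connectivity <- match.arg(connectivity)
  mask <- mask != 0
  if (!any(mask)) {
    warning("keep_largest_components: empty mask", call. = FALSE)
    return(structure(mask, empty_input = TRUE))
  }
  if (!is.finite(k)) return(mask)
  if (k < 1) stop("k must be >= 1 or Inf", call. = FALSE)
  conn <- if (connectivity == "full") 26L else 6L
  lab <- label_components(mask, connectivity = conn)
  sizes <- tabulate(lab[lab > 0L])
  # component ids are assigned in first-encounter scan order, so ordering by
  # (size desc, id asc) breaks ties toward the earliest scan-order voxel
  keep <- order(-sizes, seq_along(sizes))[seq_len(min(k, length(sizes)))]
  array(lab %in% keep, dim(mask))
}

#' @rdname fill_holes
#' @param radius_vox Ball radius of the closing, voxels.
#' @export
morphological_smooth <- function(mask, radius_vox = 0L) {
  mask <- mask != 0
  r <- as.integer(radius_vox)
  if (r <= 0L) return(mask)
  d <- dim(mask)
  padded <- array(FALSE, d + 2L * r)
  padded[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])] <- mask
  closed <- binary_erode(binary_dilate(padded, r), r)
  closed[r + seq_len(d[1]), r + seq_len(d[2]), r + seq_len(d[3])]
}

#' Per-class post-processing rules
#'
#' Component budgets default to the anatomical expectation: one bladder,
#' two femoral heads (bilateral), one rectum, unlimited small-intestine
#' lobes. "Largest-component retention" is the reading of the
#' maximum-region filtering step; see the vignette.
#'
#' @param keep_components Numeric length-4 per-class component budget
#'   (classes 1-4; `Inf` = unlimited).
#' @param fill_holes Logical, fill interior cavities per class.
#' @param closing_radius_vox Ball radius of the per-class closing (0 = off).
#' @param connectivity `"full"` (26) or `"face"` (6) for components.
#' @export
postprocess_rules <- function(keep_components = c(1, 2, 1, Inf),
                              fill_holes = TRUE, closing_radius_vox = 0L,
                              connectivity = c("full", "face")) {
  stopifnot(length(keep_components) == 4L, all(keep_components >= 1))
  structure(list(keep_components = keep_components,
                 fill_holes = isTRUE(fill_holes),
                 closing_radius_vox = as.integer(closing_radius_vox),
                 connectivity = match.arg(connectivity)),
            class = "postprocess_rules")
}

#' Repair a multi-class label map
#'
#' For each foreground class in index order: binarize, fill holes, keep the
#' class's component budget, apply the closing, and write back. Overlaps
#' created by the closing are resolved first-writer-wins in class order, so
#' the per-voxel single-class invariant is preserved; background is the
#' complement.
#'
#' @param labels A [labelmap()].
#' @param rules A [postprocess_rules()].
#' @return A repaired [labelmap()].
#' @export
postprocess_labelmap <- function(labels, rules = postprocess_rules()) {
  stopifnot(inherits(labels, "seg_labelmap"),
            inherits(rules, "postprocess_rules"))
  out <- array(0L, dim(labels$data))
  for (cl in 1:4) {
    m <- labels$data == cl
    if (!any(m)) next
    if (rules$fill_holes) m <- fill_holes(m)
    m <- suppressWarnings(
      keep_largest_components(m, rules$keep_components[cl], rules$connectivity))
    m <- morphological_smooth(m, rules$closing_radius_vox)
    out[m & out == 0L] <- cl
  }
  labelmap(out, spacing = labels$spacing, origin = labels$origin,
           case_id = labels$case_id, n_classes = labels$n_classes)
}
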