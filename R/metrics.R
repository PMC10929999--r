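#' Dice similarity coefficient
#'
#' Volumetric overlap `2|P ∩ G| / (|P| + |G|)`: 1 means identical masks, 0
#' disjoint masks. Both masks empty gives 1 by convention; exactly one
#' empty gives 0.
#'
#' @param pred_mask,ref_mask Logical (or 0/1) arrays of equal shape.
#' @return Value in `[0, 1]`.
#' @examples
#' m <- array(FALSE, c(2, 4, 4)); m[1, 1:2, 1:2] <- TRUE
#' dsc(m, m)
#' @export
dsc <- function(pred_mask, ref_mask) {
  if (!identical(dim(pred_mask), dim(ref_mask)))
    stop("mask shapes differ", call. = FALSE)
  p <- sum(pred_mask != 0)
  g <- sum(ref_mask != 0)
  if (p + g == 0) return(1)
  2 * sum(pred_mask != 0 & ref_mask != 0) / (p + g)
}

#' Surface points of a binary mask
#'
#' Boundary voxels are foreground voxels with at least one non-foreground
#' face neighbor; voxels on the grid edge count as boundary. Coordinates
#' are voxel centers in physical mm (0-based index times spacing).
#'
#' @param mask Logical 3D array (z, y, x).
#' @param spacing_mm Voxel spacing (z, y, x), mm.
#' @return Numeric matrix (n x 3) of mm coordinates.
#' @export
surface_points <- function(mask, spacing_mm) {
  mask <- mask != 0
  if (!any(mask)) stop("surface of an empty mask is undefined", call. = FALSE)
  interior <- array(TRUE, dim(mask))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    off <- integer(3); off[ax] <- s
    interior <- interior & shift_array(mask, off[1], off[2], off[3], fill = FALSE)
  }
  boundary <- mask & !interior
  idx <- which(boundary)
  ci <- arrayInd(idx, dim(mask)) - 1L
  sweep(ci, 2, as.numeric(spacing_mm), "*")
}

surface_distances <- function(pred_mask, ref_mask, spacing_mm) {
  sp <- surface_points(pred_mask, spacing_mm)
  sg <- surface_points(ref_mask, spacing_mm)
  list(d_pg = nn_min_dists_cpp(sp, sg), d_gp = nn_min_dists_cpp(sg, sp))
}

check_distance_masks <- function(pred_mask, ref_mask, what) {
  if (!identical(dim(pred_mask), dim(ref_mask)))
    stop("mask shapes differ", call. = FALSE)
  if (!any(pred_mask != 0) || !any(ref_mask != 0)) {
    warning(what, " is undefined for an empty mask; returning NA",
            call. = FALSE)
    return(FALSE)
  }
  TRUE
}

#' Surface distance metrics
#'
#' `hausdorff_distance` is the symmetric maximum of the two directed
#' max-min Euclidean surface distances; `hd95` the 95th percentile (linear
#' interpolation) of the pooled directed nearest-surface distances; `asd`
#' the sum of both directed nearest-distance sums divided by the total
#' surface point count. All in mm, spacing-aware. An empty mask makes the
#' metric undefined: `NA` is returned with a warning, never a silent 0.
#'
#' @inheritParams surface_points
#' @param pred_mask,ref_mask Logical 3D arrays of equal shape.
#' @return Distance in mm, or `NA` if undefined.
#' @export
hausdorff_distance <- function(pred_mask, ref_mask, spacing_mm) {
  if (!check_distance_masks(pred_mask, ref_mask, "Hausdorff distance"))
    return(NA_real_)
  d <- surface_distances(pred_mask, ref_mask, spacing_mm)
  max(max(d$d_pg), max(d$d_gp))
}

#' @rdname hausdorff_distance
#' @export
hd95 <- function(pred_mask, ref_mask, spacing_mm) {
  if (!check_distance_masks(pred_mask, ref_mask, "HD95")) return(NA_real_)
  d <- surface_distances(pred_mask, ref_mask, spacing_mm)
  unname(quantile(c(d$d_pg, d$d_gp), 0.95, type = 7))
}

#' @rdname hausdorff_distance
#' @export
asd <- function(pred_mask, ref_mask, spacing_mm) {
  if (!check_distance_masks(pred_mask, ref_mask, "ASD")) return(NA_real_)
  d <- surface_distances(pred_mask, ref_mask, spacing_mm)
  (sum(d$d_pg) + sum(d$d_gp)) / (length(d$d_pg) + length(d$d_gp))
}

#' Expert revision score
#'
#' Six-bin scale for the volumetric fraction of a contour requiring manual
#' revision: no revision scores 5, then each further 20% band scores one
#' point less, down to 0 for more than 80%.
#'
#' @param revised_volume_fraction Fraction in `[0, 1]` (vectorized).
#' @return Integer score(s) in `0:5`.
#' @examples
#' revision_score(c(0, 0.3, 1))
#' @export
revision_score <- function(revised_volume_fraction) {
  f <- revised_volume_fraction
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("revised fraction must lie in [0, 1]", call. = FALSE)
  as.integer(ifelse(f == 0, 5L, 5L - ceiling(f / 0.2 - 1e-9)))
}

#' Composite accuracy score
#'
#' Per organ, the Dice similarity plus one fifth of the mean expert
#' revision score, summed over organs. With `m` organs the maximum is `2m`.
#'
#' @param per_organ_dsc Numeric vector of per-organ DSC.
#' @param per_organ_expert_scores Numeric vector of per-organ mean expert
#'   scores in `[0, 5]`, or a list with one vector of scores per organ.
#' @return Scalar score.
#' @examples
#' composite_accuracy(0.9, 4)  # 0.9 + 4/5
#' @export
composite_accuracy <- function(per_organ_dsc, per_organ_expert_scores) {
  if (length(per_organ_dsc) == 0)
    stop("need at least one organ", call. = FALSE)
  sc <- if (is.list(per_organ_expert_scores))
    vapply(per_organ_expert_scores, mean, numeric(1))
  else as.numeric(per_organ_expert_scores)
  if (length(sc) != length(per_organ_dsc))
    stop("dsc and score lists must have equal length", call. = FALSE)
  sum(per_organ_dsc + sc / 5)
}

organ_names <- function(classes = 1:4) {
  c("bladder", "femoral_heads", "rectum", "small_intestine")[classes]
}

#' Evaluate a predicted label map against a reference
#'
#' Computes per-organ DSC, Hausdorff, HD95 and ASD (mm) on aligned label
#' maps. Organs absent from both maps get DSC 1 and undefined distances.
#'
#' @param pred,ref [labelmap()]s on the same grid.
#' @param classes Foreground class indices to evaluate.
#' @return A data frame with one row per organ (a per-case slice of a
#'   metrics report).
#' @export
evaluate_labelmaps <- function(pred, ref, classes = 1:4) {
  stopifnot(inherits(pred, "seg_labelmap"), inherits(ref, "seg_labelmap"))
  stopifnot_aligned(pred, ref)
  rows <- lapply(classes, function(cl) {
    pm <- pred$data == cl
    gm <- ref$data == cl
    defined <- any(pm) && any(gm)
    data.frame(case_id = ref$case_id, organ = organ_names(cl), class = cl,
               dsc = dsc(pm, gm),
               hd_mm = if (defined) hausdorff_distance(pm, gm, ref$spacing) else NA_real_,
               hd95_mm = if (defined) hd95(pm, gm, ref$spacing) else NA_real_,
               asd_mm = if (defined) asd(pm, gm, ref$spacing) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname evaluate_labelmaps
#' @param preds,refs Lists of [labelmap()]s (or file paths), matched by
#'   position.
#' @export
evaluate_cases <- function(preds, refs, classes = 1:4) {
  stopifnot(length(preds) == length(refs))
  rows <- lapply(seq_along(preds), function(i) {
    p <- if (is.character(preds[[i]])) read_labelmap(preds[[i]]) else preds[[i]]
    r <- if (is.character(refs[[i]])) read_labelmap(refs[[i]]) else refs[[i]]
    evaluate_labelmaps(p, r, classes)
  })
  do.call(rbind, rows)
}

#' @rdname evaluate_labelmaps
#' @param report A metrics report data frame.
#' @param path CSV output path.
#' @export
write_metrics_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
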