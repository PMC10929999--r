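#' Average-voting ensemble of probability maps
#'
#' Voxelwise arithmetic mean of the per-class probability maps produced by
#' the fold models; the mean of distributions is again a distribution, so
#' per-voxel class probabilities still sum to 1. Permutation-invariant in
#' the model order; `k` identical maps reduce to any one of them.
#'
#' @param maps List of `seg_probmap`s on the same grid.
#' @return A `seg_probmap`.
#' @export
ensemble_average <- function(maps) {
  if (length(maps) < 1L) stop("need at least one probability map", call. = FALSE)
  ref <- maps[[1]]
  for (m in maps) {
    if (!identical(dim(m$data), dim(ref$data)))
      stop("probability maps are misaligned: shapes differ", call. = FALSE)
    if (max(abs(m$spacing - ref$spacing)) > 1e-6)
      stop("probability maps are misaligned: spacings differ", call. = FALSE)
  }
  avg <- Reduce(`+`, lapply(maps, `[[`, "data")) / length(maps)
  structure(list(data = avg, spacing = ref$spacing, case_id = ref$case_id),
            class = "seg_probmap")
}

#' Decode a probability map to labels
#'
#' Per-voxel argmax over the class channels; ties break toward the lowest
#' class index, so the background wins exact ties (a conservative,
#' deterministic rule).
#'
#' @param map A `seg_probmap`.
#' @return A [labelmap()].
#' @export
labels_from_probabilities <- function(map) {
  stopifnot(inherits(map, "seg_probmap"))
  lab <- apply_argmax(map$data)
  labelmap(lab, spacing = map$spacing, case_id = map$case_id,
           n_classes = dim(map$data)[1])
}

#' Pseudo-label unlabeled volumes with a fold-model ensemble
#'
#' For each unlabeled case: z-score normalize, predict per-class
#' probabilities with every model, average the maps, and decode labels by
#' argmax. Input images are never modified. Returns the pseudo label maps
#' plus a per-case confidence summary (mean over voxels of the maximum
#' class probability); optionally writes pseudo-label NIfTI files and a
#' confidence CSV.
#'
#' @param models List of `unet_model`s or checkpoint paths (all sharing
#'   output channels).
#' @param unlabeled List of [volume()]s or image file paths.
#' @param out_dir Optional output directory (`pseudo_labels/`,
#'   `confidence.csv`).
#' @param window,overlap Passed to [predict_probabilities()].
#' @return List with `labels` (list of [labelmap()]s) and `confidence`
#'   (data frame: case_id, mean_max_prob).
#' @export
self_annotate <- function(models, unlabeled, out_dir = NULL,
                          window = NULL, overlap = 0.5) {
  if (length(unlabeled) == 0L) {
    warning("self_annotate: no unlabeled cases; nothing to do", call. = FALSE)
    return(list(labels = list(),
                confidence = data.frame(case_id = character(),
                                        mean_max_prob = numeric())))
  }
  models <- lapply(models, function(m)
    if (is.character(m)) load_model(m) else m)
  oc <- unique(vapply(models, function(m) m$config$out_channels, integer(1)))
  if (length(oc) != 1L)
    stop("ensemble models disagree on out_channels", call. = FALSE)
  labs <- vector("list", length(unlabeled))
  conf <- numeric(length(unlabeled))
  ids <- character(length(unlabeled))
  for (i in seq_along(unlabeled)) {
    vol <- unlabeled[[i]]
    if (is.character(vol)) vol <- read_volume(vol)
    nv <- zscore_normalize(vol)
    maps <- lapply(models, predict_probabilities, vol = nv,
                   window = window, overlap = overlap)
    avg <- ensemble_average(maps)
    labs[[i]] <- labels_from_probabilities(avg)
    conf[i] <- mean(apply(matrix(avg$data, nrow = oc), 2, max))
    ids[i] <- vol$case_id
    if (!is.null(out_dir))
      write_volume(labs[[i]],
                   file.path(out_dir, "pseudo_labels",
                             paste0(vol$case_id, ".nii.gz")))
  }
  confidence <- data.frame(case_id = ids, mean_max_prob = conf,
                           stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(confidence, file.path(out_dir, "confidence.csv"),
              row.names = FALSE)
  }
  list(labels = labs, confidence = confidence)
}
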