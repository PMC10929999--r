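#' Load cohort cases into memory
#'
#' Reads images (z-score normalized) and, where available, labels for the
#' cases of a given role. Ground truth of unlabeled cases (phantom cohorts)
#' is attached as `truth` so pseudo-label quality can be audited; it is
#' never used for training.
#'
#' @param cohort A `seg_cohort` manifest from [generate_cohort()] /
#'   [read_cohort()].
#' @param role `"labeled"`, `"unlabeled"` or `"test"`.
#' @return List of cases: `case_id`, `image` (normalized array), `volume`
#'   (raw [volume()]), `labels` (integer array or NULL), `labelmap`.
#' @export
load_cases <- function(cohort, role) {
  rows <- cohort$cases[cohort$cases$role == role, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    vol <- read_volume(r$image, case_id = r$case_id)
    lm <- NULL
    if (!is.na(r$label)) lm <- read_labelmap(r$label, case_id = r$case_id)
    truth <- NULL
    if (!is.null(r$truth) && !is.na(r$truth))
      truth <- read_labelmap(r$truth, case_id = r$case_id)
    list(case_id = r$case_id, volume = vol,
         image = zscore_normalize(vol)$data,
         labels = if (is.null(lm)) NULL else lm$data, labelmap = lm,
         truth = truth)
  })
}

as_train_case <- function(cs, labels = NULL)
  list(image = cs$image, labels = if (is.null(labels)) cs$labels else labels)

#' Predict, decode and repair one volume
#'
#' Convenience composition used by the experiment drivers: normalize,
#' sliding-window inference, argmax decoding, morphological repair.
#'
#' @param model A `unet_model`.
#' @param vol A raw [volume()].
#' @param rules A [postprocess_rules()]; `NULL` skips repair.
#' @export
predict_labels <- function(model, vol, rules = postprocess_rules()) {
  nv <- zscore_normalize(vol)
  lm <- labels_from_probabilities(predict_probabilities(model, nv))
  if (!is.null(rules)) lm <- postprocess_labelmap(lm, rules)
  lm
}

evaluate_on_test <- function(model, test_cases, rules) {
  rows <- lapply(test_cases, function(cs) {
    pred <- predict_labels(model, cs$volume, rules)
    evaluate_labelmaps(pred, cs$labelmap)
  })
  do.call(rbind, rows)
}

write_run_manifest <- function(out_dir, kind, seed, cfgs, outputs) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(kind = kind, seed = seed,
              config_hash = stable_hash(paste(deparse(cfgs), collapse = "")),
              config = rapply(cfgs, unclass, how = "replace"),
              outputs = outputs)
  jsonlite::write_json(man, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  invisible(man)
}

#' Supervised baseline experiment
#'
#' Trains one model on `label_budget` labeled cases and evaluates it
#' (with post-processing) on the cohort's held-out test cases.
#'
#' @param cohort A `seg_cohort` with labeled and test cases.
#' @param label_budget Number of labeled cases to use (default: all).
#' @param net_config,tc,lc,rules Network, training, loss and
#'   post-processing configurations.
#' @param seed Run seed; training seeds derive from it.
#' @param out_dir Optional directory for the checkpoint, report CSV and a
#'   machine-readable run manifest.
#' @return A `seg_run`: list with `report` (per test case x organ metrics),
#'   `model`, `history`.
#' @export
run_supervised <- function(cohort, label_budget = NULL,
                           net_config = unet_preset("2d_test"),
                           tc = train_preset("test"), lc = loss_config(),
                           rules = postprocess_rules(), seed = 1L,
                           out_dir = NULL) {
  labeled <- load_cases(cohort, "labeled")
  if (is.null(label_budget)) label_budget <- length(labeled)
  if (label_budget > length(labeled))
    stop("label_budget (", label_budget, ") exceeds available labeled cases (",
         length(labeled), ")", call. = FALSE)
  train_cases <- lapply(labeled[seq_len(label_budget)], as_train_case)
  tc$seed <- stable_hash(seed, "supervised")
  fit <- train_model(train_cases, list(), net_config, tc, lc)
  test_cases <- load_cases(cohort, "test")
  report <- if (length(test_cases)) evaluate_on_test(fit$model, test_cases, rules)
  else NULL
  outputs <- list()
  if (!is.null(out_dir)) {
    outputs$checkpoint <- file.path(out_dir, "model.rds")
    save_model(fit$model, outputs$checkpoint)
    if (!is.null(report)) {
      outputs$report <- file.path(out_dir, "report.csv")
      write_metrics_report(report, outputs$report)
    }
    write_run_manifest(out_dir, "supervised", seed,
                       list(net = net_config, train = tc, loss = lc,
                            rules = rules, label_budget = label_budget),
                       outputs)
  }
  structure(list(report = report, model = fit$model, history = fit$history),
            class = "seg_run")
}

#' Semi-supervised self-annotation experiment
#'
#' The full pipeline: split the labeled budget into `k` folds; train one
#' model per fold (the fold serving as validation); pseudo-label every
#' unlabeled case by ensemble average voting over the fold models; repair
#' the pseudo-labels by post-processing; retrain a single model from
#' scratch on labeled + pseudo-labeled cases; evaluate on the held-out test
#' cases. With zero unlabeled cases this degenerates (with a warning) to
#' the supervised baseline.
#'
#' @inheritParams run_supervised
#' @param k Fold count for the annotation ensemble (default 5).
#' @return A `seg_run` with additionally `fold_models`, `pseudo_labels`
#'   (post-processed), `pseudo_raw`, `confidence`.
#' @export
run_semisupervised <- function(cohort, label_budget = NULL, k = 5L,
                               net_config = unet_preset("2d_test"),
                               tc = train_preset("test"), lc = loss_config(),
                               rules = postprocess_rules(), seed = 1L,
                               out_dir = NULL) {
  labeled <- load_cases(cohort, "labeled")
  if (is.null(label_budget)) label_budget <- length(labeled)
  if (label_budget > length(labeled))
    stop("label_budget (", label_budget, ") exceeds available labeled cases (",
         length(labeled), ")", call. = FALSE)
  labeled <- labeled[seq_len(label_budget)]
  unlabeled <- load_cases(cohort, "unlabeled")
  if (length(unlabeled) == 0L) {
    warning("no unlabeled cases: falling back to the supervised baseline",
            call. = FALSE)
    return(run_supervised(cohort, label_budget, net_config, tc, lc, rules,
                          seed, out_dir))
  }
  ids <- vapply(labeled, `[[`, character(1), "case_id")
  folds <- make_folds(ids, k = k, seed = stable_hash(seed, "folds"))
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- lapply(labeled[folds$assignment != f], as_train_case)
    va <- lapply(labeled[folds$assignment == f], as_train_case)
    tcf <- tc
    tcf$seed <- stable_hash(seed, "fold", f)
    fit <- train_model(tr, va, net_config, tcf, lc)
    fold_models[[f]] <- fit$model
    if (!is.null(out_dir))
      save_model(fit$model, file.path(out_dir, sprintf("fold_model_%d.rds", f)))
  }
  ann <- self_annotate(fold_models, lapply(unlabeled, `[[`, "volume"),
                       out_dir = if (is.null(out_dir)) NULL
                       else file.path(out_dir, "raw"))
  pseudo <- lapply(ann$labels, postprocess_labelmap, rules = rules)
  if (!is.null(out_dir)) {
    for (pl in pseudo)
      write_volume(pl, file.path(out_dir, "pseudo_labels",
                                 paste0(pl$case_id, ".nii.gz")))
  }
  retrain_cases <- c(lapply(labeled, as_train_case),
                     lapply(seq_along(unlabeled), function(i)
                       list(image = unlabeled[[i]]$image,
                            labels = pseudo[[i]]$data)))
  tcr <- tc
  tcr$seed <- stable_hash(seed, "retrain")
  fit <- train_model(retrain_cases, list(), net_config, tcr, lc)
  test_cases <- load_cases(cohort, "test")
  report <- if (length(test_cases)) evaluate_on_test(fit$model, test_cases, rules)
  else NULL
  outputs <- list()
  if (!is.null(out_dir)) {
    outputs$checkpoint <- file.path(out_dir, "model.rds")
    save_model(fit$model, outputs$checkpoint)
    if (!is.null(report)) {
      outputs$report <- file.path(out_dir, "report.csv")
      write_metrics_report(report, outputs$report)
    }
    write_run_manifest(out_dir, "semisupervised", seed,
                       list(net = net_config, train = tc, loss = lc,
                            rules = rules, label_budget = label_budget,
                            k = k), outputs)
  }
  structure(list(report = report, model = fit$model, history = fit$history,
                 fold_models = fold_models, folds = folds,
                 pseudo_labels = pseudo, pseudo_raw = ann$labels,
                 confidence = ann$confidence),
            class = "seg_run")
}

#' Compare two metrics reports
#'
#' Per-organ mean DSC, HD95 and ASD for each run plus differences
#' (run A minus run B). Distances aggregate over the cases where they are
#' defined.
#'
#' @param report_a,report_b Metrics report data frames (from `seg_run`s or
#'   [evaluate_cases()]).
#' @return Data frame with one row per shared organ.
#' @export
compare_runs <- function(report_a, report_b) {
  organs <- intersect(unique(report_a$organ), unique(report_b$organ))
  if (length(organs) == 0L)
    stop("reports share no organs; cannot compare", call. = FALSE)
  agg <- function(rep, organ) {
    r <- rep[rep$organ == organ, , drop = FALSE]
    c(dsc = mean(r$dsc), hd95 = mean(r$hd95_mm, na.rm = TRUE),
      asd = mean(r$asd_mm, na.rm = TRUE))
  }
  rows <- lapply(organs, function(o) {
    a <- agg(report_a, o)
    b <- agg(report_b, o)
    data.frame(organ = o, dsc_a = a["dsc"], dsc_b = b["dsc"],
               dsc_delta = a["dsc"] - b["dsc"],
               hd95_a = a["hd95"], hd95_b = b["hd95"],
               hd95_delta = a["hd95"] - b["hd95"],
               asd_a = a["asd"], asd_b = b["asd"],
               asd_delta = a["asd"] - b["asd"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
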