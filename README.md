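# selfseg

Semi-supervised **self-annotation** for multi-organ segmentation of
anisotropic 3D images, in R.

## The problem

Training organ-at-risk (OAR) segmentation models for pelvic radiotherapy
requires expert contours on MR volumes, which are expensive to produce.
Self-training reduces that cost: an ensemble of models trained on a small
labeled set annotates unlabeled volumes ("pseudo-labels"), the machine
annotations are repaired morphologically, and a single model is retrained
on the enlarged dataset. `selfseg` implements this pipeline end-to-end for
four pelvic OARs (bladder, femoral heads, rectum, small intestine) on
anisotropic volumes (thick slices, fine in-plane spacing), together with a
synthetic phantom generator so every stage is testable without clinical
data.

The pieces, each exposed as ordinary R functions:

| Stage | Functions |
| --- | --- |
| Synthetic cohorts | `phantom_config()`, `generate_phantom()`, `generate_cohort()`, `corrupt_labels()` |
| NIfTI I/O + preprocessing | `read_volume()`, `zscore_normalize()`, `resample()`, `extract_patch()`, `augment_patch()` |
| Networks | `unet_config()` / `unet_preset()`, `build_unet()`, `predict_probabilities()` |
| Training | `loss_config()`, `composite_loss()`, `make_folds()`, `train_model()` |
| Self-annotation | `ensemble_average()`, `labels_from_probabilities()`, `self_annotate()` |
| Label repair | `fill_holes()`, `keep_largest_components()`, `morphological_smooth()`, `postprocess_labelmap()` |
| Evaluation | `dsc()`, `hausdorff_distance()`, `hd95()`, `asd()`, `revision_score()`, `composite_accuracy()`, `evaluate_labelmaps()` |
| Experiments | `run_supervised()`, `run_semisupervised()`, `compare_runs()` |

The model core: 2D/3D U-Nets (conv + instance norm + leaky ReLU blocks,
strided-conv down-sampling, transposed-conv up-sampling, 5-channel
softmax head) trained with the compound loss

    loss = a * (1 - softDice) + (1 - a) * crossEntropy,   a = 0.5 by default,

where softDice is the smoothed Dice similarity averaged over foreground
classes and the cross-entropy is 5-class categorical. Evaluation uses the
Dice similarity coefficient DSC = 2|P∩G|/(|P|+|G|), the (95th-percentile)
Hausdorff distance and the average symmetric surface distance in mm, all
spacing-aware. Forward and backward passes are implemented in the package
(im2col + BLAS; finite-difference-checked) — no external deep-learning
framework is required.

## Worked example

Generate a small phantom cohort (10 labeled, 30 unlabeled, 10 test cases),
run the supervised baseline on the 10 labels, then the full semi-supervised
pipeline, and compare:

```r
library(selfseg)

cfg    <- phantom_config(grid_shape = c(16, 64, 64), seed = 11)
cohort <- generate_cohort(cfg, n_labeled = 10, n_unlabeled = 30,
                          n_test = 10, dir = "cohort")

sup  <- run_supervised(cohort, label_budget = 10, seed = 1)
semi <- run_semisupervised(cohort, label_budget = 10, k = 5, seed = 1)

compare_runs(semi$report, sup$report)[, c("organ", "dsc_a", "dsc_b", "dsc_delta")]
```

```
            organ     dsc_a     dsc_b   dsc_delta
1         bladder 0.9579695 0.9245161  0.03345338
2   femoral_heads 0.9350448 0.0000000  0.93504481
3          rectum 0.7958428 0.8491170 -0.05327421
4 small_intestine 0.2879087 0.1450139  0.14289479
```

`dsc_a` is the per-organ mean test DSC of the semi-supervised model,
`dsc_b` the supervised baseline trained on the same 10 labels, and
`dsc_delta` their difference. In this run the single supervised model
lost the femoral heads entirely (a known failure mode of short,
small-capacity training runs) while the ensemble-driven pipeline kept
them — the annotation ensemble is far more robust than any single model.
The machine annotations themselves are good for three of the four
organs; against the hidden ground truth of the 30 unlabeled cases this
run's repaired pseudo-labels score

```
pseudo-label DSC vs hidden truth: 0.969 0.932 0.925 0.416
```

(bladder, femoral heads, rectum, small intestine). Results vary
noticeably across seeds at this problem size, and at desk scale the
retrained model does not systematically beat the baseline — the methods
vignette analyses that regime in detail. `semi$pseudo_labels` holds the
repaired machine annotations, `semi$confidence` the per-case mean
maximum class probability.

A thin command-line wrapper with the same operations ships in
`exec/selfseg` (subcommands `generate-cohort`, `run-supervised`,
`run-semisupervised`, `self-annotate`, `postprocess`, `evaluate`,
`compare`).

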