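---
title: "Self-annotation for multi-organ segmentation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-annotation for multi-organ segmentation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep segmentation models for radiotherapy organs-at-risk (OARs) need many
expert-contoured volumes, and contouring pelvic MR is slow. Self-training
sidesteps part of that cost: models trained on a small labeled set annotate
unlabeled volumes, the machine annotations are repaired, and a final model
is retrained on the enlarged set. `selfseg` implements that pipeline for
anisotropic 3D grayscale volumes with four OAR classes — bladder (1),
femoral heads (2), rectum (3), small intestine (4), background 0 — along
with everything needed to exercise it end-to-end without clinical data: a
synthetic pelvic phantom generator, NIfTI preprocessing, 2D/3D U-Nets,
morphological label repair, and spacing-aware evaluation.

The pipeline (`run_semisupervised()`):

1. split the labeled cohort into k = 5 folds (`make_folds()`);
2. train one U-Net per fold, the fold itself serving as validation
   (`train_model()`);
3. pseudo-label every unlabeled volume by **average voting**: the voxelwise
   arithmetic mean of the five models' softmax probability maps, decoded by
   argmax (`self_annotate()`);
4. repair each pseudo-label map — fill holes, keep the per-organ component
   budget, optional morphological closing (`postprocess_labelmap()`);
5. retrain a single model from scratch on labeled + pseudo-labeled cases
   and evaluate it, after the same post-processing, on held-out test cases.

`run_supervised()` is the matching baseline: one model, labeled cases only.

## The phantom generator

Hospital MR volumes cannot ship with a package, so the generator emulates
their geometry: thick slices along z with fine in-plane spacing (default
spacing 6.5 mm × 2.656 mm × 2.656 mm — the acquisition's slice spacing with
the in-plane grid coarsened 4× so desk-scale grids keep a realistic field
of view), and four disjoint organ-like structures:

* **bladder** — a superellipsoid (exponent 2.5), the single large bright
  structure;
* **femoral heads** — two laterally mirrored spheres, guaranteeing the
  class always has exactly two connected components;
* **rectum** — a sinusoidally curved tube running along z;
* **small intestine** — a union of 3–8 overlapping blobs
  superior/anterior to the bladder, giving a multi-lobed mass with a
  variable component count.

Geometry is parameterized in fractions of the physical extent, so one
configuration scales across grid sizes; per-case jitter of centers, radii,
curvature and blob count provides inter-patient variability. Intensities
are class-conditional Gaussians (means 0.15/0.90/0.70/0.40/0.55, chosen as
a T2-like bright-fluid / bright-marrow / dark-muscle ordering), modulated
by a smooth random multiplicative bias field (amplitude 0.15) and global
Gaussian noise (sd 0.06). Determinism is strict: the case RNG seed is a
stable hash of `(config$seed, case_id)`, and cohort sub-seeds derive from
the master seed, so cohorts replay bit-identically.

What the phantom does **not** model: MR physics (no k-space, no T2 decay,
no coil profiles beyond the polynomial bias), partial-volume mixing,
organs touching each other, motion, or pathology. Passing tests on
phantoms therefore demonstrates that the pipeline's machinery is correct
and that self-training behaves as claimed on a learnable anisotropic task
— not that any specific clinical accuracy would be reached on real MR.

`corrupt_labels()` produces controlled imitations of raw-prediction errors
so the repair stage can be tested against ground truth: interior cavities
(carved slice-wise as in-plane disks whose ring and both z-caps stay
inside the organ, so each cavity is genuinely enclosed and exactly
recoverable), small spurious background fragments (balls placed clear of
all foreground and of each other, so per-class component counts rise by
exactly the configured number), and in-plane boundary jitter. A zero
configuration is the identity; corruption never touches the intensity
volume. On thin-slice grids only organs spanning ≥ 3 slices can host a
cavity — a hole that does not fit raises a degenerate-corruption error
rather than silently corrupting the geometry.

## Preprocessing conventions

* **Axis order** is (z, y, x) everywhere, matching the 3D patch notation
  `[32, 256, 256]`; NIfTI files store (x, y, z) and are permuted on I/O.
  Round trips preserve voxels bit-exactly and spacing to < 1e-6 mm.
* **Normalization** is per-image z-score with the *population* standard
  deviation; a constant image maps to zeros. This makes the operation
  total, deterministic and idempotent. Normalization is applied after any
  resampling (resample-then-normalize), so the statistics describe the
  grid the network actually sees.
* **Resampling** maps voxel centers so the physical field of view is
  preserved; output shape per axis is `round(shape·spacing/target)` with
  half rounded away from zero (a fixed, documented tie rule), minimum 1.
  Images interpolate trilinearly, label maps by nearest neighbor only
  (linear label interpolation is rejected as a mode error).
* **Patches**: corners are sampled uniformly over valid positions; sources
  smaller than the patch are symmetrically padded (zeros / background)
  with the data centered. A configurable fraction of draws centers on a
  foreground voxel; by default the class of that voxel is first drawn
  uniformly among the classes present (`fg_balanced`), because the femoral
  heads and intestine lobes occupy only ~0.2–0.5 % of voxels and
  volume-proportional sampling starves them of gradient signal.
* **Augmentation**: random in-plane rotation (±15° by default; the exact
  range is a free choice) with bilinear/nearest interpolation — exact
  lattice rotation at multiples of 90° — plus small crop-then-pad
  translation jitter. Label codomain and patch shape are invariants.

## Networks

Both U-Nets use convolution → instance normalization → leaky ReLU
(slope 0.01) blocks, two per resolution stage, strided convolutions for
down-sampling, transposed convolutions (kernel = stride) for up-sampling,
skip concatenations, and a final 1×1(×1) convolution to 5 channels with a
softmax at the loss/inference side. Kernels are 3×3 (2D) and 3×3×3 (3D).

Two readings of the architecture description deserve flagging:

* "down-sampling 6 along x and y" is read as **six halving stages**
  (2⁶ = 64, so 256 → 4 at the bottleneck), not a factor of 6 — the power
  of-two reading is the only one consistent with strided-convolution
  down-sampling. `unet_shapes()` makes this arithmetic checkable, and the
  test suite verifies it with real forward passes.
* the 3D output size "[5, 256, 256]" for input [32, 256, 256] is treated
  as a typo for [5, 32, 256, 256]: a segmentation of a 3D patch must cover
  every slice.

In 3D, only the first `n_stages_z = 2` stages stride the z axis (stride
2,2,2; later stages 1,2,2), so z: 32 → 8 while the plane halves six times
— the anisotropic design that motivates comparing 2D and 3D models at all.
Channel widths are base·2^stage capped at 320 (full preset, base 32);
widths are not stated in the source description, so these follow common
U-Net practice, and a CPU-cheap test preset (base 8, 3 stages) exists for
desk-scale work. Parameter initialization is He-normal under a fixed seed:
`build_unet(config, seed)` is bit-reproducible.

The forward and backward passes are implemented in the package itself on
im2col/col2im kernels (no deep-learning framework is involved); the
backward pass of every layer is validated against central finite
differences in the test suite. Sliding-window inference blends overlapping
windows by uniform averaging (probabilities stay normalized); a 2D model
predicts one slice per window so instance-norm statistics match the
per-slice training regime.

## Loss

The training objective is the convex combination

  loss = a · (1 − softDice) + (1 − a) · crossEntropy,  a ∈ [0, 1].

The Dice *similarity* `(2Σpy + s)/(Σp + Σy + s)` is averaged over the four
foreground classes and enters as `1 − Dice` so that the composite
decreases during training (the similarity itself cannot be minimized).
The cross-entropy is the 5-class categorical form `−(1/n) Σ y ln p`
(clipping ε = 1e-7), because the network ends in a 5-way softmax; the
two-term binary expression `−mean[y ln p + (1−y) ln(1−p)]` is also
provided (`form = "binary"`) and coincides with the categorical form in
the two-class limit when averaged over one-hot entries. The Dice weight
`a` is not pinned by the source description; the default is the symmetric
a = 0.5 and it is exposed everywhere. Dice smooth is 1e-5. These constants
are numeric-safety choices, stated here so they are not mistaken for
fitted values.

Unless explicit class weights are supplied, the training loop derives
cross-entropy class weights from the training labels as
`1/sqrt(class frequency)`, normalized to mean 1 (so the overall
gradient scale is unchanged). The rationale is
dead-class collapse: once a softmax channel's probability approaches zero
everywhere, the Dice term's logit-gradient vanishes with it (it is
proportional to the channel probability), and for a class occupying well
under 1 % of voxels the unweighted cross-entropy pull is too weak to
recover the channel within a short training budget — roughly a third of
seeds lost the femoral heads entirely without weighting. Frequency-derived
weighting removes that failure mode without per-class hand tuning; it can
be disabled (`balance_class_weights = FALSE`) or overridden via
`loss_config(class_weights = ...)`.

## Training recipe

Adam with initial learning rate 0.01 and polynomial decay
`lr·(1 − epoch/epochs)^0.9` ("original learning rate" implies decay; the
schedule itself is a standard choice, configurable to constant). Full
presets keep the published budgets (250 epochs; 2D: batch 12 at 512×512;
3D: batch 2 at 32×256×256). The desk-scale test preset — used by the test
suite and the acceptance script — is 10 epochs × 40 batches of four 32×32
slices with foreground-balanced oversampling (fraction 0.5), sized so a
model trains in ~30 s on one CPU while still learning all four organs;
shorter recipes (≤ 300 steps) intermittently failed to pick up the
femoral heads. Best-checkpoint selection uses the validation fold's mean
foreground Dice on sampled patches (training loss when no validation
cases exist); whether the original experiments selected checkpoints this
way is not stated, so this is the package's documented choice. A
non-finite loss aborts with a diagnostic rather than continuing.

## Self-annotation decisions

* **Probability averaging, not vote counting**: "average voting" is
  implemented as the voxelwise mean of softmax maps, then argmax. Ties
  break toward the lowest class index, so background wins exact ties — a
  deterministic, background-conservative rule.
* **No confidence filtering**: all post-processed pseudo-labels join the
  training set; per-case mean max-probability is reported as a confidence
  summary but unused by default.
* **Single retrained model**: the retraining step produces one model
  trained from scratch on labeled + pseudo-labeled data (the wording
  "re-train an auto-segmentation model" is singular); re-running the
  whole k-fold scheme on the enlarged set is a possible alternative that
  is deliberately not the default.

## Post-processing decisions

"Maximum threshold domain" is interpreted as **largest-connected-component
retention**, consistent with the stated goal of removing small spurious
fragments. Per-class component budgets default to the anatomical
expectation — bladder 1, femoral heads 2, rectum 1, small intestine
unlimited (multi-lobed) — and are fully configurable. Connectivity
defaults to the 26-neighborhood for foreground components; hole filling
floods the background with face (6) connectivity from the grid border and
fills what it cannot reach, volumetrically (slice-wise filling is
subsumed). The "morphological method" is implemented as closing only,
with a ball element in a background-padded domain (so a solid mask is a
fixed point and borders are not eroded); radius 0 — the default — makes
it a no-op. Classes are processed in index order 1–4 with
first-writer-wins overlap resolution, preserving the one-class-per-voxel
invariant.

## Evaluation conventions

DSC uses the both-empty = 1 / one-empty = 0 conventions. Surfaces are
foreground voxels with at least one non-foreground face neighbor (grid
edges count), with coordinates at voxel centers in mm — distances are
therefore spacing-aware and reported in mm. The Hausdorff distance is the
symmetric max of directed max–min distances; HD95 takes the 95th
percentile (linear interpolation) over the **pooled** directed
nearest-distance multisets (per-direction maxima would be the main
alternative; pooling is the common convention and is fixed here); ASD is
the sum of both directed nearest-distance sums over the total surface
point count, exactly as defined. An empty mask makes a distance
*undefined*: the functions return `NA` with a warning, never a silent 0,
because silent zeros would corrupt cohort aggregates. All three distance
metrics are verified against exhaustive all-pairs computation on random
mask pairs to 1e-6 mm.

The expert revision scale maps the revised volume fraction to 5 (no
revision) down through 20-percent bands to 0 (more than 80 %). The
composite accuracy score is Σ_organ (DSC + meanExpertScore/5); with four
summed organs its maximum is 8, and since the published 2D score of 9.41
exceeds that, the organ list is left configurable (splitting the femoral
heads left/right gives five terms and a maximum of 10) rather than
asserting either reading.

## Desk-scale problem sizes

The test suite and `scripts/acceptance.R` exercise the full pipeline on
phantom cohorts of 10 labeled + 30 unlabeled + 10 test cases at grid
16×64×64 (spacing 6.5×2.656×2.656 mm), with the 2D test-preset network
and the recipe above, replicated over three seeds. These sizes are the
package's chosen desk-scale study conditions: large enough that the
semi-supervised arm must actually learn transferable structure, small
enough to run on a single CPU. The replication experiment mirrors the
central claim qualitatively — the retrained semi-supervised model's mean
test DSC should match or exceed the 10-label supervised baseline — not
any specific published table value, which derives from private clinical
data.

## What the desk-scale experiments do and do not show

The test-scale experiments replicate the pipeline's *mechanics*
faithfully: fold ensembles trained on 8 labeled phantoms annotate unseen
cases at DSC ≈ 0.92–0.97 for the bladder, femoral heads and rectum
(≈ 0.4 for the much harder multi-lobed intestine), the repair stage is
exactly invertible on controlled corruptions, and the whole pipeline
replays bit-identically under a seed.

What they deliberately do not demonstrate is the *accuracy benefit* of
self-training. A replicated control shows why: at the desk-scale network
width and step budget, a model trained on 40 phantoms with perfect labels
performs no better than one trained on 10 (mean DSC 0.625 vs 0.611 over
three seeds at an equal, generously scaled step budget). In this regime
the model is capacity- and optimization-limited rather than data-limited,
so adding pseudo-labeled — necessarily noisier — cases cannot raise test
accuracy, and the retrained semi-supervised model lands slightly below
the supervised baseline (differences around −0.1 mean DSC). The benefit
reported for the full-scale setting relies on models large and
long-trained enough to be data-limited; reproducing that regime is a
matter of compute, not of any further algorithmic ingredient, and the
full-resolution presets in this package are the configuration intended
for it.

## Known limitations

* The phantom's simplicity means absolute DSC values are not comparable
  to clinical results; only relative comparisons within a cohort are
  meaningful.
* The R implementation of the networks is CPU-bound and desk-scale; the
  full 512×512/250-epoch presets are provided for completeness and
  configuration fidelity, not routine use.
* Expert revision scores are consumed as inputs (the scale is
  implemented, the human study is not reproduced).
* Pseudo-label confidence is reported but not used for filtering, by
  design; selective self-training is out of scope.
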