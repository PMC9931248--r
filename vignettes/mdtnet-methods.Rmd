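---
title: "Grading retinal arterio-venous crossings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading retinal arterio-venous crossings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mdtnet)
```

## The clinical problem

Arteriolosclerosis — hardening of the small arteries — leaves a visible
signature in the retina: where a stiffened artery crosses a vein, it
compresses it, narrowing the venular caliber at one or both edges of the
crossing. Ophthalmologists grade this on a four-level severity scale
(*none*, *mild*, *moderate*, *severe*), but the grading requires long
experience, is subjective, and has poor inter-grader reproducibility.
`mdtnet` implements an automated pipeline that mirrors the clinical
workflow in three inspectable stages:

1. **Candidate detection.** From a vessel segmentation mask and an
   artery/vein pixel classification (produced upstream by external
   models; this package consumes their rasters), find locations where an
   artery and a vein cross.
2. **Crossing validation.** Not every detected contact is diagnostically
   usable: only crossings where the *artery passes over the vein* carry
   the compression sign. A binary CNN classifier judges each 150 × 150
   patch.
3. **Severity grading.** A four-class ensemble (MDTNet) assigns the
   severity grade to each validated crossing.

Every intermediate — refined label maps, skeletons, candidate tables,
patches, per-crossing probabilities — is persisted, so a clinician can
audit how each decision was reached.

## Preprocessing: label refinement and skeletons

Artery/vein pixel classifiers are noisier than vessel segmenters, so
labels are reconciled with the vessel mask before detection. The vessel
mask is skeletonized (topology-preserving thinning; spurs shorter than
10 px that end in a branch point are pruned, and skeleton endpoints are
re-extended inside the mask to undo the end-shortening of iterative
thinning). Removing branch points together with a 3 px ball around them
cuts the skeleton into single-vessel *arms*; each mask pixel joins its
geodesically nearest arm, and each arm's pixels take the majority of
their original non-background labels (exact ties become *unknown*).

One deliberate exception: pixels within 15 px of a branch point keep
their original (clipped) labels. Inside a junction or crossing zone the
notion of a single-vessel segment breaks down, and it is precisely there
that the pattern of which vessel overwrites which encodes the z-order a
later stage must read. Majority-relabeling such zones was measured to
destroy a third of detectable crossings on synthetic scenes.

## Candidate detection

Detection works on the refined artery/vein map:

* **Contact pixels** are artery pixels with a vein pixel among their
  8-neighbours; 8-connected contact clusters become raw candidates
  (cluster size = candidate score).
* **Merging.** Because the occluded vessel is interrupted at the
  overlap, a single crossing typically produces *two* contact arcs, one
  on each flank. Candidates closer than `merge_radius_px` (default
  20 px) are merged at their score-weighted centroid — before any
  further testing, so that subsequent checks run at the true crossing
  center. Merging conserves total score.
* **Recentering.** Contact-arc centroids are biased sideways when the
  flanking arcs are asymmetric (up to ~8 px with a narrowed vein). Each
  merged candidate is snapped to the intersection of total-least-squares
  line fits of the artery and vein label masks inside a 20 px window.
  The snap is skipped when either fit has fewer than 5 supporting pixels,
  the crossing angle is below ~10°, or the shift would exceed 12 px.
* **Traversal check.** Within a disc of radius `check_radius_px`
  (default 15 px) both the artery skeleton and the vein skeleton must
  *traverse* the disc: skeleton clusters reaching the boundary zone
  count as one boundary hit each, or two when a single cluster reaches it
  on roughly opposite sides (>120° apart); a vessel needs ≥ 2 hits. A
  4 px outer margin absorbs the occlusion gap of the vessel drawn
  underneath, whose skeleton resumes roughly
  \((r_a + r_v)/\sin\theta\) plus thinning erosion from the center. A
  branch that merely terminates on the other vessel (T-junction) scores
  one hit and is discarded.
* **Cup exclusion.** Candidates whose centroid lies in the optic-cup
  mask are dropped; vessel geometry there is too unreliable.

Patches of 150 × 150 are cut centered on each candidate with the
half-open convention (rows \([r-75, r+75)\)), reflect-padding the fundus
when the window leaves the image.

## Class imbalance: focal loss and log-ratio weights

Grade labels are heavily imbalanced (in the motivating study: 1177 /
816 / 457 / 57 across *none*/*mild*/*moderate*/*severe*, i.e. the
rarest class is ~2%). Two mechanisms address this:

The **focal loss**
\[
L(y, t) = -\sum_l \alpha_l\, t_l\, (1-y_l)^{\gamma} \log y_l
\]
down-weights well-classified examples; \(\gamma = 0\) recovers the
cross-entropy exactly (verified to 1e-9 over random inputs), and the
loss is strictly decreasing in both \(\gamma\) and the true-class
probability. Predicted probabilities are clipped to
\([\varepsilon, 1]\), \(\varepsilon = 10^{-7}\), before the logarithm;
batch reduction is the mean, keeping the loss scale independent of batch
size.

The **class weights** \(\alpha_l = \ln N_l / \ln N\) shrink rare
classes' influence sub-linearly (a class seen once gets weight 0, the
majority class stays near 1). The package computes them from
*training-split* counts rather than the full dataset — a deliberate
choice to keep any test-set information out of training.

## MDTNet: a diagnosis team of sub-models

Choosing \(\gamma\) is notoriously data-dependent. Instead of tuning it,
MDTNet trains several sub-models — base members with cross-entropy
(optionally on different backbones) and focal members with
\(\gamma = 1..n\) — *independently*, then freezes them all and trains a
small fusion head (two fully-connected layers with a rectifier between,
softmax output, hidden width 256 by default) on the concatenation of
their penultimate-layer features. The frozen sub-models are bit-identical
before and after fusion training; the fused input width is exactly the
sum of the feature dimensions.

The backbone registry contains four compact CNNs sized for CPU training
on 150 × 150 patches (`tiny`, 3 conv blocks, 64-d features, is the
default and the one used throughout the test suite; the others provide
architectural diversity for the base module). The conv/pool kernels are
implemented in C++ (im2col + BLAS GEMM) with analytically verified
gradients (finite-difference agreement to ~1e-9). Training uses Adam;
the learning rate defaults to 1e-4 (the published setting for
ImageNet-pretrained backbones), but the compact backbones train from
scratch and converge better at 1e-3, which is what the package's own
experiments use. After every epoch the model is evaluated on the
validation split and the best checkpoint is retained. All training is
exactly seeded: same seed and data give identical parameters.

Grad-CAM explanations (`explain_prediction()`) backpropagate the target
class score to the last convolutional layer of the designated sub-model
(the first base member for an ensemble), average gradients per channel,
rectify the weighted channel sum, normalize to \([0,1]\) and upsample to
the patch size.

## Augmentation pool

Training patches pass an eleven-operator pool, each operator firing
independently with probability 0.5, in fixed order: vertical flip,
horizontal flip, crop-and-pad, scaling (0.8–1.2), translation (±15 px),
rotation (±30°), shearing (±10°), Gaussian blur (σ ≤ 1.5), additive
noise (σ ≤ 8/255), low-frequency noise, and hue/saturation shifts. The
parameter ranges are package conventions, configurable per operator;
geometric operators interpolate bilinearly with reflected borders.
Labels and the 150 × 150 shape are always preserved.

## Evaluation protocol

Splits are grouped by *subject* (an examinee may contribute several
images), shuffled by seed and partitioned 8:1:1 by largest-remainder
rounding — so split sizes deviate from the exact ratio by at most one
subject and no subject ever appears in two splits. Metrics are
precision/recall (binary validity task: positive class = true crossing),
accuracy, and Cohen's kappa
\(\kappa = (p_o - p_e)/(1 - p_e)\) with the convention \(\kappa = 1\)
for perfect degenerate agreement and 0 otherwise; the closed form is
tested exhaustively against a brute-force pair-agreement oracle on all
2 × 2 confusion matrices with entries 0–5. End-to-end evaluation matches
reported crossings to ground truth greedily one-to-one by ascending
distance (5 px tolerance), scores validity on matched candidates, and
grades only the crossings that are truly valid and were ruled valid —
mirroring the clinical protocol of grading only correctly detected
crossings.

## The synthetic scene generator

The study's cohort images are private, so the package ships a seeded
generator that plants the *constructs* the pipeline must recover:

* two vessel tubes per crossing (smooth spline-jittered centerlines,
  artery caliber 6 px, vein caliber 10 px by default) intersecting at
  ≥ 45°, placed with ≥ 140 px separation (placement failures after
  bounded retries raise an informative error);
* a known z-order per crossing — artery-over-vein with probability
  2507/4240, matching the study's true/false crossing frequencies; the
  top vessel overwrites the bottom one both in the label map and in the
  painted fundus, so validity is learnable from appearance exactly as in
  real images;
* grade-dependent venular narrowing: each grade scales the vein radius
  on the two sides of the crossing by factors (defaults: none (1, 1),
  mild (0.85, 0.85), moderate (0.6, 1), severe (0.6, 0.6) — reading the
  clinical descriptions "slight shrink", "a single venular edge", "both
  venular edges"; the literature gives no morphometric definition of
  these words, so the factors are conventions, exposed in
  `scene_spec()`). Grades are drawn from the study's empirical label
  distribution (1177, 816, 457, 57)/2507. The narrowing holds out to
  35 px from the crossing and tapers back to nominal by 50 px, so a
  perpendicular profile at ±20 px measures the scaled caliber to ±1 px;
* an optional bright optic-cup disc with its mask, and Gaussian sensor
  noise (σ = 0.02 by default);
* subject identifiers assigned round-robin — synthetic metadata whose
  only purpose is exercising the grouped split.

Learning-based stages are tested in a *strong-signal regime*: noise 0,
vein caliber 12 px, narrowing factors spread far apart (0.65 / 0.35
instead of 0.85 / 0.6). This is a deliberate separability condition: it
establishes that the architecture, losses, fusion and bookkeeping are
correct, not that the grades of real fundus photographs are this easy.
What passing tests do **not** show: robustness to segmentation errors,
anatomical tree structure, illumination variation, camera artifacts, or
the true difficulty of distinguishing *mild* from *none* in vivo — the
generator draws tubes, not retinas, and its grade signal is honest but
exaggerated relative to clinical imagery.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 0-based, origin top-left, everywhere in
  manifests and candidate tables; R's 1-based indexing is internal only.
* Probability ties in `predict()` resolve to the lowest class index.
* A vessel-free mask is a refinement error; an empty candidate list is a
  normal pipeline outcome (reported, not raised).
* Zero denominators in precision/recall yield `NaN` plus a warning
  record, never silent zeros.
* Class weights reject zero counts (ln 0) and a lone singleton class
  (ln N = 0).
* Scenes are quantized to 8 bits at generation so in-memory rasters are
  byte-identical to their PNG round-trip, which is what makes pipeline
  reports reproducible byte-for-byte for a fixed config and seed.

## Problem sizes used by the test suite

Unit tests run on 40-scene datasets (~160 patches). The quantitative
contracts use: 200 scenes (detection recovery, tolerance 5 px), 100
seeded splits of 50 subjects, 10<sup>4</sup> augmentation draws, and —
for the ensemble-no-harm check — one 250-scene dataset split 800/100/100
patches with four sub-models (γ = 0, 1, 2, 3) trained for 15 epochs at
three seeds. These sizes were chosen so the full suite runs on a single
CPU in well under half an hour while keeping every threshold meaningful
at the realized sample sizes.

## Known limitations

* The vessel segmenter and artery/vein pixel classifier are out of
  scope; the pipeline consumes their rasters (or the generator's) as-is.
* The backbone registry contains compact CNNs; large pretrained
  backbones (ResNet/Inception/DenseNet-class) would slot into the same
  `submodel_spec()` interface but are not bundled.
* The detector's morphology (contact pixels + skeleton traversal) is
  this package's concrete definition of a "classic" crossing detector;
  published pipelines rarely specify theirs precisely enough to
  replicate operator-for-operator.
* Optic-cup masks are consumed, never detected.
* Synthetic grades are planted morphology, not pathology; accuracy
  numbers on generated data must not be read as clinical performance.
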