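---
title: "Multi-task placenta segmentation in 3D ultrasound: models, uncertainty, fusion and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task placenta segmentation in 3D ultrasound: models, uncertainty, fusion and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plaseg)
```

## The problem

Automatic segmentation of the placenta in 3D fetal ultrasound is hard for
three connected reasons. First, placental appearance depends strongly on
position: an *anterior* placenta lies close to the probe and images with
high contrast, while a *posterior* placenta sits behind the fetus and is
degraded by acoustic shadows and attenuation. A model trained on one
position class is effectively tested out-of-distribution (OoD) on the
other. Second, the poor contrast of ultrasound makes even expert manual
annotation ambiguous, so any single reference mask is one draw from a
distribution of plausible segmentations. Third, the ultrasound sector
(frustum) is too narrow to hold a late-gestation placenta, so whole-organ
assessment needs several probes imaging the same anatomy from different
angles, fused into one extended field of view.

`plaseg` implements a complete toolkit for this setting: a family of 3D
convolutional networks in which placental-position classification serves
as a pretext task for segmentation, Monte-Carlo (MC) dropout uncertainty
scored with the Generalized Energy Distance (GED), voxel-weighted
multi-view fusion, the full evaluation-metric protocol, and placental
volumetry. Because clinical cohorts of this kind are private, the package
ships a synthetic frustum-phantom generator that emulates the relevant
physics qualitatively, and every claim the test suite makes is made on
those phantoms.

## Network family

Five variants share one `network_config()`:

* **UNet** — the segmentation baseline. A 3D encoder–decoder with skip
  connections; each level is a residual block (two 3×3×3 convolutions,
  each followed by group normalization and ReLU, with an identity
  shortcut that becomes a 1×1×1 projection when the channel width
  changes). Downsampling is 2×2×2 max pooling; upsampling is
  nearest-neighbour followed by a residual block on the concatenated skip
  features. Dropout (rate 0.2) follows every decoder level and doubles as
  the MC-dropout mechanism at test time. The output is a single-channel
  sigmoid foreground probability.
* **EncNet** — the classification network: the same encoder followed by a
  pretext head (a 3×3×3 convolution with layer normalization and ReLU,
  global average pooling, then a linear layer with layer normalization
  and sigmoid scores renormalized to a probability vector over
  anterior / none / posterior). One additive attention gate sits at
  encoder level 3: a 1×1×1 projection of the level-3 features plus a
  projection of the upsampled bottleneck pass through ReLU and a 1×1×1
  convolution with sigmoid to give a single-channel gating map, which
  multiplies the level-3 features. The pooled gated features join the
  pretext head's input, so the gate is trained by the classification
  loss, and the gating map (upsampled to input resolution) is exposed as
  the attention map.
* **MTUNet** — UNet and the EncNet head on one *shared* encoder (the same
  parameter arrays, not copies). The decoder consumes the gated skip at
  the attention level, so the gate serves both tasks.
* **TUNet / TMTUNet** — the same architectures as UNet / MTUNet, but
  initialized by `transfer_init()` from a pretrained EncNet: TUNet copies
  the encoder and bottleneck; TMTUNet additionally copies the pretext
  head and the attention gate. Decoder weights always start fresh.

The default configuration is five levels with (16, 32, 64, 128, 256)
feature maps at 128³ input. Defaults the architecture description leaves
open were fixed once and documented here: group-normalization group count
8 (capped at the channel width), 3×3×3 kernels with padding 1, the
pretext head's hidden width equal to the bottleneck width, and the
attention gate's inner width equal to the gated level's width.

### Why an in-package network engine

No deep-learning framework is available to this package's R dependency
set, and the network family *is* the package's core contribution, so
`plaseg` carries a compact 3D CNN engine of its own: `im2col`-based
convolutions (Rcpp kernels feeding BLAS matrix products), group/layer
normalization, max pooling, nearest upsampling, dropout and the attention
gate, each with hand-derived backward passes, optimized with Adam. The
engine is validated by a finite-difference gradient check in the test
suite (relative error below 1e-4 on randomly sampled parameters of a full
multi-task model), which is the strongest available oracle for
backpropagation correctness.

## Losses and training schedule

The segmentation loss is binary cross-entropy plus soft-Dice loss,
`L_seg = BCE(p, S) + (1 - (2·Σp·S + ε) / (Σp + ΣS + ε))`, with ε = 1e-5
so that an empty prediction of an empty reference costs nothing, and
probability clipping at 1e-7 inside the BCE only. Classification uses
cross-entropy. The multi-task loss is

L_MT = L_Class + β · L_Seg,   β > 0 (default 4),

so β > 1 emphasizes the segmentation downstream task. β also sets the
alternating schedule: because many more images carry position labels than
masks, each training cycle runs one classification mini-batch step
followed by β segmentation steps until both loaders are exhausted
(`alternating_schedule()`); a segmentation step optimizes the full
multi-task loss since those images carry both labels, while images of
class *none* (no placental tissue, hence no mask) contribute only the
classification term — their segmentation term is skipped, not
zero-filled. "Sub-iteration" is interpreted as one mini-batch step; the
1:β ratio, not the granularity, carries the semantics.

Default optimization follows the per-variant protocol: Adam throughout;
EncNet lr 1e-5 for 400 epochs; UNet lr 1e-4 decayed ×0.1 at epochs
30/70/90 over 100 epochs; multi-task variants lr 5e-5 decayed at 20/30/40
over 50 epochs. Fixed epoch budgets replace "train until convergence" for
reproducibility. Augmentation draws flips about the x and z axes only
(never the depth axis, which would invert the frustum), translations up
to 10 voxels, rotation up to 15° about the depth axis, scaling ±10% and a
lateral shear up to 15 voxels, applied identically to image (trilinear)
and mask (nearest). One global seed covers weight initialization, data
order, dropout and augmentation draws; runs are exactly reproducible in
this single-threaded engine.

## Uncertainty: MC dropout and the Generalized Energy Distance

`mc_dropout_sample()` keeps the decoder dropout active at test time and
thresholds each of `n_samples` (default 20) stochastic forward passes at
0.5, giving samples from an approximate posterior over segmentations.
Two such distributions — e.g. MC samples versus a set of rater
annotations — are compared with the squared energy-distance estimator

GED² = 2·E[d(A,B)] − E[d(A,A′)] − E[d(B,B′)],  d = 1 − Dice (or 1 − IoU),

with plug-in means over all pairs; the within-set means run over all
ordered pairs including self-pairs, negative finite-sample estimates are
clamped to zero and flagged, and both the squared form and its root are
reported because published "GED scores" are ambiguous between the two.
Empty-mask conventions: d(∅,∅) = 0 and d(∅, X≠∅) = 1. Pairwise distances
are accumulated in sorted order so the estimate is bit-identical under
sample reordering and argument swaps.

## Evaluation protocol

Overlap: Dice `2|A∩B|/(|A|+|B|)` and IoU `|A∩B|/|A∪B|`, both 1 for two
empty masks. Surface metrics use surface voxels (foreground with a
face-adjacent background neighbour) and Euclidean distances in mm
honouring anisotropic spacing: ASD is the mean of the *pooled union* of
both directed distance multisets (chosen over the mean-of-directed-means
so tests are unambiguous; the two differ only when surface sizes differ),
and RHD95 is the maximum of the two directed 95th percentiles — the
common robust-Hausdorff convention. Surface metrics versus an empty mask
are errors, not sentinel values; the evaluation harness records them as
missing. Classification is scored one-vs-rest per class: balanced
accuracy (mean of sensitivity and specificity), precision, and F1.
Variant comparisons use the paired Wilcoxon signed-rank test
(normal approximation, tie-corrected, zero differences dropped, no
continuity correction, no multiple-comparison adjustment) with effect
size r = |z|/√N categorized small (r ≤ 0.3), moderate (0.3 < r < 0.5) or
strong (r ≥ 0.5).

## Multi-view geometry and fusion

A two- or three-probe holder fans the probes about the shared apex line
at a fixed inter-probe angle (default 30°, which keeps a large overlap
between sectors); `holder_transforms()` returns the corresponding rigid
transforms, and each `probe_view()` maps its apex-centred local frame
into world mm so all apexes coincide at the holder origin. Registration
is out of scope: alignment comes only from the holder geometry or
user-supplied matrices.

Fusion weights follow the qualitative contract that points near the beam
axis, at shallow depth and with strong signal are most trustworthy. The
separable form

w = cosᵖ(θ/θ_max · π/2) · exp(−λ·depth) · (I + ε  if signal weighting)

with defaults p = 2 and λ = 0.01/mm is the package's concrete choice of a
weight function stated only qualitatively in the source protocol; the
*tested* contract is monotone decay with lateral angle and depth, zero
weight outside the frustum, and higher weight for stronger signal (which
suppresses view-dependent shadows). `fuse_images()` computes the
weight-normalized mean of trilinearly resampled view intensities on the
bounding-box grid of all transformed frusta at the minimum input spacing.
`fuse_segmentations()` fuses per-view foreground *probabilities* (chosen
over binary masks for smoother seams) with the same geometric weights,
signal term disabled, thresholded at 0.5 with ties resolving to
foreground.

## Volumetry

`placental_volume()` is pure voxel counting times voxel volume
(partial-volume effects ignored, as in standard mask volumetry).
`reference_volume()` evaluates the MRI-derived gestational growth curve
f(x) = −0.02x³ + 1.6x² − 13.3x + 8.3 mL over its supported 19–33-week
range (the published curve's SD and min–max bands are not reproduced
here). `bland_altman()` reports mean difference and conventional 1.96-SD
limits of agreement.

## The phantom generator as study condition

The synthetic generator defines the conditions under which everything is
tested, so its choices matter. A phantom is a pyramidal frustum sector
(default opening 60°, apex at the top of the depth axis; depth is the
second array axis and is never flipped). The placenta surrogate is a
curved slab — a shell segment bending away from its uterine wall — whose
centre sits at 28% of the depth extent for anterior and 72% for posterior
phantoms, matching the geometry that makes the two classes different
distributions. Appearance: background tissue level 0.30, slab level
0.75, a global depth attenuation exp(−0.004·depth_mm), multiplicative
Rayleigh-like speckle (mean-one Rayleigh field blended with weight
`speckle_sigma`), and, for posterior phantoms only, `shadow_count`
occluding cones cast from the apex through the region in front of the
slab with attenuation `shadow_strength`. The speckle field is drawn
before the shadow parameters so phantoms differing only in shadow count
share identical speckle. `generate_dataset()` groups 2–5 images per
synthetic patient of a single class and jitters slab and artifact
parameters within their valid ranges, mirroring per-patient clustering in
clinical cohorts.

What the phantoms do *not* emulate: real speckle correlation, fetal
anatomy, refraction/reverberation artifacts, inter-rater ambiguity, or
the appearance diversity of real placentas. Passing the phantom studies
therefore demonstrates that the algorithms behave as specified under a
controlled distribution shift, not that clinical performance numbers
would be reproduced.

## Scaled-down distribution-shift study

The full-scale protocol (128³ volumes, hundreds of epochs) is not
appropriate for a test suite, so the packaged study runs at deliberately
small size: 32³ phantoms, 40 images per class, a 3-level network with
(4, 8, 16) features, 12 training epochs (learning rate 2e-3, decayed at
epoch 9) for segmentation variants, and 6 epochs for EncNet pretraining —
sizes chosen so the whole study runs in minutes on one CPU while still
exhibiting the phenomena of interest. Patient-grouped splits
(`make_splits()`, stratified by class, ~60/20/20) guarantee no patient
crosses partitions and every patient appears in exactly one test set
across folds. Training-set modes A (anterior-only), P (posterior-only)
and AP control the segmentation training distribution; classification
always sees all classes, which is exactly the mechanism by which the
multi-task variants receive information about the out-of-distribution
class. The properties asserted are *orderings*, not absolute values:
in-distribution Dice is high for the baseline, out-of-distribution Dice
drops sharply, and the transfer multi-task variant recovers a large part
of that drop — the qualitative signature of the full-scale study.

## Numerical choices and degenerate inputs

* Soft-Dice smoothing ε = 1e-5; BCE clipping 1e-7; Adam (β₁ 0.9, β₂
  0.999, eps 1e-8).
* Probability/mask threshold 0.5 everywhere, ties to foreground.
* Dice/IoU of two empty masks is 1; GED distance between two empty masks
  is 0; surfaces of empty masks are undefined (error).
* Wilcoxon: all-zero differences return the degenerate r = 0.
* `alternating_schedule()` requires an integer β and instructs rounding
  otherwise; a depleted loader drops out of the cycle.
* Voxel indexing is 1-based in R; the frustum apex is at depth index 1;
  world coordinates are mm, right-handed; NIfTI pixdim is authoritative
  for spacing; masks are written as 0/1 float volumes.

## Known limitations

* The engine is CPU-bound; the full 128³/5-level configuration is
  supported but impractically slow for training outside small studies.
* Nearest-neighbour upsampling in the decoder (rather than transposed
  convolution) and single-channel attention are the simplest members of
  their design families; they were chosen for robustness at small scale.
* Phantom realism is qualitative only (see above).
* The MC-dropout posterior is an approximation; no explicit
  noisy-label or latent-variable uncertainty modeling is attempted.
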