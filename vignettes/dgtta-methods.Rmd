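---
title: "Domain-generalized pre-training and test-time adaptation for 3D segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-generalized pre-training and test-time adaptation for 3D segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A segmentation network trained on one imaging domain (say, abdominal CT)
typically collapses when applied to another (say, abdominal MR): the anatomy
is unchanged, but the mapping from tissue to intensity is remapped
non-linearly and non-monotonically, corrupted by acquisition noise, and
modulated by smooth intensity inhomogeneity. `dgtta` implements a two-stage
answer that never needs target labels:

1. **Domain-generalized pre-training.** The network is trained on labeled
   source data only, but its *inputs* are made robust: a randomized shallow
   convolutional network remaps intensities afresh at every iteration (GIN
   augmentation), and/or the image is replaced by the 12-channel
   self-similarity context (SSC) descriptor, which encodes local structural
   similarity rather than raw intensity.
2. **Source-free test-time adaptation (TTA).** Given one unlabeled target
   scan, the pre-trained weights are fine-tuned for a fixed, small number of
   steps to make predictions *consistent* across two differently
   spatially-augmented views of the same scan. No source data, labels, or
   target statistics are used.

## The model pieces

### GIN intensity augmentation

An augmented image is the convex blend `alpha * g(x) + (1 - alpha) * x`,
where `g` is a shallow convolutional network whose weights are freshly
re-randomized for every training iteration and `alpha ~ U(0, 1)` per volume.
The literature leaves the architecture of `g` open; this package uses 4
convolution layers (8 hidden channels, leaky rectifier), weights drawn from
a scaled normal, edge-replicated borders (so constant inputs stay constant),
and an output rescaled to the input's mean and standard deviation so
augmented images stay in a trainable range. The default kernel size is 1: a
voxelwise nonlinear intensity remapping that leaves spatial structure — in
particular the local self-similarity pattern the SSC descriptor keys on —
exactly intact. Kernel 3 (which additionally mixes neighbourhoods, and in
composition with the descriptor degrades the structural signature) is
available as an option. These are declared defaults in `gin_config()`, not
claimed fidelity to any particular prior work.

### SSC descriptor

For each voxel, the six neighbours at `patch_distance` voxels along the
axes form 12 *diagonal* pairs (opposite neighbours are excluded). For each
pair the sum of squared differences (SSD) between the two neighbouring
patches is computed, and the channel value is `exp(-SSD / sigma2)` with
`sigma2` a per-voxel noise estimate: the mean of that voxel's 12 SSDs. The
descriptor deliberately ignores the centre patch itself, so any affine
intensity change `a*x + b` cancels: SSD scales with `a^2` and so does
`sigma2`, leaving the ratio unchanged. Channel order follows a fixed
lexicographic enumeration of the neighbour offsets (`ssc_pair_offsets()`),
making outputs reproducible.

Two readings of "the mean of all patch distances" are defensible: a
per-voxel mean or one image-global scalar. The per-voxel reading preserves
*local* contrast invariance (each voxel is normalized by its own
neighbourhood energy) and matches the descriptor's self-similarity lineage;
it is the default, with `sigma_mode = "global"` available. The normaliser is
floored at `max(1e-6 * mean(SSD), 1e-12)` so perfectly flat regions yield
`exp(0) = 1` rather than 0/0. Borders are handled by edge replication,
keeping the output grid equal to the input grid.

### The two-branch consistency scheme

For a target scan `x`, each adaptation step draws random patches. Each
patch is pushed through two branches, A and B, each applying an independent
random *invertible affine* spatial transform (rotation up to 10 degrees,
isotropic scale 0.9–1.1, shear up to 0.05, translation up to 5% of extent —
unstated in the source literature, declared here as mild, invertible
defaults in `affine_ranges()`). The two softmax outputs are inverse-warped
back to the common frame. Voxels introduced at the borders by either warp
carry no real image content; instead of a sentinel intensity value the
package carries an explicit boolean validity channel through every warp
(this avoids collisions with genuine probability values, and validity is
propagated conservatively: a warped voxel is valid only if every
interpolation corner with non-zero weight was itself valid). The
consistency mask is the logical AND of the two branch validity masks.

The masked fields are compared with a Dice-form loss whose denominator
uses exponent `d`:

```
loss = 1 - mean_C [ (2 * sum(a*b) + e) / (sum(a^d + b^d) + e) ]
```

With `d = 2` the loss is exactly zero whenever the two predictions agree,
soft or not — the loss landscape is zero along its diagonal. With `d = 1`
agreement at soft values is still penalised, which pushes the network to
also maximise confidence; `d = 2` is the default because confidence
inflation is not the objective of consistency adaptation. `e = 1e-5` is a
declared default (its value is not stated in the source literature). The
background channel is excluded from the channel mean by default; the class
subset is configurable because the classes of interest are a use-case
choice. An empty mask (fully disjoint fields of view) yields zero loss with
a warning so the patch loop can skip degenerate draws.

### Optimisation strategy

Adaptation uses AdamW (learning rate `1e-5`, weight decay `0.01`, no
scheduling), exactly `N_s = 12` steps, each accumulating gradients from
`N_p = 16` randomly drawn patches into a single update — patch-based
inference limits the field of view, and accumulation prevents overfitting
the weights to one region. Patch origins are uniform over valid origins: at
test time no labels exist, so there is no foreground-biased sampling. By
default gradients flow only through branch A (branch B's output is treated
as a fixed target, i.e. detached), both branches receive spatial
augmentation, and intensity augmentation is off — the configuration found
to be the best trade-off across conventionally and domain-generalized
pre-trained models in the source study's ablation. All of these are
exposed in `tta_config()` (`grad_branches`, `spatial_aug_branches`,
`intensity_aug`, `parameter_subset`) for ablation parity. Adapted weights
are discarded after predicting the sample; adaptation is strictly
per-sample and the final inference routine averages the softmax outputs of
an ensemble of three independently pre-trained, independently adapted
models (independent random streams per member; a `shared_stream` style
coupling was rejected as the members are meant to disagree).

There is deliberately no early stopping: a reliable convergence measure
without target ground truth is not available, so the step count is fixed.

## The backbone

The method is the input-feature pipeline plus the adaptation loop; the
backbone is treated as given. The package ships a compact 3D
encoder–decoder: three resolution levels (two 2x average poolings), one
3x3x3 convolution block per level, nearest-neighbour upsampling with skip
concatenation, and a softmax head (`base_filters = 8`, about 60k weights).
Forward and backward passes are hand-written (convolutions in C++), which
keeps the whole pipeline trainable and differentiable on a single CPU and
makes gradient correctness directly testable against finite differences.

Two deliberate backbone choices differ from large-scale practice:

* **No normalisation layers by default.** With 16^3 training patches a
  patch frequently covers a single structure; instance statistics then
  cancel the absolute-intensity signal and the compact network plateaus.
  Instance normalisation (and a `"batch"` alias, identical at batch size
  one) remains available via `norm =`, and when present its scale/shift
  parameters are what `parameter_subset = "normalization_only"` adapts.
* **Z-scoring of descriptor channels only** (`apply_feature_pipeline()`).
  The SSC channels live in a narrow band around 0.5; per-volume z-scoring
  conditions them for training and does not affect the descriptor's
  invariance. Raw intensities are deliberately *not* normalised: any
  per-volume statistic depends on how much foreground the volume contains,
  so normalising with it would shift the class intensity levels from
  volume to volume and destabilise the raw-intensity route.

Supervised pre-training uses Dice + cross-entropy on class-balanced random
patches (a class present in the volume is drawn uniformly, then a random
voxel of that class becomes the patch centre), Adam at `1e-3`, and is fully
deterministic under its `seed`. SSC features are computed on the whole
volume *before* patch extraction so patch borders see true neighbourhoods;
GIN is re-randomized at every volume visit. In `gin+ssc` mode the
composition is exactly `SSC(GIN(x))` at training time and `SSC(x)` at test
time.

## The synthetic cross-domain phantoms

Real cross-domain benchmarks need multi-hour GPU training; the package
instead ships a generator whose default spec defines the study conditions
for all tests:

* 64^3 voxels at 1.5 mm isotropic spacing (the uniform spacing the
  pipeline resamples to), 4 foreground classes, each a randomized
  smooth-boundary ellipsoid.
* **Source domain (CT-like):** monotone per-class intensity lookup
  (0.25, 0.45, 0.65, 0.85 over background 0), additive Gaussian noise
  (sigma 0.05).
* **Target domain (MR-like):** a non-monotone, non-affine remapping on a
  different overall scale (1.70, 0.50, 1.30, 0.90 over background 0.20 —
  classes 1 and 2 invert their order), extra noise, and a smooth
  multiplicative bias field (`exp` of a random quadratic in normalized
  coordinates, amplitude 0.3). A merely affine gap would be closed by the
  SSC descriptor by construction, so the remapping is deliberately
  non-affine.
* **Class-distinctive oriented texture.** Each class carries a sinusoidal
  plane-wave texture with a class-specific orientation and wavelength
  (5–9 voxels). The pattern geometry is shared by both domains — it plays
  the role of anatomy — while its amplitude and, for classes 1 and 3, its
  sign change with the domain (a locally affine appearance change).
  Without texture the phantom classes would differ *only* in absolute
  intensity, which is precisely the cue the SSC descriptor discards; the
  descriptor route would then have nothing to generalize from. Real tissue
  is textured; this is the minimal analogue.

All randomness flows from one seed through named substreams (geometry,
intensity/bias/texture phases, noise) so components vary independently.
What the phantoms do **not** emulate: anatomical shape realism, partial
volume effects, resolution or orientation gaps, and scanner-specific noise
correlations. Passing the package's tests therefore demonstrates the
mechanics and the direction of the method's effects under a controlled
intensity-gap model, not clinical performance.

## Evaluation

Per-class Dice is reported in percent; HD95 is the 95th percentile (linear
interpolation between order statistics) of the *pooled* symmetric
surface-distance set — distances from prediction surface to ground-truth
surface and vice versa pooled before taking the percentile. The directed-max
convention is the main alternative; the pooled one is declared so numbers
are reproducible. Surfaces are boundary voxels (a 6-neighbour outside the
class, with volume edges counting as outside), distances in physical mm. A
class absent from either map has undefined HD95 and is excluded from means
with the exclusion count reported. Improvements are tested with the
one-sided paired Wilcoxon signed-rank test (`stats::wilcox.test`,
alternative "greater"); an all-zero difference vector is degenerate and
reported as p = 1.

## Numerical choices and degenerate inputs

* Resampling to a target spacing uses the closed-form output size
  `round(n * spacing / target)`, trilinear interpolation for scalar
  volumes (edge-clamped), nearest for label maps (linear interpolation of
  labels is rejected), and is the identity at the current spacing.
* Warps fill out-of-field voxels with 0 but truth lives in the validity
  mask; warped probability maps are renormalized per voxel on valid voxels
  (trilinear interpolation of a simplex is a simplex up to rounding, so
  this is a safeguard).
* The affine sampler composes rotation, shear and isotropic scale about
  the grid centre and stores the exact matrix inverse; matrices with
  near-zero determinant are rejected.
* Softmax is computed with per-voxel max subtraction; cross-entropy clamps
  probabilities at 1e-12.
* The TTA loop skips a patch whose consistency mask is empty and skips the
  whole step (with a warning) if all patches are empty.

## Problem sizes used by the test-suite experiments

The end-to-end experiment trains on 8 source phantoms (64^3), evaluates on
6 held-out phantoms rendered in both domains, pre-trains the raw-intensity
model for 30 epochs and the `gin+ssc` model for 24 epochs (4 class-balanced
patches of 16^3 per volume per epoch), and adapts with the default
`tta_config()` (12 steps, 16 patches). These sizes are the package's
declared desk-scale study conditions: large enough for the cross-domain
collapse, the descriptor's robustness, and the adaptation's recovery to be
measurable, and small enough to run on one CPU. Headline numbers from
large-scale GPU benchmarks are out of reach at this scale by design; the
experiments assert directions of effects, not magnitudes.

## Known limitations

* The backbone is a compact stand-in, not a self-configuring framework
  network; absolute Dice values on the phantoms reflect that.
* Orientation harmonization is not performed; volumes are used as stored.
* The spatial-augmentation consistency scheme cannot repair a model whose
  errors are spatially consistent (e.g. a systematic label swap): its
  gradient is zero wherever the two branches already agree.
* Intensity augmentation inside the TTA branches is implemented for
  ablation parity but is off in the default configuration.
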