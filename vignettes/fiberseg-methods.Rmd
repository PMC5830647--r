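---
title: "Axon and myelin segmentation: models, procedures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Axon and myelin segmentation: models, procedures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fiberseg)
```

# The problem

Osmium-stained electron microscopy renders myelin sheaths as high-contrast
annuli wrapped around axons. Quantifying white matter — axon diameters,
densities, axon/myelin volume fractions and g-ratios — requires labelling
every pixel of such images as background, myelin or axon, over fields of
view that can contain tens of thousands of fibers. `fiberseg` implements a
complete patch-based semantic-segmentation pipeline for this task: data
preparation, a fully specified encoder–decoder convolutional network with
its training procedure, overlap-tile inference, evaluation metrics, and
morphometric map extraction. A synthetic fiber-image generator with exact
ground truth makes the whole pipeline testable on a desktop with no
microscopy data.

# Data model and preparation

Images are 8-bit grayscale grids with a known isotropic pixel size in
micrometers (PNG/TIFF on disk, real-valued in memory; the pixel size rides
in a JSON sidecar because PNG carries no physical metadata). Label masks
use three classes encoded 0 (background), 127 (myelin), 255 (axon) on
disk and 0/1/2 in memory. The coordinate convention is row-major, 0-based,
origin at the top-left pixel corner; pixel centers sit at
`(i + 0.5) * pixel_size` micrometers.

Preparation resamples every image to the working resolution of the model
(0.1 µm/pixel for the SEM variant, 0.01 µm for TEM), with bilinear
interpolation for intensities. Labels are resampled with nearest-neighbor
instead: bilinear interpolation of a label image produces values outside
the class alphabet, so class preservation takes precedence. Images are
then cut into non-overlapping 512 × 512 patches; sides that are not a
multiple of the patch size are mirror-padded up to the next multiple,
because reflection introduces no intensity discontinuity at the seam
(constant or zero padding would). Patches are split at random into
training and validation sets with a 70/30 ratio (train count =
`round(0.7 n)`).

Each patch is normalized by global 256-bin histogram equalization followed
by standardization to zero mean and unit variance. The order matters and
is fixed as equalization first: the network then always receives zero-mean,
unit-variance input regardless of the equalization map. The standardization
variance is floored at 1e-8, so a constant patch maps to all zeros rather
than dividing by zero.

# Network architecture

The network is a depth-4 encoder–decoder, fully convolutional, so any
input whose sides are divisible by 16 is accepted.

* **Contracting path** — four blocks with channel widths 16, 32, 64, 128.
  Each block applies `convs_per_block` convolutions (3 in the SEM variant,
  2 in TEM) with 5 × 5 kernels in the first block and 3 × 3 elsewhere;
  every convolution is bias-free and followed by batch normalization and
  ReLU. Resolution is halved after each block by a channel-preserving
  5 × 5 convolution of stride 2 (again BN + ReLU) rather than pooling.
* **Expanding path** — mirror of the contraction, deepest level first:
  bilinear ×2 upsampling followed by a 2 × 2 convolution down to the skip
  connection's width, concatenation with the block's pre-stride features,
  then `convs_per_block` convolutions, the first of which halves the
  concatenated width (kernels 3 × 3 except 5 × 5 at the finest level).
* **Classifier** — a 1 × 1 convolution with bias to 3 channels and a
  per-pixel softmax.

Several of these details (bias-free convolutions, the 5 × 5 strided
downsampling, the 2 × 2 post-upsampling convolutions, the 5 × 5 kernels at
the finest expansion level, the biased 1 × 1 classifier) are not
individually decisive on paper, but they are jointly pinned down by an
exact checksum: the SEM and TEM variants must total 1,953,219 and
1,552,387 trainable parameters. `count_trainable_parameters()` computes
the total from the layer plan (kernel weights + batch-norm scale/shift
pairs + classifier bias; running statistics are not trainable) and
`parameter_ledger()` exposes the per-layer breakdown. The components are:
contracting block convolutions 497,040 / 297,104 (SEM / TEM), strided
convolutions 544,000, up-convolutions 108,544, expansion block
convolutions 799,744 / 599,808, batch normalization 3,840 / 2,880, and
classifier 51. The SEM−TEM difference, 400,832, is exactly one extra
bias-free convolution plus batch norm per block on each path. Changing any
of the reconstructed details breaks at least one of the two totals.

The activation order is convolution → BN → ReLU throughout, including
strided and up-convolutions — BN "before each activation". Dropout (rate
0.25) acts after the activation of each block convolution on both paths,
but not on strided, up-, or classifier convolutions; dropout has no
parameters, so the checksum cannot arbitrate its placement, and the block
convolutions are where "used in the convolutional layers" most plausibly
points. Weights initialize with fan-in-scaled (He) normals,
`N(0, 2 / (k² · in_channels))`; BN scales start at 1, shifts at 0.

The layers themselves (im2col GEMM convolutions with TensorFlow-style
"same" zero padding, batch normalization over batch and spatial axes,
pixel-center bilinear upsampling) and their analytic backward passes are
implemented in C++ on BLAS. A finite-difference gradient check on a tiny
network is part of the test suite.

# Training procedure

`training_config()` reproduces the published procedure:

| parameter | default | meaning |
|---|---|---|
| `lr0` | 0.001 | starting learning rate |
| `decay_power` | 0.9 | polynomial decay exponent |
| `decay_epochs` | 200 | decay length; training stops there |
| `batch_size` | 8 | patches per optimizer step |
| `class_weights` | 1.1 / 1.0 / 1.3 | background / myelin / axon |
| `dropout` | 0.25 | block-convolution dropout |
| BN momentum | 0.7 → 0.9 | scheduled per epoch |
| optimizer | Adam (0.9, 0.999, 1e-8) | |

The loss is a spatially-weighted 3-class cross-entropy: the mean over
pixels of `w[class] · (−log p_class)`, with probabilities floored at
1e-12 before the logarithm. With unit weights it reduces to ordinary
cross-entropy.

The learning rate decays polynomially, `lr0 · (1 − t/T)^0.9`, applied per
optimizer step with `T = decay_epochs × steps_per_epoch` (per-step
application is the convention of the schedule's origin; a per-epoch
variant differs negligibly). A batch-norm momentum "decayed from 0.7 to
0.9" is literally contradictory — the value increases — so it is read as
intent: start with a low momentum so the running statistics track the
batches quickly, end high for stability. The implemented schedule is an
exponential approach, `m(e) = 0.9 − 0.2 · exp(−5 e / decay_epochs)`,
which is 0.7 at epoch 0 and ≈ 0.899 at the decay length; the rate
constant 5 makes the schedule effectively complete within the decay
length without ever reaching 0.9 exactly.

Each epoch shuffles the training patches, iterates batches of 8 (the last
partial batch is kept — desk-scale datasets are too small to drop data),
augments each patch on the fly, then normalizes it (augmenting the raw
intensities keeps the blur and elastic transforms on the physical scale;
normalization afterwards guarantees the network still sees zero-mean
input). Validation (no augmentation, running BN statistics, dropout off)
is recorded every epoch, and the parameters with the lowest validation
loss are returned; no particular checkpoint rule is prescribed by the
procedure, and lowest validation loss is the conservative default.

# Data augmentation

Six randomized transforms are applied jointly to each training patch and
its label patch, in the fixed order shift → rotation → rescale → flip →
blur → elastic deformation, each independently with probability 0.5 (the
source gives ranges but no application probability; 0.5 is standard
practice and configurable). Magnitudes: shifts up to 10% of the patch
side per axis, rotations of 5–89°, rescaling by a factor in [1/1.2, 1.2],
horizontal or vertical flips, Gaussian blur with SD uniform in [0, 4]
pixels (image only), and elastic deformation with per-pixel displacement
fields drawn uniformly in [−1, 1], smoothed by a Gaussian of fixed SD 4,
and scaled by a coefficient α uniform in [1, 8] — smoothing averages
values in [−1, 1], so α bounds the maximum displacement in pixels. Shift
and rotation signs are randomized (the stated ranges are magnitudes).
All geometric warps use mirror fill, bilinear interpolation for the image
and nearest-neighbor for the label, so augmented masks remain exactly
3-valued. Rescaling above 1 crops the central `floor(512/f)` square and
scales it back up; below 1 it downscales and mirror-pads back, centered.

# Inference: overlap-tile stitching

A fully convolutional network segments borders less reliably than
interiors. Inference therefore slides a 512-pixel window in steps of
`512 − 2d` and keeps only each window's central core, with the overlap
`d = 25` pixels by default. The image (already resampled to the model's
working pixel size) is mirror-padded by `d` plus the remainder needed to
make the interior a multiple of the core, so every original pixel —
border pixels included — is predicted with full context and emitted
exactly once. Each window is normalized independently, exactly as during
training. The three stitched probability maps are resampled back to the
native resolution bilinearly *before* the per-pixel argmax: interpolating
probabilities is meaningful where interpolating labels is not. Argmax
ties break towards the lowest class index, deterministically.

# Evaluation metrics

Segmentation quality: Dice coefficients `2|A∩B| / (|A|+|B|)` for the axon
and myelin binarizations separately (two empty masks give Dice 1), and
3-class pixel-wise accuracy. Detection quality: axon objects are
8-connected components of the axon class; each predicted object's
centroid is assigned to the ground-truth object containing it. A
ground-truth object with at least one assigned centroid is a true
positive; with none, a false negative; predicted objects whose centroid
falls in no ground-truth object — plus surplus centroids beyond the first
in one object — are false positives. Sensitivity is TP/(TP+FN), precision
TP/(TP+FP); zero denominators are reported as 0 with an explicit flag.
The containment rule penalizes both misses and over-segmentation while
needing no distance threshold; the test suite checks all metrics
bit-for-bit against an independent brute-force implementation.

# Morphometry

Per axon object (8-connected, area = pixel count × pixel_size²):
equivalent diameter `√(4·Area/π)` and centroid. Binned maps at
50 × 50 µm² (configurable): per bin, the axon and myelin volume fractions
AVF and MVF (pixel fractions), the aggregate g-ratio
`√(1/(1 + MVF/AVF))`, axon density in axons/mm², and the mean and SD of
the equivalent diameters of axons *whose centroid lies in the bin* — the
centroid rule counts every axon exactly once, unweighted (the alternative,
area-weighting boundary axons, is not what the map definitions suggest).
Partial edge bins are flagged invalid rather than rescaled; so are bins
with no axon pixels, and — when a region mask is supplied — bins with
less than 50% region coverage.

# The synthetic generator

`sample_population()` places non-overlapping annular fibers by dart
throwing: log-normal axon diameters (median 3 µm, log-SD 0.3, matching
the 1–10 µm range of myelinated fibers), truncated-normal g-ratios (mean
0.7, SD 0.05, bounds 0.4–0.95, consistent with the 0.5–0.75 range of
healthy white matter), centers uniform with rejection when outer circles
would come within `min_gap_um` (default 0.2 µm) of touching. The small
gap plays the role of extracellular space and guarantees each fiber
rasterizes to its own connected object. The default canvas is 102.4 µm at
0.1 µm/pixel — a 1024² image, deliberately larger than one patch so the
patching and stitching code paths are exercised. Default fiber counts put
tens of axons in a 512² patch, the density regime the working resolution
was designed for.

`rasterize()` samples pixel centers (a pixel belongs to the axon disk or
myelin annulus iff its center lies inside), with no anti-aliasing, so
masks are exactly 3-valued; rasterization error in areas is O(perimeter),
under 5% for objects ≥ 20 pixels across. `render()` paints class mean
intensities (myelin-dark for the TEM-like polarity, myelin-bright for
SEM-like), blurs, adds Gaussian noise, and clips to [0, 255].

What the generator does **not** emulate: subcellular texture
(mitochondria, microtubules), unmyelinated axons, incomplete or
degenerating sheaths, staining gradients, charging artifacts, focal blur
variation. Passing the desk-scale learning check therefore demonstrates
that the architecture, loss, optimizer and pipeline plumbing can learn
and reproduce annular geometry from realistic contrast and noise — not
that the package reaches any particular accuracy on real microscopy,
which depends on training data this package does not ship.

# Desk-scale problem sizes and the desk-scale operating point

The test suite and acceptance checks run on one CPU with problem sizes
chosen to finish in minutes while staying in the regime the procedures
were designed for: parameter-recovery checks use a 1024² canvas with 120
fibers; metric-equivalence checks use 100 random 32² mask pairs; the
learning check trains the TEM variant width-reduced to base width 4 (the
full ledger widths 16–128 are used for the parameter checksum, which
needs no training) on 30 synthetic 512² patches of ~35 fibers each — the
tens-of-axons-per-patch density the working resolution was designed
around — and evaluates Dice on held-out synthetic images.

The published training settings are calibrated for a 200-epoch schedule
with thousands of optimizer steps; a desk-scale run has fewer than a
hundred. Training dynamics on this task show a sharp phase transition:
the majority background class and the blob-shaped axon class fit within
the first dozen steps, while the thin-annulus myelin class only crosses
the argmax boundary after roughly 60–90 Adam steps, almost independently
of batch size. The desk-scale learning check therefore runs at an
operating point adapted to its shortened schedule, with every knob an
exposed configuration value and the published values left as package
defaults: learning rate 0.01 (rate scaling for a ~30× shorter schedule),
batch 4 (twice the optimizer steps per epoch at equal compute), dropout
off (removing a quarter of a 4-channel trunk's features per step delays
the myelin transition past any desk-scale budget; dropout guards against
an overfitting that cannot occur in 14 epochs), and augmentation off
(image-only blur up to SD 4 erases 5–7-pixel myelin rings from the input
while their labels remain, which actively miscalibrates the minority
class at this scale). Fourteen epochs at this operating point reach axon
Dice ≈ 0.98 and myelin Dice ≈ 0.94 on held-out synthetic images in
minutes on one CPU.

# Numerical choices and degenerate inputs

* Batch-norm eps 1e-5; batch statistics use the biased variance.
* Softmax is computed with the per-pixel max subtracted; probabilities are
  floored at 1e-12 inside the loss only.
* Standardization variance floor 1e-8 (constant patch → all zeros).
* Argmax ties → lowest class index.
* Dice of two empty masks = 1; sensitivity/precision with empty
  denominators are 0 with `undefined_*` flags.
* Mirror padding uses reflection without edge repetition (period 2n−2),
  defined for any pad width.
* Dropout inside the fused BN–ReLU–dropout kernel uses a xorshift
  generator seeded once per call from R's RNG stream, so training remains
  reproducible under `set.seed()` at a fraction of the cost of
  per-element R RNG calls.
* All randomized entry points (`sample_population`, `render`,
  `split_train_val`, `build_network`, `generate_dataset`) take an
  explicit seed and restore the caller's RNG state; `augment` and
  `train_network` draw from the global stream (the training seed lives in
  `training_config`).

# Known limitations

* The momentum schedule's functional form and rate are a reconstruction
  of stated intent, not a published formula; endpoints and direction are
  honored, the path between them is a choice.
* The centroid-matching rule and the handling of merged axon objects are
  likewise underdetermined by the source; the containment rule used here
  is one defensible convention and is applied consistently in both the
  implementation and its brute-force test oracle.
* Training on one CPU is slow; the default full-width configuration is
  practical for the parameter checksum and for inference, but training
  experiments should use width-reduced configs as the tests do.
* Anisotropic pixel sizes, 16-bit normalization dialects and multi-channel
  stains are out of scope.
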