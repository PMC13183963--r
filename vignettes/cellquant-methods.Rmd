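---
title: "cellquant: models, synthetic data, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellquant: models, synthetic data, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

cellquant provides the three trainable models used in routine label-free
cell culture analytics — confluency segmentation, flow-field instance
counting, and live/dead viability classification — together with the
quantitative layer built on top of them (growth rate and doubling time,
four-parameter dose–response with IC50, sampling plans, chamber
concentration, and agreement metrics). Because no public dataset of
annotated brightfield culture and counting-chamber images accompanies
this problem, the package ships a seeded synthetic-image generator with
exact ground truth, and every model is trained and validated end to end
on it.

## The segmentation models

**Confluency.** The confluency model is a standard U-Net: four encoder
blocks of two 3×3 convolutions (64/128/256/512 filters at full scale),
each followed by 2×2 max pooling; a 1024-filter bottleneck; 0.5 dropout
after the deepest block and in the bottleneck; a decoder of 2×
upsampling, a 2×2 convolution (512→256→128→64), skip concatenation and
two 3×3 convolutions per level; and a final 3×3 convolution with two
filters (ReLU) followed by a 1×1 sigmoid convolution. The two-filter
penultimate layer is unusual but implemented verbatim. Training uses
Adam and binary cross-entropy. `base_scale` multiplies every filter
count (rounded up), which is how the desk-scale configurations below are
derived. The probability threshold for binarizing the sigmoid output is
0.5 and exposed on the model handle.

Images of any size are letterbox-resized: padded to square with the
median intensity (padding never enters the ROI), then resized to the
model input. Downscaling applies a Gaussian anti-aliasing prefilter with
sigma equal to half the scale factor. This matters for resolution
robustness: without a matched low-pass filter, the same field entering
at different native resolutions aliases differently and the predicted
coverage drifts by several percentage points; with it, inputs from
different resolutions collapse onto nearly the same model input.
Predicted masks are mapped back to native resolution with
nearest-neighbour resizing and coverage is computed inside the ROI as an
exact pixel ratio.

**Counting.** The count model predicts, per pixel, a cell probability
plus vertical and horizontal flow components pointing toward the owning
object's centre (a U-Net backbone with a 3-channel head; encoder
32/64/128/256 at full scale). Ground-truth flows are built by diffusing
heat from each object's median-centre pixel inside the object and
normalizing the spatial gradient of `log1p` of the diffused field.
Training minimizes binary cross-entropy on the probability map plus L2
on the flows (targets scaled ×5, the usual flow-regression
stabilization). At inference, pixels above the probability threshold are
advected 200 Euler steps along the bilinearly interpolated flow field;
converged positions are histogrammed, 3×3 local maxima seed instances,
seed regions grow over the landing histogram, and each pixel takes the
label of the cell its trajectory landed in (lowest label wins ties).
Instances are hole-filled, instances smaller than `min_object_px` (9) are
dropped, and a quality-control filter discards instances whose
re-derived flows disagree with the predicted flows by a mean squared
vector error above 0.9 — a level chosen from the observed error
distributions of correct instances (median ≈ 0.09, 95th percentile
≈ 0.29) so that genuine cells are essentially never discarded.

**Viability.** The live/dead classifier runs strictly after instance
segmentation. It is a small encoder–decoder: four 3×3 convolutions
(ReLU) with 2×2 max pooling after the first two, then three 2×2
transposed convolutions, then a 1×1 convolution with tanh producing a
single-channel map in [−1, 1]. As written, two poolings cannot be
inverted by three stride-2 transposed convolutions, so the third
transposed convolution has stride 1 (implemented as a size-preserving
2×2 convolution); the output is exactly input-sized. The training target
is +1 on dead-object pixels, −1 on live-object pixels, 0 elsewhere, with
an L2 loss against the tanh output — the natural encoding for a tanh
head. An object is called dead when the mean map value over its pixels
exceeds 0 (configurable). The same network, thresholds and API serve
both Trypan Blue and Erythrosin B renderings; one model is trained on
both dyes jointly.

**Size estimation.** Cell size is estimated in two passes. Pass 1
segments at a default diameter and computes a style vector — a globally
pooled summary of the network's features — from which a linear
regression predicts log-diameter. Pass 2 rescales the image by
(training diameter / predicted diameter), re-segments, maps masks back,
and reports the median object equivalent diameter `2*sqrt(area/pi)`.
The regression target is log-diameter because sizes are strictly
positive; a ridge penalty (1e-3) is applied whenever there are fewer
training pairs than style dimensions. The default pass-1 diameter is the
model's training diameter (the conventional default of 30 px encodes
the same convention for models trained on 30 px objects). The style
vector is taken from pass 1 only.

The default style pooling is *multiscale*: the per-channel mean and
standard deviation of every encoder and bottleneck activation map,
L2-normalized. Plain global average pooling of only the deepest features
(the classical 256-float style array, available as `pool = "deepest"`)
carries too little size information at desk scale — a linear probe on
deepest-only styles explains only about half the held-out variance in
log-diameter, while the multiscale pooling restores R² above 0.9. The
deepest-only array remains the faithful full-scale convention; the
multiscale default is the package's own choice, made once after that
probe comparison and documented here.

## The CNN engine

No deep-learning framework is available to this package's dependency
set, so it carries a compact CNN engine of its own: im2col+GEMM
convolution, 2×2 max pooling, nearest-neighbour upsampling and 2×2
transposed convolution in RcppArmadillo, with a static-graph executor,
manual reverse-mode gradients, He-normal initialization, dropout and
Adam in R. All randomness (weights, shuffling, dropout, augmentation)
flows through R's RNG, so training is bit-reproducible given a seed.
Analytic gradients match finite differences to six significant digits.
Training processes one image per step (batch size 1).

## The synthetic-data generator

The generator emulates two scene families with exact ground truth.

*Adherent fields* place irregular cells — ellipses with axis ratio
U(1, 1.8), boundary radius perturbed by Fourier modes 2–4 (amplitudes up
to 0.10), textured darker interior, bright 1–2 px halo — on a noisy
background (Gaussian σ = 0.02 plus a per-image illumination plane) until
pixel coverage reaches the target confluency; placement stops within
about ±2 percentage points of the target, except near saturation where
coverage ≥ 98% is accepted. *Chamber scenes* render etched grid lines at
the chamber pitch, near-round live cells (bright interior, dark
membrane), dye-filled dead cells (dark blue for Trypan Blue, red-pink
for Erythrosin B; stained scenes are RGB), reference beads (dark ring,
bright centre) and small dark high-eccentricity debris specks. Debris is
labelled in the instance map and object table but excluded from the
semantic ground truth and from counting targets. Pairwise object IoU is
capped at 30% by default so touching and partially overlapping cells are
exercised; `overlap_cap = 0` additionally enforces a guard gap so
connected components equal objects. Seeds are hierarchical — the scene
seed spawns one stream per object — so changing the object count never
reshuffles earlier objects, and identical specs render bit-identical
samples.

Mean interior intensity of dead versus live cells differs by at least
0.2 in stained scenes for both dyes, so viability is learnable by
construction. Defocus is modelled as Gaussian blur with explicit odd
kernel support; the training augmentation uses the kernel/sigma grid
(5/9/13/15 × 0–2) that brightfield defocus augmentation conventionally
spans.

What the generator does *not* emulate: physically accurate optics (no
phase-contrast transfer function, no depth-dependent PSF), uneven
chamber loading, cell clumps with fully hidden boundaries, fluorescence,
or time-lapse correlation. Passing the synthetic suite therefore shows
that the architectures, losses, post-processing and analytics are
correct and trainable — it does not certify performance on any real
microscope's images, which requires fine-tuning on annotated data from
that distribution (the human-in-the-loop scaffold in `run_cycle()` /
`check_stop()` is the intended route).

## Desk-scale study conditions

The reference models behind the published-scale system train at
1024×1024 with the full filter schedule on hundreds of annotated images.
This package's validation suite runs the same code at a reduced scale
chosen once for a single CPU:

* **Confluency**: 110 training + 20 validation fields at 64×64
  (1 µm/px, 14 µm cells ≈ 14 px — the proportion 10× brightfield images
  take after letterboxing into the full-scale input), `base_scale =
  1/16` (encoder 4/8/16/32), dropout 0.1, learning rate 1.5e-3, 32
  epochs. Augmentation: flips/rotations, the defocus grid, and
  resolution degradation (downscale to 25–100% and back) mirroring the
  resize pipeline. Resolution-robustness panels render the same fields
  at native microscope scale (256×256, 0.25 µm/px).
* **Count**: 80 cell scenes (64×64 at 2 µm/px, 3–18 objects, cell
  diameters 10–20 µm, 20% debris), 18 bead scenes (1 µm/px, 6–17 µm) and
  24 debris-only scenes; `base_scale = 1/4` (encoder 8/16/32/64),
  learning rate 2e-3, 14 epochs. Flip augmentation negates the matching
  flow component.
* **Viability**: 40 Trypan Blue + 40 Erythrosin B scenes (64×64, 6–16
  cells, dead fraction U(0.1, 0.9)), filters 8/16/32/32, learning rate
  2e-3, 8 epochs.
* **Density strata**: evaluation fields of 128×128 at 2 µm/px
  (0.0655 mm²); the <50 / 50–300 / >300 objects-per-mm² strata of a
  1×1 mm chamber square scale to 1–3 / 4–19 / 21–40 objects per field.
  Matching counts per *area* keeps the local crowding comparable to the
  chamber regime instead of compressing hundreds of objects into a tiny
  field.
* **Dilution series**: a 0.2 mm × 0.1 mm counting square (the small-
  square geometry used for dense samples) rendered at 2 µm/px, Poisson
  per-field counts, eight dilution steps spanning the 1e4–2.5e7
  cells/mL-equivalent range.

Training thresholds are unchanged from the full-scale goals: held-out
pixel F1 ≥ 0.90 for confluency, instance precision and recall ≥ 0.90 at
IoU 0.5 for counting, per-object viability accuracy ≥ 95%, end-to-end
viability within 5 percentage points, size R² ≥ 0.95, dilution
linearity R² ≥ 0.99.

## Numerical and statistical choices

* **Pixel/instance metrics** use exact integer confusion counts;
  precision and recall are defined as 0 (and flagged) on empty
  denominators. Instance matching is greedy one-to-one by descending
  IoU at a threshold of 0.5 — the matching criterion is not dictated by
  any published convention here, so it is exposed as a parameter.
* **Counting border rule**: objects crossing the top or left ROI edge
  count, bottom or right are excluded (standard chamber practice),
  applied to object pixel sets; the centroid decides for objects
  entirely inside.
* **Doubling time** is fitted by OLS of log counts on time over all
  timepoints, which reduces exactly to `gr = ln(Nt/N0)/t` for two
  points; `Td = ln 2 / gr`, reported infinite with a flag when growth
  is non-positive.
* **Dose–response** uses the GraphPad-style 4PL on log10 dose,
  `response = bottom + (top − bottom) / (1 + 10^((log10 d − log10
  IC50)·hill))`, so `hill > 0` means viability decreases with dose.
  Fitting is Levenberg–Marquardt with a data-driven start and a coarse
  multi-start fallback; the 95% CI of IC50 is asymptotic (t-based on
  log10 IC50 from the Jacobian). Zero doses are fitted at
  `min(nonzero dose)/10`. Monte-Carlo calibration at 5% response noise
  puts the CI's empirical coverage near its nominal level (~95%).
* **Sampling plans** bootstrap the SD of the n-field mean (2000
  resamples) and return the smallest n below the target SD; for i.i.d.
  fields this agrees with the SD/√n closed form within one field.
* **Growth noise** is mean-one lognormal, so log-linear regression
  recovers the growth rate without bias.

## Known limitations

* The CNN engine is single-threaded and batch-1; it is sized for the
  desk-scale configurations above, not for 1024×1024/1024-filter
  training.
* Resolution robustness of the scaled-down confluency model is weaker
  than the full-scale system's: with anti-aliased letterboxing the
  spread of predicted confluency across 80/50/20/8% rescales averages
  2-3 percentage points (worst case 5-7 on near-saturated fields),
  versus the <2 points reported at full scale.
* EXIF orientation metadata in JPEGs is not interpreted; images are
  used as decoded.
* The human-in-the-loop scaffold records provenance and enforces split
  integrity, but annotation consensus itself is a human process it does
  not model.
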