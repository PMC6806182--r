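---
title: "Thermal face analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal face analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter, what the synthetic generator does
and does not emulate, and the choices made where the design was genuinely
open. No empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` compute.

## The problem

Long-wave infrared (LWIR) video measures emitted heat, so a face appears
markedly warmer than an indoor background, the nostril region cools and
warms with each breath, and facial expressions move both the landmark
geometry and the thermal texture. Extracting any of these signals from a
freely moving subject requires an automatic chain: detect the face, fit
and track anatomical landmarks, warp the face into a canonical frontal
frame so fixed regions of interest stay anatomically registered, and only
then run the actual analysis. Each stage of `thermoface` is usable on its
own; the pipeline runtime composes them with per-frame failure isolation.

## Coordinate and calibration conventions

All pixel coordinates are continuous, 0-based, `x` = column, `y` = row,
origin at the top-left pixel *center*; landmark positions are floats and
are never rounded until rasterization (warping accuracy depends on this).
Boxes are half-open. Temperature calibration is a per-frame affine map
`T = gain * intensity + offset` carried as metadata and applied lazily:
all detection and fitting runs on raw intensities, because thermal-face
models are trained on grayscale and an affine map never changes the order
of intensities. Whether a given camera's grayscale is radiometric is a
device property the user must check; the calibration is flagged as an
assumption, not a fact about the data.

## Face detection

The detector is the standard HOG + linear SVM sliding window:

* HOG: 8-px cells, 2x2-cell blocks, 9 unsigned orientation bins, 64-px
  square window, L2-Hys normalization (clip 0.2). Orientation bins are
  centered at multiples of 20 degrees and votes are linearly interpolated
  between the two adjacent bins; gradients are centered differences with
  replicated borders, so a constant patch yields an exactly zero
  descriptor. Descriptor length is `((64/8 - 2 + 1)^2) * 4 * 9 = 1764`.
* Sliding stride equals the cell size (descriptors are reused from the
  cell grid), over an image pyramid with factor 1.2.
* Training: positives are face boxes resampled to the window; negatives
  start as random background windows; two hard-negative rounds append the
  current detector's false positives. The SVM is `e1071::svm` (linear
  kernel, cost 1), reduced to an explicit weight vector so detection is a
  dot product.
* The score threshold is not a free parameter of the user's data: it is
  calibrated on a held-out background split to a false-positive budget of
  at most one detection per ten background frames.

None of the window size, pyramid factor or threshold are dictated by the
problem; they are the de-facto standard values and all are exposed in
`hog_spec()` / `train_detector()`.

## The shape model ("PCA layer")

Sixty-eight landmarks with fixed semantics (0–16 jaw, 17–26 brows, 27–35
nose, 36–47 eyes, 48–67 mouth, 0-based) are aligned by generalized
Procrustes analysis: iterated closed-form similarity alignment to the
evolving mean (complex cross-covariance rotation, reflections excluded),
the mean re-normalized to unit centroid size each round, until it moves
less than 1e-7 (at most 100 iterations). Shapes are normalized to unit
centroid size in model space so the eigenvalues are pose-free. Tangent-
space projection is omitted: at the pose ranges involved its effect is
far below the fitting error, and plain similarity normalization keeps the
procedure transparent.

PCA of the aligned coordinates gives `x = x̄ + P b`. The retained count
`k` is the smallest reaching 98% variance by default (90% for the fast
AAM), both exposed. Decoding clamps every coefficient to ±3√λᵢ — the
standard plausibility constraint — so *any* parameter vector decodes to a
face-like configuration; encoding does not clamp, so round trips on the
span are exact. This is the property the shape-constrained regressor
exploits.

## Landmark fitters

**Active appearance models.** Appearance lives in the mean-shape reference
frame; training images are warped into it with the same piecewise-affine
machinery used for frontalization, and a PCA appearance basis is built per
pyramid level. Two presets mirror the precision/speed trade-off:

* `high_quality`: reference diagonal 150 px, 3 pyramid levels, 36-channel
  dense gradient-orientation features (9 unsigned orientation maps,
  box-pooled, sampled at 4 spatial offsets of ±3 px, L2-normalized per
  pixel — the channel *count* is the committed design, not any particular
  descriptor implementation), joint shape+appearance updates.
* `fast`: diagonal 70 px, 2 levels, raw intensity features (normalized to
  zero mean / unit deviation per sample), appearance projected out,
  reduced component budget (90% variance). It is deliberately the
  low-precision end of the family.

Fitting is Gauss–Newton in the reference frame with forward-additive
parameter updates: the image (or its feature channels) is sampled through
the current warp, the Jacobian combines the sampled channel gradients with
the analytic warp derivative (barycentric transfer of the per-vertex pose
and shape-basis derivatives), and the appearance block of the joint normal
equations is eliminated by a Schur complement (the appearance basis is
orthonormal, which makes the simultaneous and project-out updates two uses
of one formula). The classic formulation of these two variants composes
inverse-compositional warp increments instead; the forward-additive update
was chosen because it needs no warp-composition approximation and behaves
identically at these pose ranges, while preserving exactly the contrast
under study: joint appearance optimization versus projected-out
appearance. Steps are accepted only if the appearance-optimal residual
does not increase (backtracking halves the step up to five times), so the
cost trace is non-increasing by construction; iteration stops when the
update norm falls below 1e-4 or after 50 iterations per level.

Fitting failure is declared by cost: the threshold is calibrated at
training time as twice the 99th percentile of final costs over correct
fits of training frames.

**Shape-constrained cascaded regressor.** The deep shape-regression
architecture this stands for couples a learned image-to-parameter map with
an explicit PCA decoding layer; the property under test is the layer, not
the network. Here the learned map is multi-cell HOG features of the
(square, 1.15x padded) face crop resized to 96 px, ridge-regressed
(lambda = 5) onto pose + shape coefficients, in a 4-stage cascade where
each stage re-crops around the previous prediction. Training jitters boxes
(8 per frame) by up to 10% in position and scale so detector noise is
in-distribution; the crop resolution and ridge strength were selected for
low pose-correlated bias of the nostril landmarks, the property the
ROI-stability analysis leans on. Every prediction
decodes through the clamped PCA layer, so the output is always inside the
±3σ plausibility region — including on pure-noise input. Its confidence
proxy is the disagreement between the last two cascade stages normalized
by the predicted inter-ocular distance: stable (small) on faces, unstable
(large) on background.

**Error metric.** Landmark error is RMSE over the 68 point distances
divided by the ground-truth inter-ocular distance (outer eye corners,
landmarks 36/45). Inter-ocular normalization is one of several
conventions; it is fixed here and stated wherever numbers are reported.

## Tracking

Frame 0 is initialized from the best detection; later frames follow one of
four update strategies: `bounds_update` (tight landmark box),
`shape_update` (the shape itself warm-starts the fitter), `dynamic_box`
(detector-style face box recentered and rescaled every frame) and
`fixed_box` (size frozen at frame 0, center following the face). If the
fit cost crosses the failure threshold the detector is rerun on that frame
(`redetect_on_failure`, default on — the conservative choice for an
automated pipeline).

## Frontalization and ROIs

The canonical frame scales the model mean shape to fill 80% of a 256-px
square by default (the respiratory analyses in the tests and acceptance
script use a 128-px frame: ROI *averages* are insensitive to canonical
resolution, and the smaller frame warps four times fewer pixels). The
Delaunay triangulation is computed once on the reference shape and shared
by every frame: re-triangulating per frame could flip triangles between
frames and destroy temporal consistency. Warping is backward (canonical →
source) with bilinear interpolation, so the output has no holes; each
canonical pixel's triangle membership and barycentric coordinates are
precomputed once, making the per-frame warp a sparse linear map plus one
interpolation pass. Landmarks map exactly onto their reference points
(barycentric transfer is exact at vertices), and warping with the
reference shape itself is the identity on the pixel grid.

Self-occluded regions are *not* inpainted: they warp into the canonical
frame like everything else, and the validity mask plus each ROI's
`valid_fraction` are the downstream contract (samples under 50% validity
are flagged and linearly interpolated in the respiratory signal, keeping
the series uniformly sampled for spectral analysis while preserving the
flags).

The nostril ROI is landmark-anchored: the hull of nose-base landmarks
31–35 dilated by 4% of the reference inter-ocular distance. No standard
nostril-ROI geometry exists; this anchoring is an interpretation, and
every ROI is user-overridable by explicit polygon or by anchor indices
plus dilation.

## Analysis heads

**Respiration.** The per-frame nostril-ROI mean is the respiratory signal.
Rate estimation (linear detrend, Hann window, 4x zero-padded periodogram,
peak within 0.1–1.0 Hz, refused when the peak is below 3x the median band
power) and apnoea detection (10-s sliding windows at 1-s stride; windows
below 0.25x the global standard deviation merge into segments; segments
under 5 s are discarded) are *extensions*: the motivating line of work
extracted and plotted the signal and read the pauses visually, and
deliberately stopped short of quantitative rate estimation. Both
estimators are deterministic and refuse rather than guess (flat signal →
`NA`; no flat windows → empty segment list).

**Emotion.** The face is cropped to the landmark bounding box plus a 10%
margin (zero-padded at frame borders so the crop size depends only on the
landmarks), resized to 128 px, described by HOG (8100 features) and
classified by a seeded 1000-tree probability forest (`ranger`). The crop
is taken in *frame* coordinates, not from the frontalized face — the
margin-expanded landmark crop is the flow the feature extractor expects —
and HOG's block normalization makes the prediction invariant to affine
intensity changes. Class order is fixed (neutral, happy, sad, surprised);
argmax ties break toward the earlier class.

## The synthetic generator

The generator is the package's stand-in for a proprietary annotated
thermal-face corpus, and it is first-class, tested code. It emulates the
*statistical structure* that the pipeline depends on:

* a face 5+ noise-deviations warmer than the background (face level 3500
  vs ambient 1500 intensity units with noise σ = 20 by default — a 100σ
  contrast, comfortably past the salience floor);
* 68 semantically indexed landmarks with identity variation as a smooth
  displacement field bounded by 3% of the inter-ocular distance per point;
* thermal texture as anisotropic Gaussian kernels *anchored on the
  landmarks* (warm periorbital and inner-canthus regions, a warm nostril
  band, cooler nose tip, brows and hairline), so expression changes move
  geometry and texture together and the breathing modulation rides on the
  nostril landmarks;
* emotion-dependent deformation at 12% of the inter-ocular distance
  (above the 10% separability floor);
* rigid head motion: none, bounded sinusoidal ("slow": ≤10% translation,
  ≤10° rotation), or a smooth seeded random walk ("complex": ≤25°
  rotation, shear ≤0.28, out-of-plane rotation approximated by horizontal
  shear plus foreshortening rather than a 3-D head model — enough to
  exercise the frontalization failure modes at a fraction of the
  complexity);
* breathing as `A sin(2π f t)` on the nostril band, frozen inside
  programmed apnoea windows.

Defaults are chosen once as study conditions: 8 Hz frame rate (typical of
low-cost LWIR cores and ample for the sub-1-Hz respiratory band),
breathing amplitude 300 intensity units (15% of the face contrast),
160-px frames with faces at 23–33% of the frame, training-pose ranges
(rotation ±0.45 rad, shear ±0.28) covering the motion envelope the tracker
must handle — a training corpus narrower than its deployment poses would
be a design error, not a harder benchmark. Everything derives from a
single integer seed; equal seeds give bit-identical output.

What the generator does **not** emulate: photometric realism,
fixed-pattern or row noise, emissivity and reflection artifacts, glasses
(which are opaque in LWIR), hair occlusion, 3-D self-occlusion beyond the
shear surrogate, or inter-subject texture variability beyond
landmark-driven changes. Passing tests therefore demonstrate that the
*algorithms* are implemented correctly and interact correctly — detector
recall, fitter ordering, warp exactness, signal recovery — not that any
particular accuracy will transfer to a given camera and population.
Real-data performance must be validated per deployment.

## Pipeline runtime

Stages resolve through a registry (detector / landmarker / frontalizer /
analyzer / sink) and run as an ordered in-process chain; a distributed
message transport adds operational surface without changing the testable
contract, which is isolation and swappability. A stage exception on one
frame marks that stage failed, skips its downstream stages for that frame
only, and never aborts the run; one structured log record is emitted per
stage per frame. The default landmarker stage is initialized from the
current frame's detection, which makes per-frame results independent —
a fault injected on one frame leaves every other frame bit-identical,
the strongest isolation property a stateful tracker cannot offer. Setting
`track = TRUE` in the landmarker config switches it to the stateful
update strategies of `track_video()`, trading that independence for
temporal coherence; after a failed frame it reinitializes from the
detector.

## Problem sizes and numerical choices

The test suite and acceptance script train on 200 synthetic faces + 100
backgrounds (detector, regressor), 60 faces (AAMs), and 400+120 faces
(emotion), and evaluate on held-out sets of 20–50 faces and 20 tracked
sequences of 65–83 s at 8 Hz — sizes at which every quantity under test
(recall, median NRMSE, rate error) is stable across seeds while the whole
suite stays desk-scale. Numerical details fixed throughout: bilinear
interpolation clamps at image borders (no zero-fill bleeding into
gradients); Delaunay triangles are ordered by sorted vertex indices and
pixel-membership ties at shared edges resolve to the first triangle in
that order; HOG normalization uses ε = 1e-6; ridge regression uses λ = 5;
Gauss–Newton adds 1e-8 to the normal-equation diagonal; all stochastic
steps (negative sampling, jitter, forest growth) consume an explicit seed
and restore the caller's RNG state.

## Known limitations

* The fast AAM is honest about being imprecise; on difficult real data it
  is expected to be unusable, which is the documented trade-off.
* The emotion classes are geometric prototypes; real expression
  recognition contends with far subtler and person-dependent signals.
* Rate estimation assumes quasi-stationary breathing within the analysis
  window; strongly varying rates need a short-time variant.
* The affine temperature calibration ignores emissivity and atmospheric
  correction (out of scope by design).
* Single-face processing: the tracker follows the best detection only.
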