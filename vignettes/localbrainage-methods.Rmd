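---
title: "Local brain-age: model, bias adjustment and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local brain-age: model, bias adjustment and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Global brain-age models reduce a structural MRI to one number: the age a
healthy-trained model predicts for the scan. The difference between
predicted and chronological age (brain-PAD) is a widely used marker of
apparent brain ageing, but a single value per brain cannot say *where* a
brain looks old. This package implements a local formulation: a fully
convolutional regression network predicts age at every voxel of
grey-/white-matter volume maps, and all downstream statistics (bias
adjustment, reliability, group comparison) operate on the resulting maps.

# The model

## Architecture

`unetSpec()` describes a three-scale encoder–decoder ("U") network:

* input: two channels (GM, WM) over a 52³-voxel block;
* two valid (no-padding) 3×3×3 convolutions per scale, stride 1, channel
  width 64 at the first scale and doubling with each downsampling;
* 2×2×2 average pooling between encoder scales, nearest-repeat ×2
  upsampling between decoder scales, with centre-cropped skip connections;
* each convolution is followed by a leaky rectifier (negative slope 0.2)
  and a squeeze-and-excite (SE) gate — global average pooling over the
  block, a two-layer bottleneck (reduction ratio 16, floored at one
  channel), and a sigmoid channel reweighting. SE internals are not fully
  pinned down by the architecture's public description; we apply the gate
  after the activation and initialise its output bias at 2 so gates start
  near identity (sigmoid(2) ≈ 0.88) — ten stacked blocks would otherwise
  attenuate the forward signal by 0.5¹⁰ at initialisation;
* output: a 1³ convolution to one channel — a 12³ block of voxelwise
  predicted age — plus two auxiliary heads (global average pooling + one
  dense unit) at the bottleneck and mid-decoder scales predicting
  block-level age.

Because every convolution is valid, the spatial contract 52³ → 12³ holds
for any weights; `forwardNetwork()` checks it structurally and the test
suite checks it empirically. Weights are initialised with fan-in-scaled
Gaussians under a fixed seed.

## Loss

`compositeLoss()` sums absolute voxel errors over the 12³ output block
(the target block is filled with the participant's chronological age) and
adds the two auxiliary absolute errors weighted by α₁, α₂. The auxiliary
weights decay linearly from 1 at iteration 0 to 0 at 50,000 iterations
(`lossConfig(decay_iterations = )`), after which gradients flow only from
the voxel-level term. The decay form is a design choice: the auxiliary
losses are a stabiliser, and a linear ramp is the simplest schedule with
the required endpoints.

## Effective resolution (receptive field)

`measureReceptiveField()` reports the effective local resolution of the
voxel predictions using per-layer field-of-view accounting: for each layer
along the encoder–decoder path it measures, by finite perturbation with
non-negative (absolute-valued, offset) weights, the sensitivity support of
one output voxel on that layer's own grid, and sums the per-layer growths.
A 3³ convolution contributes +2 voxels per axis, a 2³ average pooling +1,
repeat upsampling 0; the full architecture totals 23 voxels per side. SE
gates are channel reweightings, not spatial mixings, and are held fixed
during the measurement.

Two caveats are deliberate and documented rather than hidden. First, this
accounting composes the per-layer fields additively on each layer's native
grid — the convention of treating pooling as unit-stride. The bounding box
of input voxels with *any* nonzero end-to-end influence is wider (44
voxels for this network), because stride-2 pooling dilates deeper layers'
fields in input coordinates. We report the additive accounting as the
effective resolution because it is the scale on which the deep layers
actually integrate information, and note the alternative here. Second,
the within-block homogeneity of predictions means single-voxel outputs
should be read at this coarser effective scale.

## Translation covariance

The network's total downsampling stride is 4, so predictions are covariant
to input shifts by multiples of 4 voxels: outputs of two windows offset by
4 agree exactly on their shared voxels. A 12-voxel shift (the block
stride) is also a multiple of 4, which is what makes block-wise prediction
and whole-volume prediction consistent; since the output block is only 12
wide, the covariance is *tested* at shift 4, where compared windows share
output voxels. The covariance is exact for the convolutional geometry
alone; the squeeze-and-excite gates average over the whole window and so
couple every voxel weakly, breaking exactness at the 0.1% level — the
test holds the gates constant, and this global coupling is another reason
block-wise and whole-volume prediction agree only approximately.

# Whole-brain prediction

`planBlocks()` tiles the brain mask with 12³ output regions on a
stride-12 lattice anchored at the mask bounding box; input windows extend
20 voxels beyond their output region on every side and are zero-padded
past the volume (preprocessed tissue maps are zero outside the head, so
zero padding is distribution-consistent). Lattice origins overshooting the
far volume edge are clipped back, and `stitchBlocks()` averages the
overlapping predictions this creates; blocks whose output region contains
no in-mask voxel are dropped as carrying no discriminative tissue. The
inter-block stride and the overlap rule are our choices — the source
architecture specifies overlapping input blocks but not how neighbouring
output blocks meet.

`predictMap()` offers two routes: the reference block-wise route
(extract → forward → stitch), and `method = "whole"`, which exploits full
convolutionality to predict the entire volume in one forward pass over the
margin-padded volume. The two agree up to the pooling-phase alignment of
individual blocks; the pipeline uses the whole-volume route because it is
an order of magnitude faster.

# Training

`trainConfig()` defaults mirror the reference optimisation: Adam,
learning rate 1e-4, minibatch 32 processed as four gradient-accumulation
splits, an 80/20 participant-level split, and a validation plateau rule
(no improvement in validation voxel-MAE beyond a tolerance for a given
number of evaluations) formalising what was originally a visual stopping
criterion. Evaluation frequency and tolerance are configurable because no
published values exist.

## Standardisation

`standardize = "voxel"` (the default) z-scores every voxel against its
mean and SD across the training cohort — a cohort template — and predicts
age through an affine output head (`age_mean + age_sd · raw`). The
constants are stored in the network spec and travel with the checkpoint,
so prediction applies them automatically. The rationale is conditioning:
in raw tissue maps the anatomical mean dwarfs the age-related contrast by
more than an order of magnitude, and with an absolute-error loss (whose
per-voxel gradients are ±1) the distance the optimiser must move the
output head scales with that ratio. A reference-scale run (hundreds of
thousands of iterations) can afford to learn the anatomy first; a
desk-scale run cannot. Per-voxel standardisation removes the anatomical
mean so the entire training budget is spent on the age signal. Scalar
channelwise z-scoring (`"global"`) and no standardisation (`"none"`) are
available for comparison.

# Bias adjustment

Subtracting chronological from predicted age leaves an age-dependent bias
(regression dilution): the young are over- and the old under-predicted in
proportion to model error. The global method fits Δ = α·age + β on a
calibration cohort and subtracts the fitted line (fitting on predicted age
instead is also supported); we read the adjustment as Δ − (α·age + β),
the only sign convention that zeroes a linear bias. The voxel-level
method bins calibration participants by age — [18,25), then 5-year bins,
the last bin closed — and subtracts each bin's mean voxelwise delta. By
construction the per-(bin, voxel) mean of adjusted deltas over the
calibration set is exactly zero; the test suite asserts this identity at
machine precision. Ages outside the calibrated range are clamped to the
nearest occupied bin (refusing would break clinical cohorts older than
the healthy calibration range); clamping can be disabled, in which case
an uncalibrated bin is an error.

# Statistics

Group comparisons use Welch's unequal-variance *t* with
Welch–Satterthwaite degrees of freedom and two-sided p-values, Bonferroni
correction over the number of tests actually performed at the given scope
(user-overridable), and Cohen's *d*. For *d* we use the pooled *standard
deviation*; a printed formulation that pools raw variances without a root
is dimensionally inconsistent with a standardised effect size. Voxel-scope
comparisons pool voxelwise deltas across participants into one population
per group — reproducing the published procedure; we note that treating
voxels as independent observations inflates degrees of freedom, and we
reproduce the procedure without endorsing that exchangeability assumption.
Reliability uses ICC(2,1) — two-way random effects, absolute agreement,
single measure — vectorised over voxels in `iccMap()`, plus the classical
two-measurement formula (`icc(x, "fisher")`) for reference.

# The phantom generator

The synthetic cohorts stand in for preprocessed real MRI and define the
package's study conditions:

* geometry: a superellipsoid brain mask (exponent 4, semi-axes 0.42 of
  the grid); the white-matter channel occupies a scaled-down core and the
  grey-matter channel the surrounding shell — disjoint supports as a crude
  cortex/white-matter analogue;
* intensity model: `I(v) = base(v) − β(v)·(age−18) − β(v)·δ_g(v) + ε`,
  smoothed with a Gaussian kernel (FWHM 2.7 voxels, emulating 4 mm
  smoothing at 1.5 mm voxels) applied after noise. The stored truth fields
  are the smoothed, masked fields, so at zero noise ordinary least squares
  recovers them exactly — a property the tests assert;
* atrophy rate β(v): a linear anterior–posterior gradient, zero in the
  posterior 30% (the control region), peak 0.004 intensity-units/year
  (≈ 29% lifetime decline against a baseline of 1.0), capped so intensity
  stays positive over the full age span. This gives regions where age is
  and is not locally decodable;
* noise: Gaussian, SD 0.05 before smoothing (smoothing leaves ≈ 0.006
  per-voxel noise, i.e. a high-SNR but not noise-free regime);
* ages uniform on [18, 90]; group effects add β(v)·δ years-equivalent
  atrophy inside configured atlas ROIs only; the atlas is a 3×3×3 block
  partition of the mask;
* repeat scans share the age signal and differ by fresh within-scanner
  noise; between-scanner repeats are additionally modulated by a smooth
  multiplicative site field shared across participants.

What the phantoms do *not* emulate: real anatomy, registration error,
site/sequence covariance structure, age-nonlinear atrophy, or
disease-specific spatial patterns beyond a uniform ROI offset.
Consequently, passing the packaged end-to-end checks demonstrates that the
implementation is correct and that the method behaves as designed under
its own assumptions — not that it attains any particular accuracy on real
cohorts.

# Desk-scale study configuration

`deskConfig()` fixes the packaged end-to-end experiment: grid 48³, 100
healthy training participants (80/20 split), 30 held-out healthy test
phantoms, 60 calibration phantoms (the reference design used 200; 60
keeps every 5-year bin populated in expectation at this cohort size), 20
clinical phantoms aged 60–90 with +5 years-equivalent atrophy in the ROI
with the strongest atrophy gradient, healthy controls age-matched at
>60 years, 6 reliability participants scanned twice within- and twice
between-scanner (site-field amplitude 0.03). The network keeps the full
layer structure — so the 52³→12³ contract and the 23³ receptive field
remain testable at full width — but uses base width 2: the phantom task is
nearly linear and width mainly costs time. Training runs 200 iterations at
learning rate 1e-3 with minibatch 4 in four accumulation splits; the rate
is scaled up from the reference 1e-4 because a 200-iteration schedule
cannot otherwise move an MAE-trained output by tens of years. Problem
sizes were chosen so the full study runs in minutes on one CPU core.

# Numerical choices and degenerate inputs

* Out-of-mask voxels in every output map carry NA, never 0 — zero is a
  legal brain-PAD value.
* Voxel SDs in the per-voxel standardisation are floored at 10% of the
  median positive SD so flat voxels cannot produce unbounded z-values.
* Welch's t with both group variances zero, ICC with zero total variance,
  Cohen's d with zero pooled SD, and regression on a zero-variance
  covariate are explicit errors, not NaNs.
* Empty masks, shape/affine mismatches and unmatched participant ids fail
  fast with the offending file or id named.
* Determinism: all randomness flows through R's RNG under configurable
  seeds; a fixed seed reproduces cohorts, splits, training trajectories
  and maps exactly (single-threaded BLAS assumed).

# Known limitations

* The auxiliary-weight schedule and SE placement are choices where the
  source description is silent; both are documented above.
* At desk scale the auxiliary heads contribute little: their gradient is
  one term against 1728 voxel terms per sample. They matter at reference
  scale, and the α = 0 reduction is tested.
* The pooled-voxel group test inherits the independence caveat above.
* Whole-volume prediction differs from block-stitched prediction by
  pooling-phase alignment at clipped lattice origins; both routes are
  exposed.
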