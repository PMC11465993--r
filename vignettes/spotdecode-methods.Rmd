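---
title: "Counting and localizing emitters inside the diffraction limit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and localizing emitters inside the diffraction limit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In single-molecule localization microscopy (SMLM/STORM), two fluorophores
separated by less than the diffraction limit — about
$d = \lambda / (2\,\mathrm{NA}) \approx 240$ nm for AF647 emission at NA 1.4 —
produce a single apparent emission spot. Such sub-diffraction-limited spots
are morphologically almost indistinguishable from single-emitter spots: their
fitted sizes and ellipticities overlap heavily, especially at small
separations. Conventional localization treats every spot as one molecule,
which under-counts events and misplaces emitters in dense structures.

`spotdecode` addresses this with a two-stage model:

1. a **classification network** predicts the number of emitters $I$
   (1–4; 1–2 by default) behind each 15×15-pixel spot crop;
2. a count-specific **localization network** regresses the $2I$ emitter
   coordinates in nm.

Because each localizer has a fixed output dimension $2I$, the ill-posedness
of detecting highly overlapping targets is avoided: the classifier picks the
head, the head emits exactly the right number of coordinates.

## Training data by superposition

The key to supervised training is that multi-emitter spots with exact
ground-truth positions can be *derived* from single-emitter spots. Each
single-emitter 7×7 crop carries a Gaussian-fitted emitter position (the
fitted center of the pixel-integrated 2D Gaussian
$I(x,y) = I_0\exp\!\big(-\tfrac{(x-x_0)^2+(y-y_0)^2}{2\sigma^2}\big)$).
To make an $I$-emitter spot, $I$ library spots are translated so their
fitted positions land on target coordinates drawn inside a 240 nm-diameter
disk on a 1 nm grid, then summed pixel-wise. Every pairwise distance inside
that disk is automatically sub-diffraction. The target coordinates become
the regression label; $I$ becomes the classification label.

**Sub-pixel translation.** A spot with $\sigma \approx 102$ nm sampled at
160 nm/pixel is not band-limited, so pure Fourier (sinc) interpolation errs
by up to ~6% of peak at half-pixel shifts and bilinear interpolation by far
more. The default translation therefore re-renders the record's *fitted*
pixel-integrated Gaussian at the shifted position and Fourier-shifts only
the fit residual (noise plus any non-Gaussian structure). For an exactly
Gaussian spot this is exact; for real spots the residual — which is small —
is the only interpolated part. Pure `"fourier"` and `"bilinear"` modes
remain available via `merge_spots(shift_method = )`.

**Canvas placement.** Merged spots are rendered on a 15×15 canvas with the
centroid of the emitter configuration placed at the canvas center plus a
uniform ±0.5 px jitter. The jitter prevents the centroid from being a
trivial cue, mirroring inference where crops are centered on a noisy
Gaussian-fit center. At inference, 11×11 crops (5 px around the fitted
center) are zero-padded to 15×15 — networks see the same geometry either
way.

**Label ordering.** The plain MSE loss is order-sensitive, so emitters are
canonically sorted by $x$ then $y$. A permutation-invariant variant
(minimum over emitter orderings) is available via
`train_config(loss_variant = "permutation_min")`; the canonical ordering is
the default because it matches the plain MSE formulation.

**Split hygiene.** Train and test splits use disjoint library molecules, so
no experimental (or synthetic) source spot is shared across splits.

## The synthetic spot generator

No deposited experimental library exists, so the package generates one that
emulates its statistics:

* **PSF**: pixel-integrated isotropic Gaussian, $\sigma = 102$ nm
  (FWHM ≈ 240 nm at 160 nm pixels). Integration over each pixel uses exact
  error-function differences, not center sampling, so flux is conserved and
  the quadrature oracle in the test suite is meaningful.
* **Photon yield**: truncated lognormal, median 5000 photons, geometric SD
  1.8, truncated to [500, 50000] — a broad, right-skewed distribution of
  the kind AF647 shows under STORM buffers. The exact experimental
  parameters are unpublished; these are package defaults, declared in the
  configuration and easy to override.
* **Camera**: Poisson shot noise on signal plus a 10 photon/px background,
  1 e⁻ RMS Gaussian read noise, unity gain, 160 nm pixels.
* **Blinking**: a two-state Markov chain per molecule (off→on probability
  1e-3 per frame, mean on-time 2 frames), started from its stationary
  distribution. Photon counts are drawn per on-frame.
* **Placement**: library emitters are uniform within the central pixel of
  their 7×7 crop, mimicking detection-centered experimental crops.

What this generator does *not* emulate: PSF width variability across the
field (defocus, aberrations), non-Gaussian PSF tails, EMCCD excess noise,
fluorophore photophysics beyond two states, and drift. Consequently,
passing the desk-scale checks demonstrates that the pipeline recovers what
it was trained on under realistic noise — it does not certify performance
on any particular microscope's data, for which a real library should be
substituted (the dataset builder accepts any fitted `spot_library`).

One measurable consequence: with a fixed-width PSF, a pair at separation
$d$ inflates the fitted spot variance by about $d^2/4$, so two-emitter
*relative areas* (the $2\sigma_x \times 2\sigma_y$ statistic) run ~15–20%
larger than singles on average, while experimental libraries mask this
shift under natural width spread. Close pairs (< 60 nm) remain
indistinguishable from singles here too, which is the regime that matters
for the classifier's difficulty.

## Networks and training

The reference backbone for this method is ResNet-50 trained for 400 epochs
(Adam, batch 64, L2 penalty 0.01, learning rate cosine-annealed from 1e-5
to 1e-8) on 280k images. That recipe is preserved as the
`"paper_scale"` profile of `train_config()`, but it is not a desk-scale
computation. The default `"desk"` profile uses a **compact backbone**
implemented in C++ (RcppArmadillo): two skip-connected 3×3 convolution
blocks (1→C→C, max-pool, C→2C→2C with C = 8), a 48-unit fully-connected
layer, and the task head — softmax over counts, or a linear layer emitting
$2I$ coordinates relative to the crop center in nm. Skip connections keep
low-frequency image content flowing past the conv blocks, the property that
motivates residual backbones here. Desk defaults: 20k training spots, 30
epochs (45 for the two-emitter localizer, whose regression objective
converges more slowly), Adam with cosine annealing from 1e-3 to 1e-5,
weight decay 0.01, batch 64. Training is single-threaded and deterministic
given `set.seed()`: all weight initialization and batch shuffling draw from
R's RNG.

Inputs are divided by a fixed global constant (5000, the photon median)
rather than per-image maxima, because absolute brightness is a physical cue
— a two-emitter spot is on average twice as bright as a single — and
per-image normalization would discard it.

Losses are the standard ones: non-negative cross-entropy for
classification and the per-spot mean-square error
$L = \tfrac{1}{2I}\sum_i \big[(x_i-\bar x_i)^2 + (y_i-\bar y_i)^2\big]$
for localization (nm²).

## Evaluation

* **Counting**: confusion matrix with the two-emitter class as positive;
  recall $\mathrm{TP}/(\mathrm{TP+FN})$, precision
  $\mathrm{TP}/(\mathrm{TP+FP})$, accuracy
  $(\mathrm{TP+TN})/\mathrm{total}$. Undefined ratios are reported as
  `NaN`, never silently zero.
* **Localization**: per-spot RMS
  $\sqrt{\sum_i [(x_i-\bar x_i)^2 + (y_i-\bar y_i)^2] / (2I)}$ after
  minimum-cost matching of predictions to truths (exact bitmask dynamic
  program on squared distances; any other pairing inflates the error
  artifactually). Spots whose predicted count disagrees with the truth are
  excluded from RMS and reported separately. Errors are binned by true pair
  separation (0–60, 60–120, 120–180, 180–240 nm). The *midpoint baseline* —
  predicting both emitters of a pair at their midpoint, RMS $= d/(2\sqrt2)$
  — is the lower bar any two-emitter localizer must beat at resolvable
  separations; at $d = 30$ nm it equals 10.6 nm, which bounds what any
  method can be expected to report there.
* **Reconstruction comparison**: localizations are rendered as unit spikes
  on an 8× upsampled canvas, convolved with a Gaussian kernel (σ = 1
  high-resolution pixel), and compared by SSIM (uniform 7×7 window,
  unbiased covariance, standard stabilization constants; verified to 1e-6
  against scikit-image's implementation). The kernel width used by
  spike-based reconstruction tools is not standardized; both σ and the
  upsampling factor are configurable.

## STORM simulation of dense ultrastructures

`ultrastructure_spec()` describes a 240 nm disk holding 50–550 molecules
with a centrally peaked radial Gaussian density (σ = diameter/4,
rejection-sampled inside the disk — the reference figures show a
center-dense profile but do not parameterize it). `simulate_sequence()`
gives every molecule an independent blink trace, renders co-active
molecules per frame with camera noise, and keeps exact ground truth:
per-frame active molecules are grouped into apparent spots by
single-linkage clustering at 240 nm, so every spot decomposes into its
contributing molecules. The single-Gaussian-fit baseline treats each spot
as one molecule, so its event count is at most the true count, with
equality only when no co-activations occur — at high density the two-stage
pipeline recovers visibly more of the structure, which the SSIM-vs-density
curve quantifies.

## Numerical choices and degenerate inputs

* Gaussian fits use Levenberg–Marquardt (`minpack.lm`) with an analytic
  Jacobian, centroid/1-px initialization, and box bounds keeping the center
  inside the crop; flat or non-positive crops raise a fit error rather than
  returning garbage.
* Detection band-pass is a difference of Gaussians (σ 1 px / 3 px) with
  zero padding, applied *only* to find maxima — the pixels handed to
  fitting and to the networks are always raw, preserving photon statistics.
  (Whether the reference networks consumed filtered or raw crops is
  ambiguous in the source; raw is the default here, filtering is a
  detection-only concern.)
* Class-probability ties at inference break toward the lower emitter count
  (the conservative choice); detections within 2 px merge into one crop.
* Seeds: every stochastic entry point takes an explicit seed; a global seed
  fans out to per-module seeds by fixed offsets.

## Problem sizes used by the checks

The shipped acceptance computations regenerate everything from scratch at
desk scale: a 4000-molecule library, 20k labeled spots (10k per class, 10%
held out), 30-epoch classifier and 45-epoch two-emitter localizer on one
CPU, a 6.5k-spot held-out evaluation set for the sub-60 nm bin, 1.2k
constrained pairs at 30 ± 2 nm, and a 10k-spot independently seeded batch
with the photon median shifted +10% for the generalization check. These
sizes were chosen as the smallest at which the quantities of interest are
stable to re-seeding; the `"paper_scale"` profile documents the full
reference recipe.

## Known limitations

* 2D only; no astigmatic/3D PSFs, no drift correction.
* Emitter counts cap at 4 (and the default study uses 1–2); spots spanning
  more than one diffraction-limited region are out of scope.
* The compact backbone is sized for 15×15 crops; larger fields are handled
  by detection + cropping, not by a fully convolutional pass.
* Synthetic-twin caveats above: results on real data depend on building a
  library from that data.
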