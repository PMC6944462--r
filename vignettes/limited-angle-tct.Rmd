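---
title: "Limited-angle translational CT: geometry, SART, and U-net post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Limited-angle translational CT: geometry, SART, and U-net post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tctrecon)
```

## The problem

Translational CT (TCT) replaces the slip-ring gantry of a conventional
scanner with two opposed linear stages: the X-ray source translates along
one line while a flat-panel detector translates in the opposite direction
on the other side of the object. One translation sweeps a 30° wedge of view
angles; the pair is then manually rotated by 30° and the translation is
repeated. When the total coverage stays below the classical sufficiency
range (180° plus the fan angle) — e.g. the three standard arms [0°, 90°],
[0°, 120°] and [0°, 150°] — the reconstruction problem is ill-posed and
analytic methods produce directional streak and shading artifacts.

This package implements the full simulation-and-reconstruction chain for
that setting:

1. a geometry builder for the segmented translational scan,
2. a matrix-free Siddon projector with exact adjoint,
3. SART and a rebinning FBP baseline,
4. a synthetic phantom generator and Gaussian projection-noise model,
5. a U-net that post-processes SART images (the combined pipeline is
   exposed as `sartconvnet_reconstruct()`), and
6. global PSNR/SSIM metrics.

## Scanning geometry

`tct_params()` records the physical scanner: source–detector distance
1300 mm, source–axis distance 900 mm, 207 source positions per 30° segment
at 0.145° spacing, an 800-element detector with 1 mm elements, and a
256 × 256 image grid with 1.38 mm pixels. The nominal field-of-view
diameter (352.90 mm) is carried as metadata only; the package never derives
anything from it because its relation to the other parameters is not
defined by the scanner description (it is close to, but not exactly,
256 × 1.38 mm).

Within a segment, the view at offset angle γ (from −span/2 to +span/2,
span = 206 × 0.145° = 29.87°) places the source at `(R_s tan γ, R_s)` in
the segment frame. Two conventions had to be fixed here:

* **Source/detector pairing.** The detector array is centred where the
  source–axis line meets the detector translation line and stays parallel
  to that line (a translating flat panel). This makes the central ray of
  every view pass through the rotation axis, and gives the source-to-panel
  centre distance `1300 / cos γ` — both asserted in the tests from the
  construction.
* **Segment placement.** Segment *m* is segment 0 rotated rigidly by
  30 *m*°, so its central view direction sits at 30 *m*° + 15°. Because
  206 × 0.145° = 29.87° < 30°, each segment leaves a 0.13° slack; the
  literal per-segment counts take precedence over exact angular closure,
  and no views are duplicated at segment boundaries.

All coordinates are in mm with the rotation axis at the origin. Image
matrices use a Cartesian convention: the first index runs along +x, the
second along +y, pixel (i, j) centred at `((i − 1/2 − n/2) px, (j − 1/2 −
n/2) px)`.

## The projector

The system matrix entry `a_ij` is the exact intersection length of ray *i*
with pixel *j*, computed by Siddon grid traversal with one ray per detector
element (source point to element centre; no element footprint integration).
The traversal is shared verbatim between the forward projection, the
backprojection and the fused SART sweep, so `⟨Af, g⟩ = ⟨f, Aᵀg⟩` holds to
rounding (the tests require 1e−10 relative). Rays that miss the image
square have row sum 0 and are excluded from SART updates; pixels crossed by
no ray have column sum 0 and are never updated. No ray discretization is
canonical for the algebraic formulation; Siddon lengths were chosen because
they make the algebraic system exact for a piecewise-constant image and the
adjoint implementable exactly. The projector is deterministic: fixed
traversal order, no stochastic elements.

A note on the accuracy model, because it shapes the oracle tests: for a
uniform disk of radius *r*, a ray at perpendicular distance *d* from the
centre has the analytic integral `2√(r² − d²)`. That function is not
Lipschitz at `d → r`, so near-tangent rays cannot match it to sub-pixel
accuracy under *any* pixel-basis rasterization of the disk — the error
there is a property of the representation, not of the traversal (the
traversal itself matches a brute-force sampling of the same rasterized
image to < 0.01 mm). The tests therefore assert the one-pixel-diagonal
bound for rays whose closest approach is at least r/4 inside the boundary,
and a uniform envelope (the chord change induced by a one-pixel-diagonal
boundary shift) for all rays.

## SART

The reconstruction update is the doubly normalized additive correction

$$f_j^{(n+1)} = f_j^{(n)} + \beta\,\frac{1}{a_{+j}} \sum_{i=1}^{M}
\frac{a_{ij}}{a_{i+}}\left(b_i - A_i f^{(n)}\right)$$

with relaxation β = 1 and a fixed 2500 sweeps at full scale. As printed,
the sum runs over all M rays simultaneously — a SIRT-like simultaneous
update — whereas classical SART cycles view by view. The package implements
the literal simultaneous form as the default (`update_mode =
"simultaneous"`, verified against a dense-matrix implementation of the same
formula to 1e−8) and offers `"view_sequential"` as an option; the
view-sequential mode normalizes by the *per-view* column sums, the
classical SART convention, because using the global `a_+j` there would
scale each sub-update down by the number of views.

Initialization is `f⁽⁰⁾ = 0`, there is no nonnegativity clamp by default
(a flag is provided), and the iteration count is the only stopping rule;
the per-sweep residual norms `‖A f⁽ⁿ⁾ − b‖` are recorded for diagnostics.
These three choices are deliberate defaults where the method description is
silent.

## FBP baseline

No FBP construction is canonical for the translational geometry, so the
baseline is the simplest defensible one: every ray is mapped to
parallel-beam coordinates (normal angle θ, signed offset s), scattered
bilinearly onto a (θ, s) grid, empty bins are filled by interpolation along
s, each angle row is Ram-Lak filtered (spatial-domain kernel, FFT
convolution), and the result is backprojected over the covered angles only.
On full-coverage data (≥ 180° + fan) this reconstructs a 64 × 64 disk
phantom above 25 dB PSNR with the correct amplitude; on limited-angle data
it shows the expected directional artifacts and is dominated by SART, which
is the comparison the baseline exists to support.

## Synthetic data

`make_phantom()` provides the classical 10-ellipse head phantom and a
`random_anatomy` generator: an elliptical body outline (attenuation 0.4,
arbitrary units) containing 4–10 seeded random internal ellipses with
attenuations in [0.05, 0.9], clipped to the body. It emulates only the
gross statistics of torso CT labels — piecewise-smooth compact structures
at 256 × 256 (64 × 64 at desk scale) — and none of the texture, noise
spectrum or anatomical correlations of real scans; conclusions from passing
tests are therefore about the *algorithms*, not about clinical image
quality.

The attenuation scale was chosen once so that line integrals are O(10²)
(body diameter ~300 mm × attenuation ~0.4), which makes the Gaussian
projection noise with absolute variance σ² = 10 a visible but moderate
perturbation. The noise is additive on the line-integral (post-log)
projection data — the literal reading of "noise added to the projection
data"; a pre-log intensity-domain model would require a dose parameter the
experiment description does not state.

`build_dataset()` chains phantom → forward projection → optional noise →
SART and pairs each SART image with its phantom label. Train and test items
draw phantom seeds from disjoint streams derived from one master seed, so
the splits cannot overlap and any archive is regenerable bit-identically
from its provenance sidecar.

## The U-net and its training

The network follows the encoder–decoder convolutional architecture that
FBP-style post-processing networks use: `depth` encoder stages of two 3 × 3
zero-padded convolutions + ReLU followed by 2 × 2 max pooling, channels
doubling per stage; a two-convolution bottleneck; decoder stages of 2 × 2
up-convolution, concatenation with the matching encoder map, and two 3 × 3
convolutions with batch normalization + ReLU; a final 1 × 1 convolution to
a single channel; and an additive residual skip from input to output so the
network learns the artifact component. The published figure of the
architecture does not fix per-layer channel counts legibly; depth 4 with 64
base channels — the standard U-net convention this family of networks
inherits — is the default and both are configurable. Batch normalization is
placed on the decoder path only, matching the description of the uphill
path; with batch size 1 it normalizes each channel over its spatial extent.

Training is plain momentum SGD on mean squared error (the loss is not named
in the training recipe; MSE is the convention of the family and consistent
with the discussion of MSE over-smoothing), batch size 1, learning rate
log-spaced 0.01 → 0.001 across 151 epochs, momentum 0.99, and gradient
clipping interpreted as clipping the global gradient norm to 10⁻². Patch
size 256 equals the full image at full scale, so no cropping happens at
defaults; larger inputs would be randomly cropped. Inputs and labels are
scaled by one constant (the maximum over training labels) recorded in the
model.

Two initialization choices matter:

* Weights are He-normal, seeded, so runs are reproducible to the
  floating-point determinism of the BLAS backend (bit-identical on one
  machine; the determinism test asserts identical loss histories for
  identical seeds).
* The final 1 × 1 convolution is **zero-initialized** by default, which
  together with the residual skip makes the untrained network exactly the
  identity. This is the usual initialization for residual artifact-learning
  networks: every optimization step then acts on the artifact component
  instead of first un-learning random initialization noise. It can be
  disabled (`final_zero_init = FALSE`).

## Desk scale

Paper-scale training (450 pairs at 256², 2500 SART sweeps, 151 epochs of a
depth-4/64-channel network) is a multi-hour GPU task. All package tests and
the acceptance script instead run the `desk` preset, a scaled-down version
of the same study: 64 × 64 grid covering the same ~353 mm field of view, 52
views per segment, a 200-element panel, 300 SART sweeps, a 20/5 train/test
split, and a depth-2/8-channel network trained for 100 epochs with the same
learning-rate schedule, momentum and batch size. One deviation from the
full-scale recipe: the gradient-norm clip is 0.1 rather than 10⁻², because
the 10⁻² clip — tuned to hundreds of thousands of optimization steps —
permits essentially no parameter motion within a few-thousand-step budget.
These sizes were chosen once so the complete suite runs on a single CPU in
minutes.

At these settings the package reproduces the qualitative findings of the
study design: SART PSNR increases strictly with scan range
([0°, 90°] < [0°, 120°] < [0°, 150°]), SART dominates FBP on limited-angle
data, the trained post-processor improves both PSNR and SSIM of every
held-out SART reconstruction, and the smoothed training loss decreases and
plateaus. The acceptance script (`scripts/acceptance.R`) recomputes all of
these numbers from scratch.

## Numerical notes and limitations

* Ties in the Siddon plane-crossing order produce zero-length cells that
  are emitted and ignored; rays of zero length are skipped.
* The global SSIM of the evaluation formulas is a single-window statistic
  over the whole image (population variances, C₁ = (0.01 L)², C₂ =
  (0.03 L)², L = max of the label). A sliding-window variant (11 × 11
  Gaussian, σ = 1.5) is available behind `windowed = TRUE` for cross-tool
  comparison; whether the original evaluation was windowed is not stated,
  so the printed global formula is the default.
* PSNR of identical images is reported as `Inf`; a non-positive label
  maximum is an input error for both metrics.
* FBP rebinning logs the number of empty (θ, s) bins it filled; with very
  sparse view sets the interpolation along s is the dominant error source.
* The batch-norm layers always use current-map statistics (batch size is 1
  throughout); there are no running averages, so train and eval behaviour
  coincide.
* Real-data handling is limited to what the simulation chain needs;
  validating against measured TCT projections, polychromatic physics,
  scatter, and 3-D/cone-beam geometry are out of scope.
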