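---
title: "Normalizing signal intensity in fluorescence image stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing signal intensity in fluorescence image stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intensify3d)
```

## The problem

Large single-channel image stacks from 2-photon and light-sheet microscopy
carry intensity artifacts that are unrelated to the specimen: excitation and
emission decay with depth, lateral illumination gradients, plane-to-plane
variation in beam penetration, photobleaching, and sample-specific effects
such as uneven clearing or antibody penetration. These artifacts defeat
downstream tools that assume a comparable intensity scale everywhere —
threshold-based detection, feature extraction, 3D rendering, stitching.

`intensify3d` implements the Intensify3D normalization strategy. Its two
working assumptions are:

1. In an ideal experiment the *background* intensity distribution would be
   the same everywhere; observed differences in the background are artifact
   and should be removed.
2. Signal pixels are sparse (often well under 1% of a plane), while
   background pixels are numerous and form a continuous histogram, so
   background quantiles can be estimated accurately on every plane.

The correction therefore estimates the background of each plane, divides by
it, and then harmonizes the per-plane intensity histograms across the stack.

## The per-plane (XY) correction

For each plane $I$ the package builds a smooth, strictly positive background
mask $M$ and corrects by division,

$$N(x) = \frac{I(x)}{M(x)} \cdot s,$$

where $s$ (the *standardization scale*) is the median of $M$ over tissue
pixels: division alone would send background to $\approx 1$ and invite
clipping artifacts on integer conversion; rescaling by $s$ restores the
native ADU range so pure background maps back to its typical level. The
stages:

**Signal removal.** The user supplies the *maximum background intensity*
(MBI): the highest pixel value attributable to background on a chosen
reference plane. Tissue pixels above the plane's propagated MBI are deleted
and re-filled by resampling observed sub-MBI tissue pixels. The donors are
drawn from a local window (side = SFS) around each deleted pixel: under a
lateral gradient — the very artifact being corrected — plane-wide donors
would bias the infill toward the plane median and distort the fit near
bright regions.

**MBI propagation.** Each plane receives the user's MBI scaled by the ratio
of its median tissue intensity to the reference plane's. The median tracks
the background (signal is sparse) and is equivariant under per-plane
multiplicative dimming, while remaining insensitive to plane-to-plane
differences in signal content. We experimented with propagating the MBI by
matching its quantile *rank* instead; because planes differ in how much
signal they contain, an identical rank lands inside the signal range on
signal-rich planes and inside the background on signal-free ones, which
measurably corrupted the background fit. The reference plane should be
chosen representative of the stack's signal content (a signal-free margin
plane makes any propagation rule extrapolate badly).

**Iterative background fit.** The signal-free plane is smoothed into $M$ by
a separable 2D Savitzky-Golay filter of window SFS (the *spatial filter
size*, chosen by the user at roughly twice the largest signal structure)
and polynomial order 3. A single plane-wide threshold cannot remove the
faint point-spread skirts of bright objects, and in strongly attenuated
regions whole objects can sit below the plane-wide MBI; the fit is
therefore iterated (`bg_passes`, default 3): residual outliers more than
2 robust standard deviations above a running-median pilot surface are
removed and re-filled before the final fit. The outlier cut scales with the
local background level because the noise is effectively multiplicative
across an illumination gradient. The mask is floored at `mask_floor`
(default 1 ADU) so division can never blow up.

**Numerical notes on the filter.** Interior points use the standard central
Savitzky-Golay kernel; the first and last half-windows use off-center
projection rows of an *order-1* fit. A cubic least-squares fit evaluated at
the end of its window has large, oscillating weights and rings on residual
structure — in testing this produced spurious bright streaks on border
rows — whereas the linear edge fit is stable and still reproduces constant
and linearly ramped backgrounds exactly, everywhere. Polynomial surfaces up
to the configured order are reproduced exactly in the interior.

## Tissue detection

Light-sheet planes often contain large regions of imaging medium that must
not participate in normalization. Each plane is classified independently:
the plane is subsampled (stride `downsample_factor`, default 8), three
features are computed per pixel (local mean, local standard deviation, raw
intensity; each standardized), projected onto two principal components, and
split into two clusters by either Gaussian-mixture EM or k-means. The
cluster with the higher mean raw intensity is tissue — imaging medium is
darker than autofluorescent tissue — which also makes the labeling
invariant to the clustering seed and to affine intensity rescaling. The raw
mask is cleaned by hole filling, removal of components below
`min_component_area` (default 0.1% of the plane), and dilation (default
SFS/4) to keep the media/tissue border inside the mask.

The Gaussian mixture uses equal-covariance models (EEE/EII, chosen by BIC).
Full per-cluster covariances were tried first and latched onto the
spread-out boundary band between medium and tissue, splitting the
background mode instead of separating the two classes (Jaccard 0.64 against
the known region, versus 1.0 for the equal-covariance models on the same
fixture).

Planes whose cleaned mask is empty are flagged and pass through unchanged;
degenerate (constant) planes get an all-true mask with a warning.

## Cross-stack (Z) harmonization

Each plane is treated as an independent sample — Z resolution differs from
XY and the step size is arbitrary — and is summarized by a quantile
profile: 10,000 quantiles of its corrected tissue pixels on the rank grid
$k/(Q+1)$, plus the upper-quantile rank $q^*$. Recording quantiles rather
than planes keeps Z normalization memory-light. The matching target is the
mean of the per-plane profiles (upper/lower quantile, maximum, and in
semi-quantile mode the full vector), which keeps the stack's global
brightness centered.

$q^*$ is the *certified-background rank*: the minimum over planes of both
the rank of the propagated MBI and $1 -$ (fraction of pixels the background
fit replaced, refinement passes included). Every replaced pixel was
classified signal, so ranks at or below $q^*$ are background on every
plane. Two weaker definitions were tried and rejected on measurement:
using the reference plane's rank alone, and using the per-plane MBI ranks
without the replaced-fraction cap. Both leave the upper part of the
"background" rank zone inside the sub-MBI signal skirts of signal-rich
planes under lateral gradients, so the matching target mixes one plane's
background tail with another's signal shoulder — which visibly inflates
the noise of signal-free planes (in the worst measured case by a factor
2.1, turning noise peaks into hundreds of spurious 5-voxel detections).

Three modes, all monotone within a plane:

* **Upper quantile** — multiply tissue pixels by
  `target_uq / uq_value`; shifts the histogram without reshaping it.
* **Contrast stretch** — affine map sending the plane's (10th percentile,
  upper quantile) to the target pair; extrapolated outside the anchors and
  floored at 0.
* **Semi-quantile** — below the upper quantile, full piecewise-linear
  quantile matching onto the target vector; above it, a linear stretch of
  slope `target_uq / uq_value` continued from the junction, so the map is
  continuous and the slope stays bounded even on planes whose maximum
  barely exceeds the upper quantile (planes without signal). Anchoring the
  upper branch on the plane maximum was tried and rejected: on signal-free
  planes it amplified the background noise tail several-fold. Below the
  lowest recorded quantile the map extrapolates with a slope fitted from
  the lowest knot to the 10th-percentile knot (clamping crushed the lower
  noise tail; a locally fitted slope at the extreme knot is too noisy).

A single-plane stack is its own target, so every mode reduces to the
identity there. Mode `"none"` applies the XY correction only.

## Determinism and parallelism

All randomness (background infill, clustering restarts, phantom rendering)
draws from substreams keyed by (master seed, stage label, plane index), so
results are bit-identical across reruns, plane orderings, and worker counts
(`workers` uses a process fork pool over planes).

## The sphere phantom

The validation data generator renders Gaussian spheres
$A\,e^{-\lVert r - c\rVert^2 / 2\sigma^2}$ on a flat background, convolves
with a separable Gaussian PSF, adds i.i.d. Gaussian noise, and quantizes to
the bit depth. Desk-scale defaults: $128 \times 128 \times 64$ voxels, 50
spheres, $\sigma \in [2, 4]$, amplitudes 1500–3000 ADU over background 300
with noise 30 — the amplitude floor clears background $+ 5\sigma_{noise}$,
so every sphere is detectable in the undistorted stack; signal voxels stay
well under 1%. A full-scale preset (`"full"`, $600 \times 600 \times 500$,
500 spheres) exists behind an explicit flag. Sphere centers are placed by dart throwing
with a minimum separation of $5\sigma_{max}$ (default): with fully
independent placement at desk-scale density roughly a third of the spheres
merge into single 26-connected components, which makes one-to-one counting
against ground truth ill-posed regardless of the normalization being
tested. The margin matters — at a mid-range threshold a sphere's
super-threshold radius is $\sigma\sqrt{2\ln(\text{peak}/\text{cut})}
\approx 1.7\sigma$ at the default amplitudes, so two maximal spheres need
more than $\approx 3.4\sigma + 1$ voxel to stay 26-disconnected, and a
$4\sigma$ separation measurably sits on the merge boundary.
`min_separation = 0` restores independent placement.

Four multiplicative distortion fields emulate acquisition artifacts, with
zero-based voxel indices and defaults $a = 0.7$, $c = 0.8$:

* `linear_x`: $g = 1 - a\,x/(X{-}1)$
* `linear_xy`: product of the two lateral ramps
* `log_z`: $g = (1{-}c) + c\,(1 - \ln(1{+}z)/\ln Z)$
* `combined_xy_logz`: product of the previous two

All values lie in $(0, 1]$; distortion only attenuates. By default the
field multiplies the finished noisy rendering, so a perfect correction
could restore the stack exactly; an alternative sensor-noise model
(`noise_model = "sensor"`) attenuates the noise-free volume and adds fresh
noise afterwards, under which the noise in attenuated regions is
fundamentally unrecoverable (restoration quality is then bounded away from
perfect no matter the algorithm).

## Scoring

Restoration is scored the way a microscopist scores segmentation quality:

* **3D object counting** — binarize at a single operating point (the Otsu
  threshold of the undistorted stack, applied to every stack after min-max
  matching to the undistorted range), label 26-connected components, drop
  those under 5 voxels, and measure each object. The labeling is verified
  against an exhaustive flood-fill oracle in the test suite.
* **Greedy one-to-one matching** of detections to true sphere centers
  (radius $2\bar\sigma$); detection has no defined negative count, so the
  false-positive axis is the false-discovery fraction fp/detected.
* **Relative mean absolute error** of voxel count, mean intensity, and
  integrated intensity over spheres detected in both the test stack and the
  undistorted reference.
* **Histogram restoration** — 1D earth-mover distance between
  min-max-matched 256-bin intensity histograms.

On the desk phantom, correction of each of the four distortions raises the
detection rate, lowers the false-discovery fraction, lowers every
per-sphere error statistic, and moves the intensity histogram closer to the
undistorted one (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, which recompute all of these from scratch).

## Harness choices on the phantom

The method is user-guided; the validation harness must stand in for the
user. It picks the MBI exactly as the instructions tell a user to — the
highest background value on a representative (middle) plane — which the
phantom knows analytically:
$(\text{background} + 4\sigma_{noise}) \cdot \max g$ on that plane.
Automatic histogram guesses (per-plane or stack-wide Otsu) were tried and
landed inside the background mode or below the lateral-gradient background
maximum, which corrupts the fit in ways no real user would accept. SFS is
set to twice the largest sphere diameter ($\approx 12\sigma_{max}$),
following the tool's own guidance.

## What the phantom does and does not show

The phantom exercises smooth multiplicative gradients, sparse compact
signal, Gaussian noise, and tissue/medium partition (via the disk
fixtures). It does not emulate structured background (vasculature,
white/grey matter contrast), spatially varying PSFs, stripe artifacts,
photon-limited (Poisson) noise, or signal occupying a large fraction of the
plane — the documented failure mode of any background-anchored
normalization. Passing the suite therefore demonstrates correctness of the
implementation under the stated assumptions, not performance on arbitrary
real data.

## Known limitations

* A single per-plane MBI cannot represent signal that falls below the
  background of brighter regions in the same plane under extreme lateral
  gradients; the iterative fit recovers the background, but such objects are
  partially treated as background during estimation.
* The background CV after correction is floored by the acquisition noise
  (noise/background, 10% at phantom defaults); correction removes the
  gradient component only.
* Quantile matching assumes the background *distribution* should be
  identical across planes; genuine biological differences in background
  (e.g. different tissue types along Z) will be "corrected" away.
* Detection scoring uses plain connected components, not the
  watershed-style splitting of the FIJI 3D object counter; touching objects
  merge, which is why the generator separates sphere centers by default.

## Problem sizes used in the shipped checks

The test suite and the acceptance script use the desk-scale phantom
($128 \times 128 \times 64$, 50 spheres) for the four-distortion
restoration experiment and the field-recovery check, a
$64 \times 64 \times 26$ phantom for byte-level determinism checks, and
$10^3$-voxel grids for the 100-fold component-labeling oracle comparison.
These sizes give stable statistics for every scored quantity while keeping
a full run in the minutes range on one core.
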