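---
title: "Super-resolved 3D localization and tracking of chromosomal loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-resolved 3D localization and tracking of chromosomal loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lociloc3d)
```

## The problem

Chromosomal loci in *E. coli* can be made visible as diffraction-limited
fluorescent spots by binding fluorescently tagged repressor proteins to a
short operator array inserted at the locus.  With a cylindrical lens in
the detection path the point spread function (PSF) becomes astigmatic:
the ellipticity of the spot encodes the emitter's depth, so a single 2D
image determines the 3D position.  Two complications make this harder
than conventional single-molecule localization: the fluorescent signal is
weak (a dozen binding sites rather than hundreds), and the unbound
labelled protein produces a *structured* intracellular background that
varies on the same length scale as the PSF itself.  `lociloc3d`
implements a full analysis chain for this regime: a data-driven simulator
(spline PSF, boundary-distance-conditioned background, per-pixel sCMOS
camera noise), a convolutional localizer trained on that simulator, the
geometric mapping of localizations into internal cell coordinates, and
the mean-squared-displacement (MSD) analysis of locus motion.

## Cubic-spline PSF model

Bead z-stacks are aligned by 3D cross-correlation (sub-voxel refinement
by a quadratic fit of the correlation peak, at 0.1-voxel granularity),
averaged, and normalized by the maximum of the mean of the three central
planes.  The normalized stack is interpolated by a tensor-product
piecewise cubic spline: within voxel $(i,j,k)$,

$$f_{ijk}(x,y,z)=\sum_{m=0}^{3}\sum_{n=0}^{3}\sum_{p=0}^{3}
a_{ijkmnp}\,\Big(\tfrac{x-x_i}{\Delta x}\Big)^m
\Big(\tfrac{y-y_j}{\Delta y}\Big)^n
\Big(\tfrac{z-z_k}{\Delta z}\Big)^p,$$

with 64 coefficients per voxel and first and second derivatives
continuous across every internal voxel face.  End conditions are
not-a-knot, the common choice for experimental PSF stacks because it
avoids the artificial flattening of natural splines at the stack
boundary.  Negative overshoot is clipped at zero before each rendered 2D
slice is normalized to sum to 1 and scaled to the emitter's photon count;
total-intensity variation of the PSF across z is deliberately not
modelled in the spline (the network training samples photon counts, so it
absorbs that variation).

The Cramér–Rao lower bound (CRLB) on localization precision uses the
Poisson imaging model $\mu_k = N\,g_k(x,y,z)+b$ with $g$ the
slice-normalized spline, parameters $(x,y,z,N)$ and known background.
Derivatives of $g$ come analytically from the polynomial coefficients
(including the derivative of the normalization), so the CRLB agrees with
a finite-difference Fisher-information oracle to better than 1%.  A
singular Fisher matrix (a flat or z-insensitive PSF) is reported as
infinite bounds along the affected axes rather than silent `NaN`.

## Background and camera models

In-cell background is modelled in the photon domain as a family of gamma
distributions conditioned on the integer Euclidean distance transform
(EDT) of the segmentation mask: pixels at the cell boundary form shell 1,
deeper pixels deeper shells, with outside-cell ("chip") pixels fitted
separately.  To avoid contaminating the fit with the locus signal, the
brightest 25% of each cell's pixels (`ceiling(0.25 n)` per cell per
frame) are excluded.  Naively trimming the upper quartile would bias a
maximum-likelihood gamma fit, so excluded pixels enter the likelihood as
right-censored observations at the per-cell cutoff; this keeps the
exclusion rule while making parameter recovery consistent (the test suite
verifies 5% recovery at $10^5$ pixels per shell).  Shells with fewer than
200 pixels are merged into the nearest deeper shell.  Pixels are sampled
independently given their shell; spatial correlation of the background
beyond the shell structure is a known non-modelled feature.

The sCMOS camera is described per pixel by gain (gray/e⁻), read noise
(e⁻ rms), offset and dark-current rate.  Calibration uses dark series at
multiple exposure times (offset and thermal rate from the per-pixel
linear fit of mean versus exposure; read noise from the variance at the
shortest exposure after subtracting the thermal shot term) and optional
graded flat fields for the photon-transfer gain estimate.  Because
per-pixel gain estimates are noisy, all photon/gray conversions use the
scalar median gain (default 2.58 gray/e⁻, 12-bit range).

## Simulated training data

Ground-truth frames place Poisson-distributed numbers of emitters
uniformly inside synthetic spherocylindrical cell masks, with photon
counts uniform in [750, 3000] and depths uniform in [−700, 300] nm.  The
spline PSF renders each emitter; structured background is sampled from
the gamma-shell model (cell average ≈ 5.8 photons/pixel); the camera
model converts photons to gray levels.  At the reference emitter
intensity of ~1950 photons this yields a measured signal-to-background
ratio of ~4, the regime of interest.  Per-pixel training targets follow
the detection-map convention: the probability map is 1 at each emitter's
pixel, sub-pixel offsets lie in [−0.5, 0.5] pixels, depth is scaled
affinely from [−700, 300] nm onto [−1, 1], photons are divided by 3000.
When two emitters collide in one pixel the dimmer is dropped (targets are
single-valued per pixel).

The synthetic fixtures intentionally idealize several features of real
data: cell masks are exact (no segmentation error), the PSF is spatially
invariant across the field, background pixels are independent given the
shell, and there is no photobleaching, blinking or motion blur.  Passing
tests therefore demonstrate correctness of the estimators under the
stated generative model, not robustness to those real-data effects.

## The localizer and its loss

The localizer is a fully convolutional network of two small U-nets in
series; the first consumes the photon-domain tile plus two CoordConv
channels (normalized global camera coordinates of every tile pixel), the
second consumes the first's features together with the raw input, and a
linear 3×3 head emits ten per-pixel channels: detection probability
(sigmoid), sub-pixel x/y offsets (tanh, ×0.5 pixel), scaled depth (tanh),
scaled photons (sigmoid), four positive uncertainty channels (sigmoid
scaled to 300 nm laterally, 600 nm axially, and the photon ceiling), and
a background-free emitter image (sigmoid, on the scaled-photon scale so
the squared-error term is commensurate with its weight).  Forward and
backward passes are implemented over compiled convolution kernels; every
analytic gradient is verified against central finite differences.

The training loss is the weighted sum
$\mathcal{L} = w_{count}\mathcal{L}_{count} + w_{CE}\mathcal{L}_{CE} +
w_{loc}\mathcal{L}_{loc} + w_{Mol}\mathcal{L}_{Mol}$ with weights
(0.2, 0.25, 1, 8000):

* $\mathcal{L}_{count}$: Gaussian negative log-likelihood of the true
  emitter count under the Gaussian approximation of the predicted
  Bernoulli field, mean $\sum_k \hat p_k$ and variance
  $\sum_k \hat p_k(1-\hat p_k)$ (floored at $10^{-6}$, since the
  likelihood degenerates when all probabilities saturate).  The standard
  $\tfrac12\log(2\pi\sigma^2)$ normalization is used; its value at the
  mean is checked against `dnorm`.
* $\mathcal{L}_{CE}$: pixel-wise binary cross-entropy against the one-hot
  detection map, probabilities clamped to $[10^{-7}, 1-10^{-7}]$.
* $\mathcal{L}_{loc}$: for each true emitter $u_e=(x_e,y_e,z_e,I_e)$, the
  negative log of a probability-weighted mixture of diagonal 4D Gaussians
  centred on each pixel's predicted mean (pixel centre + offsets, in
  nanometres and photons) with the predicted per-axis uncertainties,
  averaged over emitters and evaluated in log space (log-sum-exp).  With
  no emitters the term is zero.  Working in physical units makes the
  uncertainty channels directly interpretable as localization errors.
* $\mathcal{L}_{Mol}$: sum of squared differences between the predicted
  and true noise-free emitter images.

Training uses AdamW (weight decay 0.1), batch size 64 and an initial
learning rate of $6\times10^{-4}$ reduced by 90% every 5000 iterations
for 20000–40000 iterations in the full-scale configuration.  The
package's *scaled* reference configuration — chosen so a complete
training fits a single CPU — keeps the iteration count (20000), learning
rate, decay factor and weight decay, but runs batch 4 on 16×16-pixel
tiles with a compact network (8 base filters, two pooling levels, two
stages, ~29k parameters) and reorganizes the schedule into *epochs with
warm restarts*: the budget is split into passes of 2000 iterations
over an identical freshly-rendered batch sequence (the simulator is
re-seeded per pass), the AdamW state is restarted at each pass boundary,
and the final two passes run at a 10× reduced learning rate.  At this scale —
roughly 16× fewer samples than the smallest full-scale recipe — the
epoch/warm-restart schedule converged several times faster than
streaming fresh batches under the printed decay schedule, whose learning
rate freezes the optimizer long before the depth channel converges —
under-convergence shows up as a regression-to-the-mean bias in $z$.  The reference budget is 22000 iterations (11 passes: 9 at
$6\times10^{-4}$, 2 at $6\times10^{-5}$); batches are rendered in the
first pass and replayed bit-identically in later passes, so the renderer
runs once.  Training tiles carry structured cell background only: the uniform
bead-like background level (~5.8 photons/pixel) lies inside the range
spanned by the structured shells, so the same network serves both the
cell-background accuracy evaluation and the uniform-background
bead-precision protocol.  Training emitter density is raised to 4 per
cell (versus 1–2 loci per cell at evaluation) purely to increase
positive supervision per tile — target maps are exact, so training
density is a free choice of the training distribution; 70% of training
crops are centered (with jitter) on an emitter for the same reason.

## Inference

Frames are partitioned into tiles with overlapping context; every frame
pixel is owned by exactly one tile, and border tiles are reflect-padded.
The network may legitimately distribute one emitter's detection
probability over the pixels of its spot, so decoding first aggregates the
probability map over each pixel's 3×3 neighbourhood, then takes local
maxima within a 5×5 suppression window and applies the strict threshold
p > 0.8.  Channel values are read out as probability-weighted averages
over the winning neighbourhood and converted to nanometres from the image
origin (top-left corner).  Detections are scored against ground truth by
optimal one-to-one matching (Hungarian algorithm, gates 250 nm lateral /
500 nm axial) with Jaccard, per-axis RMSE and the challenge-style
efficiency score.  Tile-seam invariance holds exactly when the overlap
exceeds the decoder's influence radius; the suite demonstrates it with a
shallow configuration whose receptive field fits inside the overlap.

## Internal cell coordinates

Localizations are registered onto the segmentation frame by a projective
transform (normalized DLT homography) fitted to control points, assigned
to cells by the containing mask pixel, and converted to internal
coordinates: the cell backbone is a second-degree polynomial fitted
through the mask pixels in the frame of the two poles (farthest pair of
boundary pixels); `l` is the arc length from the new pole to the nearest
backbone point (the stationarity condition is a cubic solved exactly),
`s` the signed perpendicular distance, and the radial coordinate
$r=\sqrt{s^2+z_c^2}$ and angle $\phi=\mathrm{atan2}(z_c, s)$ combine the
short axis with the depth.  Depth itself is never remapped into the cell
frame — there is no common z reference across cells — but a per-field
tilt of the imaging plane is removed by fitting a plane to spatially
binned (8×8) mean z values and subtracting it; the correction is
idempotent.  Pole identity (new versus old) comes from lineage metadata
when available, or a caller-supplied hint; the long-axis origin sits at
the new pole so `rel_l` runs from 0 (new pole) to 1 (old pole).

## Tracking and MSD analysis

Trajectories are greedy nearest-neighbour links of per-cell, per-frame
localizations with a 500 nm displacement gate, keeping runs of at least 5
consecutive frames, in cells of at least 1.6 µm², restricted by default
to the cell half nearest the new pole (single-locus regime).  MSD curves
are time-averaged within each trajectory, then averaged without weights
across trajectories (SEM across trajectories).  The long-axis analysis
can re-zero each trajectory and subtract the ensemble-mean displacement
per elapsed time, removing net cell growth.  The radial MSD uses the
scalar radius $r(t)$ (a 2D yz-vector variant is available via
`yz_vector = TRUE`); the angular MSD multiplies the unwrapped angle by
the trajectory's mean radius (arc length), excluding points within 20 nm
of the axis where the angle is ill-defined.

Power-law fits $\mathrm{MSD}(\tau)=2D\tau^{\alpha}$ use ordinary least
squares on the log-log curve; the offset form
$2D\tau^{\alpha}+\varepsilon$ is a constrained nonlinear fit
($\varepsilon \ge 0$, initialized from the log-log fit) whose intercept
estimates the localization error as $\sigma=\sqrt{\varepsilon/2}$.
Confinement plateaus are the mean of the five longest-lag MSD values.
Sister-locus coordination is quantified by the Pearson correlation of
unwrapped angle series over overlapping frames, and short-axis
histograms are summarized by a symmetric two-component normal fit whose
mixture is reported as effectively unimodal when $\mu \le \sigma$ (the
exact condition for a mirrored equal-weight pair to have a single mode).

## Numerical choices and problem sizes

Validation uses an analytic astigmatic fixture (focal width 140 nm,
depth scale 400 nm, astigmatism offset 250 nm, 45° rotation, 110 nm
pixels, 50 nm z-steps) in place of measured bead stacks, so every
estimator can be tested as a parameter-recovery problem.  The test suite
runs the full scaled training once (20000 iterations) and evaluates
localization accuracy on 60 simulated frames at ~1950 photons over the
stable z-range [−400, +50] nm, and bead precision with 50 repeated
frames at each of seven z heights; statistical suites use a few hundred
trajectories of 30–50 steps.  fBm is synthesized exactly by Cholesky
factorization of the fractional-Gaussian-noise covariance (trace lengths
≤ 2048 keep this cheap); the OU process uses its exact discretization.
All generators are pure functions of their parameters and a seed.

## Known limitations

The scaled network is far smaller than a full-scale GPU-trained model
and its depth estimates carry a residual shrinkage toward the centre of
the training range when under-trained; the reported worst-axis accuracy
should be read with that in mind.  The greedy gated linker is a stand-in
for a full lineage-aware tracker and is validated only on synthetic
data.  Field-dependent PSF aberrations, emitter photophysics, motion
blur and segmentation errors are all outside the generative model.
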