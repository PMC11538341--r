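# lociloc3d

Super-resolved 3D localization and tracking of fluorescently labelled
chromosomal loci in rod-shaped bacteria.

Chromosomal loci tagged with a small fluorescent repressor–operator array
appear as dim diffraction-limited spots over a *structured* intracellular
background of unbound labelled protein. With a cylindrical lens in the
detection path the point spread function (PSF) becomes astigmatic, so spot
ellipticity encodes depth and a single 2D frame determines the 3D
position — provided the localizer can cope with a signal-to-background
ratio of only ~4. `lociloc3d` implements the complete analysis chain for
this regime, in five parts:

1. **Spline PSF** — bead z-stacks are aligned, averaged and interpolated
   by a C2-continuous tensor-product cubic spline (64 coefficients per
   voxel),

   f(x,y,z) = Σ_mnp a_mnp ((x−x_i)/Δx)^m ((y−y_j)/Δy)^n ((z−z_k)/Δz)^p,

   which renders the PSF at arbitrary sub-voxel positions and yields the
   Cramér–Rao lower bound (CRLB) on localization precision analytically.
2. **Data-driven simulator** — in-cell background modelled as gamma
   distributions conditioned on the distance to the cell boundary (EDT
   shells, brightest 25% of each cell excluded as right-censored
   observations), plus a per-pixel sCMOS camera model (gain, read noise,
   offset, dark current).
3. **Deep localizer** — a fully convolutional network (two small U-nets
   in series with CoordConv pixel-coordinate inputs) trained on simulated
   tiles with the compound loss
   L = 0.2·L_count + 0.25·L_CE + 1·L_loc + 8000·L_Mol
   (emitter-count likelihood, pixel-wise cross-entropy, probability-
   weighted 4D Gaussian mixture over (x, y, z, photons), and a
   background-free PSF image term). Forward, backward and AdamW are
   implemented in this package over compiled convolution kernels.
4. **Cell mapping** — localizations are registered by homography onto the
   segmentation frame, assigned to cells, converted to internal
   coordinates (arc length `l` along a quadratic backbone from the new
   pole, signed short-axis distance `s`, radius r = √(s²+z²), angle
   φ = atan2(z, s)), and corrected for imaging-plane tilt.
5. **Tracking / MSD** — gated trajectory linking (≥ 5 consecutive frames,
   cell area ≥ 1.6 µm², new-pole half), ensemble MSD along
   long/short/depth/radial/angular axes, power-law fits MSD(τ) = 2Dτ^α
   and 2Dτ^α + ε (the intercept gives the localization error
   σ = √(ε/2)), confinement plateaus, sister-locus angle correlations and
   bimodal short-axis histogram fits.

Every experimental input has a seeded synthetic stand-in (astigmatic bead
stacks, spherocylinder cell masks, fractional Brownian motion and
Ornstein–Uhlenbeck trajectories with known diffusion laws), so the whole
pipeline is testable as a set of parameter-recovery problems.

## Worked example

Calibrate a PSF from a (synthetic) bead stack, inspect the theoretical
precision at the locus signal level, and simulate + analyse a tracking
experiment:

```r
library(lociloc3d)

## 1. PSF calibration and CRLB
stack <- synth_bead_stack(astig_params())      # analytic astigmatic bead
psf   <- fit_cspline(average_bead_stacks(list(stack)))
crlb(psf, z = -200, photons = 1950, bg = 5.8)
#>   sigma_x   sigma_y   sigma_z
#>  4.912254  4.912254 17.698832
```

About 5 nm lateral and 18 nm axial precision is the information-theoretic
floor for ~1950 photons on a 5.8 photons/pixel background with this PSF —
any unbiased estimator is at best this good.

```r
## 2. Subdiffusion analysis on trajectories with a known law
##    (fractional Brownian motion, H = 0.2  =>  alpha = 2H = 0.4)
fb <- synth_fbm(H = 0.2, n_steps = 50, n_traj = 250, D = 300, seed = 5)
trajs <- lapply(seq_len(ncol(fb)), function(i)
  data.frame(traj_id = i, cell_id = 1L, frame = 0:50, t_s = 0:50,
             l_nm = fb[, i], s_nm = 0, zc_nm = 0, r_nm = 300, phi_rad = 0))
fit_msd_powerlaw(msd(trajs, "long")[1:15, ])
#> msd_fit (loglog-linear): alpha = 0.3917, D = 309.2 nm^2/s^alpha
```

The recovered anomalous exponent (0.39 versus the true 0.40) and
generalized diffusion coefficient match the generating values; on experimental locus data the
same call quantifies subdiffusion along any cell axis.

Training and running the localizer end to end:

```r
cfg   <- locnet_config(tile = 16, base = 8, depth = 2, n_stages = 2,
                       batch_size = 4, iterations = 22000, seed = 1)
model <- train_reference_model(cfg)            # ~15 min on one CPU
setup <- ref_setup(cfg)
locus_accuracy_protocol(model, setup)$rmse     # per-axis RMSE (nm)
bead_precision_protocol(model, setup$psf, setup$cam,
                        z_heights = seq(-400, 50, by = 75))
```

A command-line front end (`exec/lociloc3d`) exposes the same steps as
`calibrate-psf`, `fit-background`, `simulate`, `localize`, `map-cells`,
`track` and `msd` subcommands operating on TIFF/CSV/JSON files.

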