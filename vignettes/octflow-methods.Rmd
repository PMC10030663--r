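---
title: "Models and methods behind octflow"
author: "octflow maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind octflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

octflow reconstructs cerebral blood-flow-velocity (µODT) and angiography
(µOCA) volumes from repeated-B-scan optical coherence tomography
acquisitions of the awake rodent cortex, removes the bulk-motion artifacts
that dominate awake imaging, and quantifies the resulting microvascular
networks. This vignette explains the underlying models, the parameters
that matter, what the synthetic phantom does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The imaging model

An acquisition is a 4D complex field indexed `(z, x, r, y)`: depth along
the beam, fast (A-scan) axis, repeated B-scan frames, and the slow axis.
The A-scan at fast-axis index `x` of repeat `r` is acquired at time
`t = r*dtOCA + x*dtODT`, with `dtODT` the Doppler pair spacing (default
2.3 ms) and `dtOCA` the repeated-frame spacing (default 0.21 s); their
ratio of roughly 100 is what makes angiography far more motion-sensitive
than Doppler flow. A scatterer moving with axial velocity `v_z` advances
its phase at `4*pi*n*v_z/lambda0` rad/s (`n` = 1.35, a typical cortical
refractive index; `lambda0` = 1.31 µm), so two adjacent A-scans differ by

    dphi = 4*pi * n * v * cos(theta_z) * dtODT / lambda0,

wrapped physically into `(-pi, pi]`. Velocities beyond the `±pi` range are
synthesized wrapped — matching physical phase wrapping — and flagged as
aliased in the ground-truth sidecar, never clipped.

**Doppler reconstruction** (`phaseSubtractionODT`) takes the argument of
the lag-1 complex autocorrelation along the fast axis, averaged across all
repeat frames and optionally over a small `(z, x)` window (default 3×3)
before the argument is taken. Averaging the complex products across all
repeats, rather than using a single pair, is a free design choice here; it
reduces variance at no bias cost because the pair phase is identical in
every frame. Zero-amplitude voxels have an undefined argument and are
returned as 0 with a low-confidence flag. Outputs are *not* Doppler-angle
corrected; `angleCorrectVelocity` applies `1/cos(theta_z)` separately and
masks angles above 80° (default), where the correction diverges.

**Angiography reconstruction** (`reconstructOCA`) computes the speckle
variance — the per-voxel coefficient of variation of intensity — across
the most-correlated repeat frames. Because a CoV estimated from ~6 frames
is heavy-tailed in static tissue, each B-scan is box-averaged (3 voxels
along z and x by default) before projection; the filter is linear, so the
CoV's invariance to global intensity scaling is preserved. The slow axis
is deliberately not smoothed: replicate padding would under-average the
first and last positions and print a spurious end-of-scan band into the
en-face image. Disable with `smooth = NULL`.

## Frame selection under bulk motion

With `N = 14` repeats per position, the `N' = 6` frames correlating above
`r = 0.9` with a reference frame are selected. Two choices deserve
explanation:

* **What is correlated.** Pearson correlation is computed on
  log-compressed, Gaussian-smoothed (sigma 2 px) intensities. Raw speckle
  and intra-vessel flow decorrelation are stochastic at the single-pixel
  scale; smoothing makes the statistic measure what it is meant to
  measure — bulk frame alignment — rather than speckle noise.
* **The reference frame.** The reference is the frame whose
  `(N'-1)`-th largest correlation to the other frames is highest, i.e. the
  frame sitting in the largest clique of mutually consistent frames. A
  median-based reference breaks down as soon as more than half the frames
  are corrupted (a regime that genuinely occurs in awake imaging, and the
  regime our phantom tests exercise with 8 of 14 frames scrambled); the
  clique criterion only requires that at least `N'` clean frames exist.

Ties are broken towards lower frame indices for determinism. If fewer
than two frames qualify, the best two are used and the position is flagged
as degraded.

## Stripe detection and structure-aware inpainting

Severe motion collapses whole B-scans; in the en-face angiography MIP
these appear as bright slow-axis stripes spanning several positions.
Detection summarizes each slow-axis position by the lower quartile of the
MIP across the fast axis — robust both to speckle and to bright
vasculature covering part of the B-scan, whereas a median is biased as
soon as vessels cover a substantial fraction of the line — detrends it
with a mirror-padded running median (unbiased at the scan ends), and
flags robust z-scores above 6. The MAD scale is floored at 5% of the
background level: stripes are large-amplitude events, and a MAD estimated
from nearly noise-free data would otherwise flag benign fluctuations.
The statistic saturates once frames are fully decorrelated, so it is
monotone in corruption strength only up to that point — which is also why
detection is reliable: real stripes sit far above threshold.

Segmentation uses optimally oriented flux: the flux of the
Gaussian-regularized gradient through a sphere (circle in 2D) of radius
rho, assembled per voxel from gradient samples on the boundary; the
rectified mean of the cross-sectional eigenvalues, maximized over scales,
is the bright-tube response. The surface average makes responses
comparable across scales, and the argmax radius approximates the tube
radius. Binarization is hysteresis thresholding at the 85th/97th
percentiles of the positive responses with 5-px minimum object size; when
stripes are present their columns are excluded from the threshold
estimation, since their responses reflect the artifact, not vessels.

The inpainting model is a 3-level encoder–decoder with gated convolutions
(`h = elu(conv_f(x)) * sigmoid(conv_g(x))`) at each level, skip
connections, 8 base channels and a logit output. It is trained entirely
self-supervised: synthetic stripes (widths log-uniform 4–32 px, matching
the several-positions span of real stripes) are drawn over *clean* regions
of the binarized mask, so the original mask is a free target. The input
carries three channels — the occluded mask, a stripe indicator, and a
gradient-magnitude guidance channel computed from the (stripe-corrupted)
MIP, which preserves whatever structural cues survive inside the band.
Patches may overlap real stripe bands; those columns are zeroed and
carry zero loss weight, so supervision only ever comes from the clear
area. The loss is binary cross-entropy with weight 1 inside the occluded
band and 0.1 outside; Adam, 300 iterations on 64×64 patches at desk
scale. At inference only pixels inside detected bands are ever modified —
everything else is returned bit-exact — and the final mask multiplies the
MIP, which zeroes background exactly and is idempotent.

## Self-supervised 3D enhancement

The volume enhancer is a 3-level U-shaped 3D CNN (8 base channels,
residual output initialized near identity; the last decoder convolution
runs at half resolution to keep full-resolution work in the 8-channel
layers). Training consumes single noisy volumes only. Each iteration
draws a 32³ patch and builds two branches, each applying:

* **Intensity remapping:** a strictly monotone piecewise-linear map whose
  control abscissae are empirical quantiles of the vessel voxels and whose
  ordinates are drawn uniformly — vessels of different intensities, rank
  order preserved exactly.
* **Vessel cropping:** a fraction (default 0.3) of vessel segments —
  balls of 3–6 voxel radius around randomly chosen vessel voxels, clipped
  exactly to the requested voxel fraction — replaced by background-level
  noise, with an exact record of the dropped voxels.
* **Input perturbation:** additive Gaussian noise (sd 0.05 of the
  normalized range) applied to the input only.

The provisional vessel mask for cropping comes from oriented flux on the
noisy volume itself, thresholded *conservatively* (95th/99th percentiles,
10-voxel minimum object size). This matters: a permissive mask is mostly
noise specks, and cropping specks teaches the network to hallucinate
background structure; a conservative mask keeps the restoration task
about genuine vessels.

The composite loss is the separately-averaged L1 over the dropped
segments, plus 0.5× the mean L1 elsewhere (an identity anchor), plus 0.1×
the mean absolute disagreement between the two branch predictions (the
intensity-invariance pressure). Separate averaging keeps the
gap-restoration term from being drowned by the overwhelming background
volume. Optimization is Adam (lr 5e-3, cosine decay, batches of 2
patches, 200 iterations at desk scale); the manifest records per-iteration
losses and the loss of a fixed held-out evaluation set before and after
training, so the reported reduction is not confounded by patch-to-patch
variance. Volumes are normalized by their 1st–99th percentiles (recorded
in the manifest); enhancement operates on the phase magnitude with the
sign reattached afterwards, so flow direction is never flipped. Whole
volumes are processed in overlapping tiles with triangular-window
blending.

## Vessel quantification

* **Orientation:** per-voxel eigendecomposition of the sigma²-normalized
  Gaussian Hessian at scales {1, 2, 4} voxels; the vessel axis is the
  eigenvector of the smallest-magnitude eigenvalue, the per-voxel scale is
  chosen by maximal eigenvalue anisotropy, and near-isotropic voxels get
  confidence 0 with an undefined angle.
* **Arteriole/venule identity:** the sign of the Doppler value combined
  with the sign of the edge's axial direction gives the flow sense along
  each centerline edge; near-horizontal edges abstain. At every
  bifurcation the tree votes — one inflow splitting into several outflows
  is arterial (branching out), the converse venous (branching in) — and
  trees label by unanimity, with conflicting trees left unclassified
  carrying a conflict score. Trees whose largest diameter is at or below
  10 µm (a cutoff chosen here, at the conventional capillary boundary) are
  capillaries.
* **Diameter:** twice the Euclidean distance transform at centerline
  points, averaged per segment.
* **Capillary density:** after removing large vessels (local diameter
  above the cutoff), the mask is thinned (Zhang-Suen) and density is
  skeleton length per ROI area, with link lengths counting diagonal steps
  as sqrt(2); the fill factor (foreground fraction) is reported alongside.
* **Flow time courses:** per-ROI CBFv is the mean Doppler magnitude over
  ROI voxels above a noise floor — monotone in true speed and matching
  un-angle-corrected practice; whether to use angle-corrected velocities
  instead is left to the caller (both paths exist, uncorrected is the
  default). Relative changes are `(x - x0)/x0` against the baseline-window
  mean, so the baseline mean of the relative change is 0 by construction.
  Compartment traces are arithmetic means over member ROIs with standard
  deviations; hypothesis testing is out of scope.

## The phantom: what it emulates and what it does not

The generator builds binary branching trees (volumetric flow split at
each bifurcation with cube-root radii, so conservation is exact), dives
them into the volume like penetrating cortical vessels, and renders
capillaries as near single-voxel tubes with speeds of 20–200 µm/s.
Speckle is a per-voxel circular complex Gaussian, amplitude-scaled by
scatterer density (lumen 3× parenchyma by default), correlated along the
fast axis to mimic beam oversampling, and decorrelating across repeats at
a rate increasing with flow speed. Bulk motion adds a global phase
`4*pi*n*dz/lambda0` plus a sub-voxel axial resample per frame; severely
corrupted frames additionally have their structural envelope displaced
along the beam and their field replaced by fresh speckle (uniform phase,
Rayleigh amplitude), blended by a scramble amplitude in [0, 1]. A
fast-axis phase ramp driven by the displacement rate is available but off
by default.

Not emulated: spectrometer physics (fringes, k-linearization,
dispersion), pulsatility and autoregulation, red-blood-cell granularity,
scattering shadows below large vessels, and lateral motion. Passing tests
therefore demonstrate the *algorithms* — phase arithmetic, selection
logic, artifact removal, learned restoration, geometric quantification —
under controlled conditions; they do not certify performance on animal
data, whose noise is richer.

Noise-free phantoms make the forward phase model exact except at lumen
boundaries, where the fast-axis neighbour carries a different true flow;
round-trip checks therefore evaluate where the forward model is locally
homogeneous.

## Numerical choices and degenerate inputs

Grids are 0-based and half-open in all ROI/band indexing; physical
coordinates are micrometres with depth increasing into tissue. Arguments
of complex numbers are taken so phases lie in `(-pi, pi]`. Selection ties
break to lower frame index. Degenerate (all-equal) vesselness maps yield
an empty mask with a warning; empty stripe masks make inpainting a no-op;
a baseline of zero flow makes relative changes undefined (NA), never
infinite. All randomness flows through one seeded generator per
operation, pipeline stages derive child seeds by stable hashing of the
stage name (so inserting a stage does not perturb its siblings), and the
BLAS thread pool is pinned to one thread at package load for bit
reproducibility.

Desk-scale problem sizes used throughout the package's own test suite:
64×64×(6 or 14)×(24–128) voxel acquisitions on a 3 µm pitch, 300-iteration
inpainting runs on 64×64 patches and 200-iteration enhancement runs on
32³ patches. These sizes were chosen so a full pass exercises every
pathway at interactive speed; all are configuration knobs.

## Known limitations

* The inpainting model only ever sees synthetic stripes over clean
  regions; pathological cases where stripes cover most of the image leave
  too little supervision.
* Capillary density uses 2D en-face skeletons; strongly depth-overlapping
  capillary beds project onto each other and the density is then an
  underestimate (the fill factor is the more robust alternative there).
* The enhancement model is trained per volume (or small volume sets) at
  desk scale; no pretrained weights are distributed, by design.
* Absolute perfusion calibration and statistical hypothesis testing are
  out of scope.
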