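---
title: "Methods: layer-resolved cerebrovascular morphometry and reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layer-resolved cerebrovascular morphometry and reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasculometry)
```

This package quantifies cortical microvasculature from volumetric optical
imaging in a vessel-resolved, depth-resolved way: per-vessel blood-flow
velocity and diameter, per-branch tortuosity, per-layer density and
branching metrics, dynamic cerebrovascular reactivity, and a per-parameter
classification score that ranks which of these measurements best separates
two experimental groups. This vignette documents the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic validation does and does not establish.

## Doppler velocimetry

Between two A-scans separated by `T` seconds, moving red blood cells shift
the optical phase by `Δφ`. The axial velocity is

    v = λ₀ · Δφ / (4π · n · T · cos θ_z)

with central wavelength `λ₀ = 1.31 µm`, tissue refractive index
`n = 1.38`, `T = 1/6000 s ≈ 0.167 ms` (6k A-lines/s), and `θ_z` the angle
between the flow and the incident beam. `phase_to_velocity()` applies this
elementwise; at `Δφ = π` and `θ_z = 0` the defaults give `v ≈ 1.424 mm/s`,
which is also the largest unambiguous speed (phase wraps beyond ±π; the
package treats wrapped phase as an input error and does not attempt
unwrapping).

Design choices:

* `θ_z` is supplied per vessel (from the orientation of the corresponding
  graph edge), not per voxel, because reported CBFv values are per-vessel
  means. `truth_cos_theta_volume()` provides the phantom's exact values.
* The velocity field is kept signed; the sign encodes axial direction and
  drives vein/artery typing (`classify_vessel()`): arteries descend into
  the cortex, veins ascend. Magnitudes (`|v|`) are used for CBFv
  (`summarize_cbfv()`, which enforces the 3–10 ROI protocol).
* Branch order is assigned from graph topology — order 1 for pial
  mainstem edges (both endpoints within 50 µm of the surface), +1 per
  bifurcation away, capped at 3, veins capped at 2 (deeper venous branches
  are reported at the cap with a warning).

## Surface alignment

Imaging geometry tilts the cranial-window plane relative to the scan axes,
which would smear fixed-depth layers. `align_surface_plane()` detects the
surface in each (y, x) column as the first suprathreshold voxel (Otsu
threshold) that starts a run of at least `min_run = 5` bright voxels —
the run requirement prevents isolated noise voxels from mimicking a
surface, and a volume where more than 20% of columns have no such run is
rejected. A least-squares plane is fitted to the detected depths and the
volume is shear-resampled along z (linear interpolation) so the plane maps
to depth zero. Binary masks should be re-binarized at 0.5 after
resampling. On phantoms, a 5° applied tilt is recovered to better than
0.1° and layer metrics agree with the untilted reference within 5%.

## Vessel segmentation

`frangi_segment()` computes multiscale Hessian vesselness: at each scale
`σ` (defaults 4, 8, 16 µm — bracketing capillary-to-arteriole radii), the
volume is Gaussian-smoothed, the scale-normalized Hessian (`γ = 2`) is
formed by central differences with edge-clamped stencils (zero-padded
stencils create spurious responses at the volume faces), and its
eigenvalues `|λ₁| ≤ |λ₂| ≤ |λ₃|` enter the tubular response

    V = (1 − exp(−R_A²/2α²)) · exp(−R_B²/2β²) · (1 − exp(−S²/2c²))

for bright tubes (`λ₂, λ₃ < 0`), with `R_A = |λ₂|/|λ₃|` (plate vs line),
`R_B = |λ₁|/√|λ₂λ₃|` (blob), `S` the Frobenius norm, `α = β = 0.5`. The
structureness constant `c` is set to half the maximum `S` over **all**
scales: normalizing it per scale rescales the weak, spatially broad
response of mismatched scales up to full range and produces a halo around
every vessel. The response is maximized over scales and binarized at
`vesselness_threshold = 0.12` of the global maximum — chosen so that
noise-free tubes across the targeted radius range segment with Dice
0.92–1.00 while staying inside a 2-voxel-dilated envelope of the true
tube. Results are threshold-sensitive and the parameter is exposed;
vessels much larger than the largest scale are under-segmented (a
documented limitation, exercised in the tests).

`morph_denoise()` then applies a closing (spherical element, radius 1
voxel) and removes 26-connected components smaller than 27 voxels.

## Skeletonization and the vessel graph

`skeletonize()` implements 3D parallel thinning: per iteration, border
voxels are collected for each of the six face directions and deleted
sequentially when they are topologically simple — one 26-connected object
component in the punctured neighbourhood and one 6-connected background
component in the 18-neighbourhood — and not curve endpoints. Iteration
stops when the volume no longer changes; the result is a one-voxel-thick
skeleton that preserves each component's connectivity. Tube end caps erode
by roughly the tube radius, which is why skeleton-length checks carry a
few-voxel tolerance.

`build_graph()` turns the skeleton into nodes (voxels with ≠2 neighbours;
26-adjacent node voxels merge into one node at their centroid) and edges
(maximal degree-2 chains). Two cleanups keep the graph faithful to the
geometry rather than to thinning artifacts: terminal spurs shorter than 3
voxels are pruned (thinning burrs otherwise inflate bifurcation counts),
and through nodes left behind by pruning are dissolved into a single
merged edge. Self-loops shorter than 3 voxels are dropped with a warning;
longer cycles are legitimate edges.

**Path length.** Summing raw voxel-to-voxel steps overestimates the length
of a smooth curve by 5–10% (staircase bias), which would bias every
tortuosity upward. Edge lengths are therefore measured on a smoothed copy
of the centerline (centred moving average of the coordinates, window 5,
endpoints fixed). A straight digital line remains exactly straight under
this smoothing, so a straight branch has tortuosity exactly 1; a
semicircular tube phantom yields π/2 within 2%, and sinusoidal phantom
branches match their analytic arc/chord ratio within 3%.

**Layer metrics.** `layer_metrics()` reports, per 100-µm stratum from the
aligned surface (defaults L1–L5): vessel density (vessel voxels / layer
voxels), skeleton density (skeleton voxels / layer voxels), bifurcation
count (graph nodes of degree ≥ 3, counted once each regardless of degree —
degree-4 junctions are usually voxelization artifacts of two close
bifurcations), and bifurcation index per mm³ of full layer volume (the
denominator choice is a convention; tissue-only normalization would need a
tissue mask). Layers are half-open `[k·100, (k+1)·100)` µm so every voxel
belongs to exactly one layer. Densities are dimensionless voxel fractions;
no attempt is made to reproduce any instrument-specific "a.u." scaling.

## The phantom generator

`generate_vessel_tree()` is first-class, tested code, not a fixture: it
constructs the branch list (pial mainstems with a gentle dip so the
Doppler projection is non-degenerate, one diving vessel per mainstem
bifurcating at 240 µm depth into two children that terminate at 520 µm),
renders it as a union of tubes, and derives exact truth: graph topology
from construction, tortuosity from analytic arc length of the sinusoidal
centerlines, vessel density from rendered voxel counts, skeleton density
from compressed digital centerlines of the tube union (where sibling tubes
still overlap just below a bifurcation, their common segment is counted
once, matching what any centerline of the rendered union can contain), and
bifurcation depths from construction. Each tree owns a lateral corridor
and children split along x within it, so subtrees cannot collide and every
junction in the rendered volume is a constructed one. Defaults: 160×96×96
voxels at 4 µm isotropic (the in-plane/axial resolutions of the motivating
instrument differ by ~20%; one isotropic grid keeps the layer arithmetic
exact), 3 mainstems, radii 16/10/6 µm by order, velocities 1.0/0.8/0.5
mm/s, bend amplitude 3% of branch length.

The speckle generator (`simulate_lsci_stack()`) is an explicit statistical
stand-in, not a coherent-optics simulation: pixel intensities are drawn
from Gamma(M, M) with `M = 1 + c·flow`, the classic model of M averaged
speckle patterns, so local contrast follows `K = 1/√(1 + c·flow)`. The
prescribed input is the ideal ΔCBF(%) curve itself, which the generator
inverts through this model; only monotonicity and baseline-relative
behaviour are claimed, which is exactly what ΔCBF analysis consumes.
Defaults: 64×64-pixel frames at 1 fps, baseline flow 100 a.u., `c = 0.05`.

`simulate_feature_table()` draws two groups of Gaussian animals with
per-parameter Cohen's d; it emulates the statistical structure of an
animal-by-parameter panel (36 parameters by default), not any real
measurement correlations.

Passing phantom tests therefore shows the pipeline's operations are
correct on geometry and statistics it assumes (clean tubes, Gaussian
noise, gamma speckle, independent features); it does not establish
robustness to motion artifacts, shadowing, bulk phase drift, correlated
features, or capillary-scale incompleteness of real angiograms.

## LSCI reactivity

`spatial_contrast()` computes `K = sd/mean` over 5×5 windows per frame
(reflected edge padding; zero-mean or zero-variance windows are masked,
not propagated) and a relative perfusion index `1/K²` — a conventional
monotone mapping; since all downstream quantities are baseline-relative
percentages, any monotone convention gives the same ΔCBF up to
linearization error. `delta_cbf_trace()` pools an ROI harmonically
(`1/mean(K²)`), which inverts the pooled contrast once instead of
averaging noisy per-pixel reciprocals — per-pixel inversion is convex and
inflates responses by tens of percent at 25-pixel windows. The baseline
window is `[−5, 0)` minutes (half-open: the onset frame belongs to the
response) and traces average 5 ROIs by convention.

`cvr_metrics()` smooths the trace with a 1-minute centred moving average
(shrinking at the edges — substituting raw samples there would let a
single noisy frame define the peak). `ΔCBF_p` is the extremal smoothed
post-onset value (max for dilation, min for constriction). `t_P` is the
first time the smoothed trace enters the band `≥ 95%` of the plateau level
and the following 2 minutes stay there on average; the plateau level is
the median of the smoothed trace over the trailing 3 minutes, a robust
reference — referencing the band to the noisy maximum instead biases the
crossing late by up to minutes for slow responses. Band fraction, dwell,
smoothing width and tail window are all parameters; a trace that never
settles gets `t_P` at its extremum with a flag. `IR` integrates the raw
trace (trapezoid) from onset to the end of the recording, in %·min,
signed. On simulated stacks with known logistic responses (20 seeds,
96×96 frames, 5 ROIs), `ΔCBF_p` is recovered within 5% and `t_P` within
0.5 min of the analytic 95% crossing.

`correlation_mask()` reproduces the before/after stimulus masking: Pearson
correlation of each pixel's time course against a boxcar regressor, masked
at `|r| ≥ 0.5` by default.

## SVM biomarker scoring

`bootstrap_loocv_accuracy()` scores one parameter at a time (univariate,
matching per-parameter evaluation): each of 1000 bootstrap replicates
resamples animals with replacement — stratified within group, preserving
group sizes, to avoid single-class replicates (a non-stratified mode is
available) — then runs leave-one-out cross-validation over the n resampled
animals (n = 12 gives exactly 12 trials per replicate) with an RBF-SVM
(cost 1; features z-scored per training fold, so the kernel width 1 equals
the reciprocal feature variance). Each held-out animal scores 100 or 0;
the replicate accuracy is their mean, and the report carries the mean, SD
and percentile 95% CI over replicates. Resampling can and does place
duplicates of the test animal in the training fold; this optimistic bias
(null accuracy ~55% rather than 50% at 6 vs 6) is inherent to the
resampling design and documented rather than corrected. Single-class
training folds are skipped; zero-variance features report chance level
with a flag. `rank_parameters()` scores every column with the same seed
(duplicated columns give identical reports) and
`group_category_summary()` aggregates mean ± SEM per
vein/artery/microvasculature category.

## Statistics

`compare_groups()` runs Shapiro–Wilk per group and a two-tailed pooled
t-test; a normality failure (p < 0.05) sets a flag but does not substitute
another test, since no fallback is part of the design being mirrored. Its
empirical type-I error at n = 6/group is within [0.04, 0.06] over 10,000
null simulations. No multiple-testing correction is applied by default
(the mirrored design explicitly declines Bonferroni for small numbers of
correlated comparisons); `adjust_p_holm()` is available.
`required_sample_size()` uses the normal-approximation two-sample formula
`n = (z₁₋α/2 + z₁₋β)² (σ₁² + σ₂²) / Δ²`, which reproduces 4.7 animals per
group from the pilot CBFv statistics (0.675 ± 0.113 vs 0.495 ± 0.081 mm/s,
α = 0.05, power 0.80); a noncentral-t refinement (slightly larger n) is
available via `method = "t"`.

```{r power}
required_sample_size(0.675, 0.495, 0.113, 0.081)
```

## Problem sizes and determinism

The validation suite runs 160×96×96-voxel phantoms (5 seeds for
morphometry recovery), 20-minute 64–96-pixel speckle stacks (20 seeds for
CVR recovery), 1000-replicate bootstrap runs for classifier calibration,
and 10,000 null simulations for the t-test gate — sizes chosen so the
whole suite completes in a few minutes on one core while keeping
Monte-Carlo error well below every tolerance tested. All stochastic
stages take explicit integer seeds and are bit-reproducible at a fixed
seed.

## Known limitations

* Phase unwrapping, bulk-motion correction and any raw interferogram or
  coherent speckle physics are out of scope; inputs are assumed
  reconstructed and motion-free.
* Tube end caps shorten skeletons by about one radius; terminal branch
  lengths are slightly conservative.
* The 100-µm layer convention is geometric, not cytoarchitectonic.
* Absolute perfusion calibration from speckle contrast is not attempted;
  only baseline-relative quantities are reported.
* The bootstrap-LOOCV accuracy is optimistically biased by design (see
  above) and is a ranking statistic, not an unbiased error estimate.
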