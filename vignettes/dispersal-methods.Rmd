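---
title: "Models and measurements behind dispersim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurements behind dispersim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispersim)
```

# The scientific problem

Tumor cells deep inside solid tumors live in *ischemia*: oxygen and
nutrients are scarce and metabolic by-products such as lactic acid
accumulate. Gradient culture chambers recreate this situation ex vivo: a
metabolically active "consumer" monolayer generates a one-dimensional
gradient along the chamber axis, so a spheroid's distance to the chamber
opening (in mm) indexes how ischemic its microenvironment is. Imaging
along that axis shows that ischemic spheroids become protrusive, their
cells disperse, migrate more persistently, degrade more matrix, and see
less drug.

`dispersim` implements the quantitative half of that study design:

* **morphometry** — spheroid invasiveness, reporter ratios, local cell
  density, matrix-degradation scores, pH and drug-concentration profiles,
  and gradient-vs-distance fits;
* **trackstats** — single-cell migration statistics: speed, persistence,
  runner classification, mean-squared displacement (MSD) and its power-law
  exponent, and circular tests for directional bias;
* **cpm** — a two-cell-type cellular Potts model of a core/cortex spheroid
  in ECM that asks which cell-level changes suffice to disperse ischemic
  cells;
* **synthgen** — seeded generators for every input class, so the entire
  pipeline is testable without any imaging data;
* scenario orchestration with manifest-based reproducibility.

# Morphometry

## Invasiveness index

The index is the spheroid perimeter over the perimeter of the circle with
the same area, `P / (2 * sqrt(pi * A))` — the inverse of circularity. It
is 1 for a circle and grows with ruffling. Perimeter and area are taken
from the 0.5-level contour of the mask (marching squares via
`grDevices::contourLines()`) after a light Gaussian smoothing
(`smooth_sigma = 1.5` px). The smoothing matters: on a rasterized disk the
*raw* marching-squares polygon overestimates the perimeter by about 5%,
and naive pixel-edge counting by about 27%, both of which would break the
index-is-at-least-1 contract; with the default smoothing the measured
index of a radius-200 disk is 1.001 and a strongly ruffled analytic
boundary is recovered within 0.5%. Objects below `min_pixels = 16` are
rejected because contour perimeters are unstable below that size.

The index is invariant to translation and 90-degree rotation exactly, to
arbitrary rotation and uniform scaling within the ~2% discretization
error, and to the declared pixel size (it is dimensionless).

## Fluorescence ratios

Per-spheroid reporter levels (e.g. a hypoxia-response-element GFP reporter
against a constitutive membrane label) are background-subtracted means
over the mask: the background estimate is the *median* of all
outside-mask pixels, a robust choice left open by common practice; means
rather than integrated intensities are used, which makes the ratio
independent of spheroid size. The cleaved-collagen score is the same
ratio with the dequenched-collagen channel as numerator.

## Local density and its timecourse

Nuclei point clouds are triangulated (Delaunay) and each triangle
contributes a local density of one over its area; the per-image summary
is the mean. The triangulation is a Bowyer–Watson implementation built
into the package and is tested against a brute-force empty-circumcircle
enumeration. Collinear inputs are rejected as degenerate. Under a uniform
scaling of coordinates by *s*, densities scale as *s*^-2^, and triangle
areas always tile the convex hull. A radially dispersing point set
therefore shows a monotone decreasing mean density over frames, the
signature used to compare dispersing and static spheroids.

## Ratiometric pH

Extracellular pH is estimated from the green/blue intensity ratio of
media containing phenol red: as the medium acidifies the green channel
rises while blue stays flat. The ratio-to-pH mapping is calibrated on
titrated anchors and interpolated with a monotone piecewise-cubic
(Hyman-filtered) spline, which round-trips the anchors exactly and cannot
oscillate between them; the response has no published functional form, so
a monotone interpolant is the defensible minimal assumption. Queries
outside the anchor range are clamped and flagged rather than
extrapolated. Images are reduced to profiles in 0.5 mm distance bins
(configurable).

## Degradation scoring

For the fluorescent-gelatin assay the score is the fraction of mask
pixels whose sample intensity falls below `threshold_frac` (default 0.5)
of the co-registered reference intensity: degradation foci are local dark
spots, and the published material shows the spots without a numeric
cutoff, so the threshold is exposed as a parameter.

## Distance classes and gradient fits

Spheroids at most 2 mm from the opening are *proximal*, beyond 8 mm
*distal* (closed and open boundaries respectively, exactly as printed),
the rest intermediate. Metric-vs-distance relations are summarized by
ordinary least squares plus Pearson's correlation; two-group comparisons
use a two-tailed t test and three or more groups one-way ANOVA followed
by Tukey's HSD, the field's standard choices.

## Drug gradients

Fluorophore-conjugated Taxol stains microtubules, so staining intensity
proxies local drug level. Concentration is anchored at the source:
`c(d) = c0 * I(d) / I(0)`. The estimate is linear in `c0` and invariant
to intensity units; if noise breaks monotonicity the profile is projected
onto the nearest non-increasing one (isotonic regression) and flagged.
With `c0` = 150 nM and a bin at 30% relative intensity the estimate is
45 nM, the kind of value the method is meant to produce.

# Track statistics

Tracks are time-ordered (t, x, y) samples in minutes and micrometers at a
nominal cadence of 15 min (the generators default to 96 steps = 24 h).
Persistence is net displacement over path length: 1 for straight motion,
0 for a closed loop. *Runners* are cells whose net displacement reaches
50 um; the rule is inclusive ("50 um or more"), with a flag for the
strict variant, and a threshold sweep shows how conclusions depend on the
cutoff (the runner fraction is monotone non-increasing in it).

## MSD estimation and the exponent

The default estimator is the *time-averaged, pooled* MSD: every
admissible start time of every track contributes one pair at each lag,
and pairs are pooled across tracks. This is the convention that
stabilizes long-lag noise; an ensemble (from-origin) variant is provided
because it is unstated in most experimental reports which one was used.
The maximum lag is a quarter of the track duration — beyond that,
time-averaged estimates are dominated by a handful of long-lag pairs.
Tracks missing more than 10% of their frames are excluded from pooling;
tracks shorter than 6 frames cannot contribute the minimum 5 fitted lags.

The exponent alpha is the least-squares slope of log MSD vs log lag over
the first quarter of available lags (at least 5, each with at least 20
pairs). alpha = 1 is a random walk, 2 ballistic motion; an ensemble is
called superdiffusive when the lower bound of the bootstrap-over-tracks
confidence interval (200 replicates, 95% by default) exceeds 1. The
bootstrap resamples tracks, not pairs, because tracks are the independent
units. Coverage of the interval is checked against its nominal level on
diffusive fixtures in the test suite.

On synthetic ensembles the fits recover the analytic limits: ballistic
tracks give exactly 2, uncorrelated random walks give 1 within sampling
error at 900 tracks, and the persistent random walk (heading
decorrelating as `exp(-dt/P)`, so the turn SD per step is
`sqrt(2 dt / P)`) follows the classical Fuerth crossover
`MSD(t) = 2 v^2 P (t - P (1 - e^{-t/P}))` from ballistic to diffusive.

## Directional bias

Final displacement vectors are centered at the origin; angle 0 points
toward the chamber opening, which is the -x image direction by default
(configurable). Uniformity of the angles is tested with the Rayleigh
statistic `Z = n R^2` using the standard small-sample series correction
of the p-value (important here because per-spheroid track counts are
small), and, when displacement magnitudes are supplied, Moore's
rank-weighted variant with a Monte Carlo null. The test statistic is
validated against a 10^5-draw simulated null in the suite.

# The cellular Potts model

## Energy and dynamics

Cells are spin domains on a lattice; medium and ECM share the single
compartment M because the model's rules only distinguish cell-ECM
affinity. The Hamiltonian is the Graner–Glazier form

    H = sum over neighboring site pairs of J(tau_i, tau_j) [sigma_i != sigma_j]
      + lambda * sum over cells (v - V_T)^2

with contact energies J indexed by type (core C1, cortical C2, medium M)
over the 8-site Moore neighborhood (2nd order reduces lattice
anisotropy; a 4-neighbor option exists). Dynamics are spin-copy attempts
accepted with probability `min(1, exp(-dE/T))`. An attempt picks a random
*boundary* pair — site/neighbor draws are rejected until the two spins
differ — so the attempt budget is spent on sites that can actually
change; with uniform site sampling, the overwhelmingly common
interior-to-interior no-ops would make the prescribed attempt counts
essentially idle at this lattice size. One Monte Carlo step is accounted
as one copy attempt (an alternative sweep accounting is available by
flag, since published step counts do not always say which was meant).

Two guards keep the dynamics cellular: a cell may not lose its last site
(the model has no death or division), and an optional local-connectivity
rule refuses removals whose same-cell neighbors do not form one
contiguous arc of the 8-ring, preventing cell fragmentation. Connectivity
is off by default — the simplest Potts dynamics — matching the minimal
model the simulation mimics.

## Parameters

Absolute energies are package defaults chosen to satisfy the published
qualitative rules with mid-range contrast, then frozen:

| condition     | J(C1,C1) | J(C1,C2) | J(C2,C2) | J(C1,M) | J(C2,M) |
|---------------|---------:|---------:|---------:|--------:|--------:|
| baseline      |        8 |        8 |        8 |      16 |      16 |
| low_adhesion  |       16 |        6 |        4 |      16 |      16 |
| invasion      |        8 |        8 |        8 |      10 |      16 |
| combined      |       16 |        6 |        4 |       6 |      16 |

with `lambda = 1`, `V_T = 25` sites, `T = 8`. The low-adhesion rows
encode the E-cadherin loss of ischemic cells through
`J(C1,C1) > J(C1,C2) > J(C2,C2)`; the invasion rows raise the core
cells' relative ECM affinity, `J(C1,M) < J(C2,M)`. Two deliberate
asymmetries implement the observed synergy: in *invasion alone* the core
cells' ECM affinity approaches but does not beat their cell-cell
adhesion, so with intact adhesion they stay largely tissue-bound; in
*combined*, where adhesion is destabilized, ECM contact also becomes
cheaper than cell contact, and extrusion is additionally paid for by the
cortex healing behind the leaving cell at the cheap `J(C2,C2)` bond.
This is the model's statement of why each perturbation alone is
inefficient but their combination disperses the core.

Initialization lays cell seeds on a sunflower spiral filling a disk of
area `n_cells * V_T`, assigns lattice sites by a capacity-balanced power
diagram (so initial volumes sit within a few sites of `V_T`), and types
the innermost `core_fraction` (default 0.3) of cells C1. The lattice
boundary is fixed (no wrap); a warning fires if any cell ever touches it.

Two scales are built in: the *full* preset (200 x 200 lattice, 100
cells, 1.28e8 attempts) mirrors the published run geometry; the *desk*
preset (100 x 100, 25 cells, 2e6 attempts, snapshots every 2e4 attempts)
is the routine scale used by the test suite and the acceptance script,
chosen so a full four-condition, ten-seed comparison completes in
minutes on one CPU.

## Metrics and what the desk scale can and cannot show

Snapshots yield per-cell centroid tracks, the total energy, a *mixing
index* (fraction of heterotypic cell-cell contacts normalized by its
expectation under random type assignment, `2 n1 n2 / (n (n-1))`; sorted
layouts score well below 1, checkerboards above 1), and an *ECM-invasion
fraction* (volume of each type outside the initial cluster footprint
dilated by 2 sites). Because single-snapshot values of these metrics are
noisy in a 25-cell system, per-run summaries average the invasion
fraction over the last quarter of snapshots and the mixing index over the
whole trajectory (the latter is deliberately rate-sensitive: active
mixing and slow neutral drift end in similar states but differ in how
fast they get there). Across ten seeds the summary means reproduce the
qualitative ordering: combined invades most, invasion-alone modestly,
low-adhesion mixes without invading, baseline does neither.

The centroid-track MSD deserves honesty. At the desk snapshot cadence
(2e4 attempts, about 2 sweeps, per frame) consecutive centroid
displacements are dominated by interface fluctuations that partially
revert between frames, so short-lag fits of pooled core-cell tracks give
exponents below 1 even in the combined condition, whose cells visibly
disperse; the directed component of their motion (a few lattice sites
per escape, spread over tens of frames) is small against that
fluctuation floor at the fitted lags. Superdiffusive fitted exponents
emerge only for freely translocating cells observed at cadences beyond
the interface-relaxation time — a regime the desk preset's prescribed
cadence does not reach. The package reports what the fit measures,
including the bootstrap interval, rather than forcing the expected
value; `simulated_msd()` also flags (instead of fitting) genuinely
frozen dynamics.

# The synthetic generators

Every generator is deterministic in (spec, seed) — bit-identical output,
restoring the caller's RNG state — and each models the minimal
statistical structure the analysis consumes:

* **Spheroid masks** — star-convex boundaries
  `r(theta) = R (1 + A sum_k sin(k theta + phi_k))` with seeded random
  phases: a disk at `A = 0`, ruffled and protrusive at larger `A`. Not
  modeled: texture, holes, multiple touching spheroids.
* **Nuclei clouds** — jittered regular grids of controllable density. Not
  modeled: clustering, intensity, segmentation errors.
* **Tracks** — brownian, ballistic, persistent (Fuerth) and biased
  random walks at the study cadence (15-min frames, 24 h). Not modeled:
  measurement noise on positions, track fragmentation, cell division.
* **Gradient images** — a flat denominator channel and a numerator whose
  per-column ratio follows a requested monotone profile, repeated along
  the short axis because the chamber gradient is one-dimensional, plus
  i.i.d. Gaussian noise. Not modeled: vignetting, photobleaching.
* **Decay profiles** — exponential concentration-equivalent intensity
  curves for drug-gradient estimation.

Passing tests on these fixtures demonstrates that the estimators recover
known structure under controlled noise; they cannot certify performance
on real images, where segmentation quality, illumination artifacts and
tracking errors dominate and are explicitly out of scope (tracks are
consumed, not produced).

# Numerical choices and degenerate inputs

* Errors are classed conditions (`invalid_spec`, `format_error`,
  `geometry_error`, `fit_error`, `degenerate_signal`, ...) so callers can
  distinguish bad inputs from bugs.
* Delaunay ties (cocircular quartets, e.g. exact grids) are broken by
  insertion order; both diagonals give identical triangle areas, which is
  what the densities use.
* The calibration spline requires strictly monotone anchors and clamps
  out-of-range queries with a flag.
* MSD fits refuse non-positive MSD values (frozen dynamics) and lags with
  fewer than 20 pairs.
* `max.col` ties in the initializer are broken deterministically;
  everything downstream of a seed is bit-reproducible, and scenario runs
  write a manifest (config, package version, seed) sufficient to
  reproduce every artifact.

# Known limitations

* The Potts model is passive: no chemotaxis (gradients were concluded not
  to orient migration in this system), no active polarity, no division or
  death. Its MSD exponents at the desk cadence sit below the
  superdiffusive regime, as discussed above.
* The pH estimator assumes the denominator channel is insensitive to the
  quantity of interest; real phenol-red imaging needs per-batch
  calibration anchors.
* The invasiveness index is computed on single 2D masks; whether a
  maximum-intensity projection or a single plane feeds it is the caller's
  choice, and values from the two are not comparable.
* Per-spheroid fluorescence uses mean intensities (an assumption, flagged
  in the documentation); integrated intensity would weight spheroid size.
* The chimeric labeling ratio used to make tracks sparse is exposed as a
  parameter rather than fixed, since reported values differ between 1:10
  and 1:4.
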