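---
title: "Validating short white-matter tracts on synthetic diffusion phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating short white-matter tracts on synthetic diffusion phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lifetract` reproduces, on fully synthetic data with known ground truth,
the analysis chain used to identify a short association tract and to
quantify the statistical evidence for its existence. This vignette
explains the models, the parameters that matter, the phantom's design,
and the numerical choices — including their limitations.

## The scientific problem

A streamline connecting two cortical regions is a hypothesis, not a
finding: probabilistic tractography produces large numbers of candidate
trajectories, many of which are artefacts of crossing fibres or
parameter choices. Two ideas turn candidates into evidence:

* **Ensemble tractography** generates candidates under several
  curvature regimes (here, angular thresholds of 5.7°, 11.5°, 23.1° and
  47.2° per 0.2-mm step), because no single setting reconstructs both
  straight and tightly curving tracts well.
* **Linear fascicle evaluation (LiFE)** keeps only streamlines that
  help predict the measured diffusion signal, and supports a
  cross-validated *virtual lesion* test: remove the candidate tract,
  re-optimise what remains, and ask whether prediction in the tract's
  voxels got worse.

## The forward model and the LiFE fit

Diffusion-weighted attenuations are predicted per streamline segment by
a stick model: a segment with unit tangent $t$ contributes
$\exp(-b\,d_a (\theta \cdot t)^2)$ for gradient direction $\theta$ at
weighting $b$, with $d_a = 1.7\times10^{-3}\,\mathrm{mm^2/s}$ by
default. A streamline's contribution to a voxel is the mean over its
segments there; contributions and measured attenuations (signal over
mean $b=0$ signal) are demeaned across each voxel's diffusion-weighted
directions, which removes the isotropic component that streamlines
cannot explain. Weights solve the non-negative least-squares problem
$\min_{w \ge 0} \tfrac12\|y - Mw\|^2$.

The solver is cyclic coordinate descent with an active-set acceleration:
each coordinate update is the exact one-dimensional constrained
minimiser, so the objective is non-increasing; full passes over all
columns alternate with cheap passes over the currently supported
columns. Convergence is declared when the relative objective decrease
over a full pass falls below `tol`. Small problems (the test suite's
30×10 oracle comparisons) are run at `tol = 1e-12` and agree with
exhaustive active-set enumeration to 1e-6. At pipeline scale (thousands
of strongly collinear columns) the coordinate-descent tail is slow, so
the cohort driver uses `tol = 1e-4` with a 1,000-pass cap; empirically
this lands within ~1–2% of the objective of an 8,000-pass run and does
not change which streamlines carry weight appreciably — the quantities
downstream (predictions, $R_{rmse}$, $S$) depend on the fit only through
$Mw$, which converges much faster than the individual weights.

## $R_{rmse}$ and the strength of evidence

The data are split into two sessions; all fitting uses session 1.
Per voxel,
$$R_{rmse} = \frac{\mathrm{RMSE}(\text{model prediction},\ y_2)}
                  {\mathrm{RMSE}(y_1,\ y_2)},$$
so 1 means the model predicts the held-out session exactly as well as
the measurement replicates, and the statistic is invariant to global
signal scaling. Voxels with a test–retest denominator below $10^{-12}$
(possible only in noise-free simulations) are excluded and flagged; a
noise-free run therefore reports a *degenerate* subject rather than a
spurious statistic.

A virtual lesion removes the bundle's columns, re-optimises the
remaining *path neighbourhood* (all nonzero-weight streamlines through
the bundle's voxels) on those voxels only, and compares the two
$R_{rmse}$ distributions:
$$S = \frac{\overline{R}_{lesioned} - \overline{R}_{unlesioned}}
           {\sqrt{(\mathrm{var}_l + \mathrm{var}_u)/2}}.$$
The pooled-SD denominator is our reading of the "joint standard
deviation" in the LiFE literature. The restricted refit (path
neighbourhood × lesion voxels, warm-started from the unlesioned weights)
matches the description of the procedure and keeps the lesion test
cheap; a full-connectome refit would answer a slightly different
question and is not attempted.

Desk-scale magnitudes deserve a caveat: with ~500 lesion voxels and
thousands of streamlines, $S$ on the phantom is of order 1–2, not the
tens reported for human connectomes with millions of candidates — the
statistic grows with data volume. What the package establishes is the
*behaviour*: $S > 0$ for the essential bundle, stable in sign across
seeds; $S = 0$ exactly when the lesioned streamlines carry no weight;
and $S \approx 0$ when every bundle streamline has a duplicate, because
redundant evidence transfers to the copies.

## The phantom

The phantom is a 30³ grid of 2-mm isotropic voxels (configurable)
holding:

* a **U-shaped target bundle** — a semicircular arc (radius 13 mm) with
  short straight tails in the x–z plane, tube radius 3 mm, arc length
  ≈ 48.8 mm, chosen so the segmented bundle's mean length lands near
  the 4.7-cm scale typical of short parietal association tracts. Its
  ends terminate inside two grey-matter ROI spheres
  ("superior-parietal-like", "supramarginal-like");
* a **straight distractor bundle** crossing the U at its apex at ~90°,
  with its own pair of distractor ROIs — the analogue of a large
  fasciculus crossing the tract of interest;
* **isotropic background** with free-water diffusivity.

Per voxel, fibre volume fractions are the share of 27 within-voxel
subsamples falling inside each tube (a subsample in the overlap of two
tubes counts for the nearer centerline only, so fractions sum to at most
the within-tube fraction of 0.8); orientations are the tangent of the
nearest centerline point. The noiseless signal is the standard
multi-compartment stick/ball model
$$S = S_0\Big[f_{iso}e^{-b d_{iso}} + \sum_k f_k
      e^{-b(d_r + (d_a - d_r)(\theta\cdot t_k)^2)}\Big]$$
with defaults $d_a = 1.7\times10^{-3}$, $d_r = 0.2\times10^{-3}$,
$d_{iso} = 3.0\times10^{-3}\,\mathrm{mm^2/s}$ and $S_0 = 100$ — typical
white-matter and free-water literature values. Rician noise adds two
independent Gaussian channels in quadrature, independently per session;
the test suite verifies the between-session RMSE against the analytic
Rician moments. The default noise scale is $\sigma = 2$ (2% of $S_0$,
i.e. $b=0$ SNR 50, an averaged-acquisition regime); the suite sweeps
$\sigma \in \{0.5, 1, 2\}$ and checks that orientation-recovery error
grows with noise. The acquisition is single-shell: 64 directions at
$b = 1000\,\mathrm{s/mm^2}$ plus two $b=0$ volumes, two sessions.

What the phantom does **not** emulate: cortical folding (ROIs are
spheres, the "sulcus" is only implied by the U-geometry), susceptibility
and eddy artefacts, spatially varying SNR, partial-volume grey matter,
and multi-shell acquisitions. Passing tests show the pipeline's
operations are implemented correctly and behave sensibly under
controlled signal structure — not that the pipeline would produce
identical numbers on human data.

## Local models

The diffusion tensor is fitted by log-linear least squares (signals
clamped at $10^{-6} S_0$ before the log), giving FA and the principal
diffusion direction. The single-fibre response for CSD is estimated from
voxels with FA ≥ 0.7 (at least 20 required): attenuations are expressed
as a function of the angle to the voxel's PDD and projected onto
even-degree zonal harmonics; with too few high-FA voxels the analytic
stick response is substituted with a warning.

CSD solves a regularised linear deconvolution per voxel with iterated
non-negativity constraints: an unconstrained fit restricted to degrees
≤ 4 initialises the FOD; sphere directions whose amplitude falls below
0.1 × the mean initial amplitude are penalised (weight 1.0) and the
constraint set is iterated to stability (cap 50, non-convergence
returns the last iterate with a flag). The spherical-harmonic basis is
real, even-order, orthonormal, with degrees ascending and orders
$-l,\dots,l$ within each degree; all antipodal symmetry is inherited
from the even-order restriction. The dense direction set everywhere
(constraints, peak finding, tracking) is a 642-vertex subdivided
icosahedron — centrally symmetric and nearly uniform. Peaks are local
maxima over that tessellation refined by a shrinking spherical-cap
search (final resolution ~0.15°), merged below 25° separation, and
dropped below 0.25 of the voxel's largest peak (this cutoff also
suppresses truncation sidelobes of sharp lobes, which reach ~15% of the
main lobe at lmax = 8).

## Tracking

Streamlines grow bidirectionally from uniform points inside randomly
chosen seed voxels of the grey/white interface mask. At each step the
next direction is drawn from the tessellated FOD amplitudes within the
cone of the angular threshold about the incoming direction, with
probability proportional to amplitude (trilinear interpolation between
voxels); the first direction is drawn from the full sphere. A half
terminates when the proposed point leaves the white-matter mask (the
exit point is kept — that is how endpoints come to lie at the
grey-matter interface, which the 3-mm endpoint rule then exploits), when
no in-cone direction reaches the stopping amplitude 0.1, or when the
200-mm length budget is exhausted; streamlines under 10 mm are
discarded. "Outside the mask" is evaluated at the nearest voxel.
Identical seeds give bit-identical tractograms; every tractogram records
its full parameter set and seed in provenance.

Both the 10-mm tracking minimum and the later 15-mm segmentation filter
are applied where each is specified; no harmonisation is attempted.

## Segmentation, endpoints, atlas

Endpoint segmentation tests *terminal points only* against the two ROIs
(within 3 mm of a voxel center, Euclidean in mm): passing through an ROI
does not count. Outlier removal applies the minimum-length rule first
(degenerate fragments would corrupt the SD statistics), then the
3-SD length rule, then the 3-SD position rule, each on the statistics of
the set entering that step; the position rule resamples streamlines to
100 equidistant nodes, flips each so its first node is nearer the
centroid of current first endpoints (a registration-free node
correspondence), and measures mean node distance to the mean streamline.
Bundles with fewer than 3 members skip the SD rules with a warning.

Endpoint density counts both terminal points of every streamline within
3 mm of each grey voxel; proximity reports the proportion of ROI voxels
within 3 and 4.5 mm of any endpoint (monotone in the threshold by
construction). Visitation maps resample streamlines to half-voxel
spacing before nearest-voxel assignment so the visited set is
26-connected along the course. Normalisation to a template grid is
affine-only with nearest-neighbour interpolation (binarity preserved;
registration estimation is out of scope — the cohort driver jitters each
subject by a known ±1 mm translation to exercise this path). The
percentage-overlap atlas takes values on the lattice
$\{0, 100/n, \dots, 100\}$ and the display threshold is a strict
"greater than 25%".

## The cohort driver and problem sizes

`run_config()` surfaces every stage parameter with the study settings as
defaults. Candidate counts are configuration, not constants: the
package default is 5,000 streamlines per angular setting with a top-500
preselection per single-parameter connectome (the full-scale analysis
this emulates used 2,000,000 and 150,000; the 4 × preselection
structure is identical). Per-subject seeds derive from the master seed
as `master_seed + 7919 * subject_index`; each "hemisphere"/subject is an
independent phantom instance. The test suite runs reduced sizes
(600–1,500 streamlines per setting) for most properties and the full
default scale in the end-to-end acceptance block; the vignette's sizes
were chosen so a six-subject cohort completes in a few minutes on one
CPU core.

## Known limitations

* The stick prediction in LiFE shares one axial diffusivity across all
  streamlines; fanning, dispersion and axon-diameter effects are out of
  scope, as are multi-shell prediction models and tensor-factorised
  LiFE accelerations.
* $S$ magnitudes are desk-scale (see above); only sign and ordering
  properties are asserted.
* TRK support is read-only; TCK is the canonical streamline format.
* The phantom's grey matter is a label volume, not a surface; endpoint
  analyses are volumetric by design.
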