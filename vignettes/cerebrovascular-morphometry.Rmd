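---
title: "Cerebrovascular segmentation and morphometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebrovascular segmentation and morphometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerevasc)
```

# Overview

`cerevasc` quantifies structural change in the cerebral vasculature from
3-D time-of-flight MR angiography (TOF-MRA): it delineates the vascular
tree with a two-stage segmentation, summarizes vessel caliber through the
distance-map radius distribution and vessel tortuosity through surface
curvature, and relates those imaging markers to mean arterial pressure
(MAP) with random-intercept mixed models. Because flowing blood is bright
on TOF-MRA, the entire pipeline is built around a bright-tubular-structure
model of the vasculature.

This vignette records the package's scientific assumptions, the tunable
parameters and their defaults, the numerical choices that were genuinely
open, and what the synthetic phantom validation does — and does not — show
about real MRA data.

# Preprocessing

## Bias-field correction

MRA volumes carry a smooth multiplicative intensity inhomogeneity (coil
sensitivity, slab effects). `correct_bias()` estimates a strictly positive
multiplicative field by iterative wide-kernel Gaussian smoothing of the log
intensities over a *tissue band* — the middle class of a two-threshold Otsu
split — using normalized convolution, and divides it out. Restricting the
estimate to the tissue band matters: brain tissue is the one nominally
homogeneous compartment, so its residual low-frequency variation *is* the
field, whereas vessels, skull fat and background would masquerade as
inhomogeneity. The band is lightly eroded before use so partial-volume
voxels at its edge cannot destabilize the estimate.

Parameters:

* `fwhm_frac` (default **0.4** of the grid extent): the kernel FWHM. Much
  narrower kernels start absorbing anatomy into the field; at 0.25 of the
  extent the estimate is no longer reproducible — re-correcting an already
  corrected volume changes the field estimate by more than 1% RMS, while at
  0.4 the second-pass field is within 0.7% RMS of unity on the phantoms and
  recovery of a known linear field reaches Pearson r ≈ 0.998. That
  reproducibility argument fixed the default.
* `n_iterations` (default 3): estimate-and-remove passes.

The field is gauge-fixed to mean 1 over the estimation band, so overall
intensity scale is preserved.

## GGMRF homogeneity enhancement

`ggmrf_smooth()` runs iterated-conditional-modes (ICM) sweeps of a
generalized Gauss–Markov random field energy over the 26-neighborhood: the
update at voxel *s* replaces its level by

$$\hat q_s = \arg\min_{\tilde q_s}\;
|q_s - \tilde q_s|^{\alpha} + \rho^{\alpha}\lambda^{\beta}
\sum_{r \in v_s} \eta_{s,r}\,|\tilde q_s - q_r|^{\beta},$$

with $\eta_{s,r} = 1/\sqrt{d}$ for squared voxel distance $d$. Defaults:
$\lambda = \rho = 1$, $\alpha = 2$ (Gaussian data prior), $\beta = 1.01$,
five sweeps. $\beta$ near 1 preserves abrupt edges — vessel walls — while
still flattening noise; $\beta = 2$ smooths aggressively and visibly erodes
edge contrast. Notably, at $\beta = 1.01$ a clean two-level step edge is an
exact fixed point of the update: the neighborhood pull cannot overcome the
quadratic data term, which is precisely the edge-preservation property the
parameter is meant to deliver.

Two implementation details guarantee correctness and speed. First, the
package defines the global energy with the pairwise term counted once per
unordered neighbor pair, so the per-voxel update above accounts exactly for
every pair involving *s* and sequential ICM descent is provably monotone in
`ggmrf_energy()`. Second, the candidate search is exhaustive over gray
levels but prunes, without loss of exactness, to the interval spanned by
the datum and its neighbors: any candidate outside that interval is
dominated term-by-term by the nearest interval endpoint. The test suite
verifies single-update equality against a brute-force scan of all 256
levels.

## Skull stripping

Extracranial fat and bone share the bright appearance of vessels and must
be removed before intensity-based classification. `strip_skull()` is a
deliberately simple, topology-preserving procedure: threshold the head from
the background (lower split of a three-class Otsu), apply a one-voxel
opening (erosion, then geodesic re-dilation constrained to the head mask)
so that thin halo chains of partial-volume voxels cannot bridge the brain
to the marginal shell, take the face-connected component containing the
deepest interior voxel (the maximum of the head's Euclidean distance map),
and fill enclosed holes. The result is a single connected brain mask. The
opening step earns its keep: edge-preserving smoothing drags background
voxels adjacent to bright structures upward, and a chain of two or three
such voxels is otherwise enough to annex the entire skull shell into the
brain.

# Two-stage vessel segmentation

## Global stage: LCDG intensity model and Bayesian classification

The marginal gray-level density of brain voxels is modeled as a linear
combination of discrete Gaussians (LCDG): two dominant positive components
for the non-vessel tissue and the (much smaller) vessel class, plus up to
four positive and four negative subordinate components that absorb the
deviation between the empirical density and the dominant pair. Each
discrete Gaussian is the unit-bin integral of a normal CDF with the
boundary bins absorbing the tails, so every component sums to exactly one
over the gray range.

`fit_lcdg()` proceeds in three stages: dominant-pair EM (initialized at the
Otsu split), alternating-sign residual modeling (component count chosen by
residual-error reduction, capped at four per sign), and a modified-EM
refinement of all parameters. Refinement responsibilities are computed as
proportions of the *unsigned* mixture, which sum to one at every gray level
and keep the weight updates bounded where positive and negative components
nearly cancel; after every proposal the weights are clipped non-negative
and rescaled to the signed-mixture constraint (positive weights minus
negative weights equal one), and a damping line search rejects or halves
any step that would decrease the log-quasi-likelihood. The recorded
likelihood trace is therefore monotone by construction, and non-convergence
within `max_iter` is flagged on the returned model rather than silently
ignored.

Classification is Bayesian: a voxel is vessel iff
$P(v)\,p(q\mid v) \ge P(O)\,p(q\mid O)$, with class conditionals assembled
from the components allocated to each class (largest dominant mean anchors
the vessel class — the TOF bright-blood convention — and each subordinate
joins the nearer dominant mean), clipped at zero and renormalized since
signed mixtures can dip locally below zero. One guard proved essential: in
the valley between the two modes the clipped non-vessel density can vanish
exactly, letting the vessel class "win" at gray levels far below any
vessel. The decision is therefore closed upward from $q^\ast$, the lowest
level from which the vessel class wins contiguously through its own mode,
making the rule monotone in intensity; for well-separated equal-variance
classes with equal priors this reproduces the closed-form midpoint
boundary.

## Local stage: adaptive threshold refinement

The global boundary, pushed upward by the small vessel prior, misses dim
small vessels and smoothing-attenuated vessel boundaries. The refinement
stage recovers them with local spatial context: each axial slice of the
current vasculature is split into 8-connected components; around every
component an adaptive window (bounding box dilated by
`max(5, 0.5 × largest side)` voxels, spanning the previous and next slice)
defines a local separation threshold $T = (\mu_b + \mu_o)/2$ from the mean
intensities of vessel-labeled and other voxels in the window; seed voxels —
unlabeled, at or above $T$, with 26-neighborhood maximum contrast above
$\mu_o$ by more than a quarter of the class separation — mark likely missed
vessels; and a 26-connected region growth from the current mask plus seeds
accepts voxels meeting the locally applicable threshold (minimum $T$ over
covering windows; the global Bayesian boundary elsewhere). Rounds repeat
until no voxel is added (at most `max_rounds = 5`; growth is add-only, so
termination is guaranteed and the final mask always contains the initial
one).

Two choices in this stage are our concrete instantiation of an
under-specified algorithm and are exposed in `refine_config()`: the window
margin rule above, and a per-window floor on the *effective* acceptance
level at $\mu_o + 2\,\mathrm{sd}_o$. The floor prevents a failure mode seen
during validation: a window whose "vessel" voxels are actually
false positives barely above local tissue would otherwise set a low $T$ and
erode into tissue, recruiting more windows each round. $T$ itself is always
reported as the exact class-mean midpoint. When a brain mask is supplied,
no voxel outside it is ever added — skull stripping precedes segmentation.

# Vascular features

## Caliber: distance map, medial radii, CDF

`distance_transform()` computes the exact anisotropy-aware Euclidean
distance (Felzenszwalb's separable algorithm) from each foreground voxel
center to the nearest background voxel center, so a one-voxel-wide vessel
reads ≈ one spacing unit — the stated convention for all radius values.
Radii are sampled at the distance-ridge medial axis (foreground voxels
whose distance value is not exceeded by any 26-neighbor), the standard
local-radius estimator for tubes; an `all_voxels` flag samples every
foreground voxel instead for sensitivity analysis. `radius_cdf()` returns
the empirical CDF and the median radius (midpoint convention for even
sample sizes); the radius at which the CDF saturates summarizes the caliber
of the whole tree and supports within-subject temporal comparison.

## Tortuosity: surface curvature

The vessel surface is extracted at iso-value 0.5 from the binary mask after
a light Gaussian smoothing (σ = 0.5 voxel — raw binary iso-surfaces carry
staircase artifacts that make finite-difference curvature meaningless,
while stronger smoothing would erase sub-voxel vessels entirely). Marching
is done over the Kuhn six-tetrahedra decomposition of each cell: it has no
ambiguous cases, the induced face diagonals agree between neighboring
cells, and edge-keyed vertex welding therefore yields a watertight,
consistently outward-oriented triangulation. Extracted vertices then
receive 15 Taubin smoothing passes (λ = 0.5, μ = −0.53), which suppress
lattice jitter with negligible shrinkage.

Per-vertex normals are area-weighted averages of incident triangle normals,
regularized by 30 one-ring averaging passes: the finite-difference normal
curvature $k_{ij} = e_{ij}\cdot(n_j - n_i)/\lVert e_{ij}\rVert^2$ divides a
normal difference by an edge length, so normal noise of a few degrees
otherwise swamps curvatures of order 1/R. The sign convention makes a
convex surface with outward normals positively curved (a sphere of radius
R has H = 1/R, K = 1/R²). For each vertex the tangent-projected directions
and sampled normal curvatures are fitted by least squares to Euler's
relation $k(\theta) = k_1\cos^2\theta + k_2\sin^2\theta$ — equivalently the
second fundamental form — yielding principal curvatures $k_1 \ge k_2$, the
principal direction, mean curvature $H = (k_1+k_2)/2$ and Gaussian
curvature $K = k_1 k_2$ (so $H^2 \ge K$ identically). Sampling uses the
two-ring by default: on lattice-extracted meshes the one-ring's short edge
baselines leave the estimates noise-dominated, and the longer two-ring
baselines cut the Gaussian-curvature error on an R = 8 voxel sphere from
>10% to ≈8%; the "one-ring when it has at least four members" rule remains
available via `ring = "one"`. The residual errors (sphere: H ≈ 3%, K ≈ 8%;
cylinder: H ≈ 7–9%) are dominated by the half-voxel placement of the
digital surface, not by the estimator.

Tortuosity summaries per section are the medians and means of H and K over
vertices and the area-weighted surface integral of |K| (per-vertex area =
one third of incident triangle areas); on a closed convex surface the
latter recovers the Gauss–Bonnet value 4π to within a few percent. Medians
are the robust markers: means can be dominated by a handful of
extreme-curvature vertices on the thinnest vessels. The mean of H is, to
first order, invariant to gentle bending of a tube (the inner- and
outer-wall contributions cancel area-weighted), so the discriminating
tortuosity signals are the |K| integral and, for bends strong enough to
flip the sign of H on the inner wall (curvature × radius > 0.5), the mean
of |H|.

## Sections

The circle-of-Willis plane cannot be located without anatomy, so the
lower/upper split is a configurable axial fraction of the brain mask's
extent (`z_fraction`, default 0.5; lower = at-and-below). The two sections
partition the vasculature exactly.

# Statistical stage

`compute_map()` implements MAP = (2·DBP + SBP)/3 exactly.
`fit_map_association()` fits MAP ~ feature + (1 | subject) by full maximum
likelihood (not REML — the likelihood-ratio test compares fixed-effect
structures) and reports the χ²(1) statistic against the intercept-only
model with the same random intercept, the p-value, and the coefficient
sign. A singular random-effects fit is flagged and falls back to ordinary
least squares, never silently. Bare p-values are reported without
multiple-testing correction, matching the presentation of the source
framework; the χ² statistic is invariant to affine rescaling of the
feature.

`simulate_cohort()` generates the repeated-measures cohort used for
calibration: per-observation feature values, a per-subject random intercept
shared across timepoints (SD 5 mmHg), and MAP generated from the fitted
model's own structure, `MAP = 92.5 + effect·z + b_subject + ε` with
`effect` in mmHg per feature SD and residual SD 3 mmHg; systolic/diastolic
readings are reconstructed from a plausible pulse pressure so the MAP
identity holds exactly, and values span roughly 75–110 mmHg. The generative
direction was chosen to match the fitted model because the stated
calibration conditions (a 5 mmHg-per-SD effect with a 3 mmHg residual)
are unreachable when the feature is generated *from* MAP — in that
direction the recoverable effect per feature SD is bounded by the
within-subject MAP spread. Calibration at n = 15 subjects × 2 timepoints:
type-I error of the LRT ≈ 0.05–0.09 at α = 0.05 (the LRT is mildly
anticonservative at this sample size), power ≈ 1 at the stated effect, and
slope recovery bias < 1%.

# The synthetic phantom: what it emulates, and what it does not

`phantom_spec()`/`generate_phantom()` build seeded 3-D phantoms with exact
ground truth: smoothed random-walk centerlines (tortuosity controlled by a
single amplitude knob; zero amplitude gives straight segments) with
per-point radii in a configurable range, rasterized by exact
point-to-segment distance (so rasterized radii match requested radii — no
skeleton dilation), embedded in an ellipsoidal tissue compartment on a dark
background with an optional bright marginal shell, degraded by a low-order
polynomial multiplicative bias field and additive Gaussian (optionally
Rician) noise, quantized to 8 bits. Defaults — class means 200/90/30 with
SDs 12/10/8 gray levels, noise SD 5, ±15% bias, radii 0.75–3 voxels, eight
vessels, shell on — were chosen once as a plausible TOF-MRA contrast
configuration; the source data's actual intensity distributions are not
published, so these are plausibility choices, not calibration. Centerlines
are confined so that the full tube stays inside the tissue compartment,
and the shell is separated from it by a CSF-like gap wider than a voxel
diagonal, mirroring real anatomy where skull and brain do not touch.

The phantom deliberately omits MRA physics: no flow-related enhancement,
no slab-boundary artifacts, no partial-volume intensity mixing (each voxel
is drawn from exactly one class), and vessel intensity does not depend on
vessel caliber as it does in real TOF. Consequently the near-perfect
phantom Dice scores (≈ 0.99+ at the defaults, against the acceptance floor
of 0.90) say that the pipeline's logic is correct under its stated
intensity model — they do not predict the ≈ 0.92 Dice reported on real
patient data, where partial volume and flow effects dominate the error
budget. The phantom's role is falsification of the machinery (does
refinement strictly improve on the global stage? are radii and curvatures
recovered?), not performance forecasting.

# Problem sizes used in the shipped validation

The test suite and acceptance script run ten phantoms of 64³–96³ voxels
for segmentation, 48³ phantoms for the 14-volume two-timepoint cohort,
R = 8 spheres and r = 4 cylinders for curvature, 20 simulated histograms
(10⁵ draws each) for LCDG recovery, and 1000/200 replicates for the
type-I/power calibration — sizes chosen so the whole validation completes
in a few minutes on a single core while every check retains its
discriminating power.

# Known limitations

* The LCDG refinement maximizes a quasi-likelihood on a signed mixture;
  the damped modified EM is guaranteed monotone but not guaranteed to find
  the global optimum, and the component-to-class allocation (largest mean →
  vessel) is a convention the source text leaves open.
* The distance-ridge medial axis is not a homotopy-preserving thinning; for
  tangent or overlapping vessels the radius sample can include junction
  voxels with inflated radii.
* Curvature means (as opposed to medians) are sensitive to the thinnest
  resolved vessels; treat `mean_H`/`mean_K` with care on trees containing
  sub-voxel calibers.
* The axial section split is a geometric stand-in for the circle-of-Willis
  plane and should be re-parameterized when anatomy is available.
* Skull stripping is validated on the phantom's shell geometry only; real
  T1-weighted-style stripping (deformable surfaces, atlases) is out of
  scope.
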