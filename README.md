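# cerevasc

Quantifying cerebrovascular structural change from 3-D time-of-flight MR
angiography (TOF-MRA), for imaging scientists studying the vascular
correlates of elevated blood pressure. Chronically elevated cerebral
perfusion pressure is hypothesized to remodel the cerebral vasculature —
narrowing vessels and increasing their tortuosity — *before* systemic
hypertension manifests. `cerevasc` implements an end-to-end framework to
measure that remodeling:

1. **Preprocessing** — multiplicative bias-field correction, edge-preserving
   generalized Gauss–Markov random field (GGMRF) smoothing over the
   26-neighborhood,

   q̂ₛ = argmin over q̃ₛ of |qₛ − q̃ₛ|^α + ρ^α λ^β Σ_{r∈vₛ} η₍ₛ,ᵣ₎ |q̃ₛ − qᵣ|^β,

   and a simplified topology-preserving skull strip.
2. **Two-stage segmentation** — a global Bayesian classifier on a linear
   combination of discrete Gaussians (LCDG),
   p(q) = Σᵣ w₍p,ᵣ₎ ψ(q|θ₍p,ᵣ₎) − Σₗ w₍n,ₗ₎ ψ(q|θ₍n,ₗ₎), fitted by a
   modified EM algorithm, with the vessel rule P(v)p(q|v) ≥ P(O)p(q|O);
   then a novel local adaptive refinement: per-slice connected components,
   adaptive search windows, local thresholds T = (μ_b + μ_o)/2, seed
   generation for missed small vessels, and 3-D region growing.
3. **Morphometry** — vessel caliber via the Euclidean distance map sampled
   at the medial axis, summarized by the empirical CDF F(x) = P(X ≤ x) and
   median radius; tortuosity via per-vertex principal curvatures
   (k₁ ≥ k₂) on the triangulated vessel surface, estimated by
   least-squares fits of Euler's relation k(θ) = k₁cos²θ + k₂sin²θ to
   finite-difference normal curvatures, summarized by mean curvature
   H = (k₁+k₂)/2, Gaussian curvature K = k₁k₂, and the surface integral of
   |K| — globally and for lower/upper axial sections.
4. **Statistics** — MAP = (2·DBP + SBP)/3 and random-intercept mixed models
   MAP ~ feature + (1|subject), tested by likelihood-ratio χ²(1).

A seeded synthetic vascular phantom generator with exact ground truth
(tubular vessels, tissue/background/skull-shell intensity classes, bias
field, noise) validates every stage.

## Worked example

```r
library(cerevasc)

# a 64^3 phantom with 8 vessels (radii 0.75-3 mm), bias field, noise, skull shell
spec    <- phantom_spec(shape = c(64, 64, 64), seed = 1)
phantom <- generate_phantom(spec)
phantom$volume
#> <volume3d> 64 x 64 x 64 voxels, spacing 1x1x1 mm, Q=256
#>   intensity range [0, 252]

# full pipeline: preprocess -> LCDG -> refine -> features -> MAP
res <- run_subject_pipeline(phantom$volume, sbp = 124.5, dbp = 73,
                            subject_id = "A", timepoint = "t0")

evaluate_segmentation(res$mask_final, phantom$truth)
#> <seg_eval> DSC 99.98%  Sens 99.95%  Spec 100.00%  AVVD 0.05%

res$radius_cdf
#> <radius_cdf> n=251, median radius 2.000 mm, range [1.414, 3.162]

res$record[, c("section", "map_mmHg", "median_radius_mm",
               "median_H", "median_K", "integral_absK")]
#>   section map_mmHg median_radius_mm median_H median_K integral_absK
#> 1  global     90.2             2.00    0.170 -0.00487           337
#> 2   lower     90.2             2.00    0.133 -0.01043           181
#> 3   upper     90.2             1.73    0.209  0.00347           155
```

Reading the output: the refined segmentation recovers the ground-truth
tree almost exactly (Dice 99.98%, volume error 0.05%); the medial-axis
radius sample has median 2 mm; MAP for readings 124.5/73 mmHg is
90.17 mmHg; mean curvature medians around 0.13–0.21 mm⁻¹ correspond to
tube radii of roughly 1/(2·H) ≈ 2.4–3.8 mm including bending, and the
area-weighted integral of |K| is the per-section tortuosity index.

Association testing on a cohort table (one row per subject, timepoint and
section):

```r
fit_map_association(cohort_table, "median_radius_mm")
# <association> median_radius_mm: chi^2(1) = ..., p = ..., coef -
```

A command-line front end wrapping these functions ships in
`inst/cli/cerevasc` (subcommands `phantom`, `preprocess`, `segment-global`,
`segment`, `features`, `evaluate`, `analyze`), e.g.

```sh
cli=$(Rscript -e 'cat(system.file("cli", "cerevasc", package = "cerevasc"))')
Rscript $cli phantom --out demo --seed 3 --size 48
Rscript $cli preprocess --in demo/phantom.nii.gz --out pp.nii.gz --brain-out brain.nii.gz
Rscript $cli segment-global --in pp.nii.gz --brain brain.nii.gz --out init.nii.gz
Rscript $cli segment --in pp.nii.gz --init init.nii.gz --brain brain.nii.gz --out final.nii.gz
Rscript $cli evaluate --seg final.nii.gz --truth demo/truth.nii.gz
```

## Package layout

* `R/phantom.R` — synthetic phantom generator (centerlines, rasterization,
  intensity synthesis, bias, noise)
* `R/preprocess.R` — bias correction, GGMRF/ICM smoothing, skull stripping
* `R/lcdg.R` — LCDG fitting (modified EM) and Bayesian classification
* `R/refine.R` — local adaptive refinement (windows, thresholds, seeds,
  region growing)
* `R/features-radius.R`, `R/features-curvature.R` — distance map, medial
  radii, radius CDF, iso-surface extraction, principal curvatures,
  tortuosity summaries, axial sections
* `R/analysis.R` — MAP, segmentation metrics, cohort simulation, mixed
  models, the per-subject pipeline
* `src/cerevasc.cpp` — exact Euclidean distance transform, connected
  components, region growing, GGMRF sweeps, separable Gaussian filtering,
  tetrahedral iso-surfacing, curvature fitting
* `vignettes/cerebrovascular-morphometry.Rmd` — the methods vignette:
  models, assumptions, parameter rationale, validation scope.
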