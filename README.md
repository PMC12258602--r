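# spinalign

Spine-to-back-shape registration geometry and rater-reliability analysis
for scoliosis research.

## The problem

In adolescent idiopathic scoliosis, the "back-shape-to-spine" approach
tries to estimate the internal spinal alignment from a radiation-free 3D
surface scan of the back. Validating that approach requires (i) registering
surface scans onto biplanar radiographs through radiopaque skin markers,
(ii) extracting Cobb angles from annotated spine centerlines, (iii)
quantifying how well the standing posture was replicated between the two
acquisitions, (iv) correlating the externally visible spinous-process line
(SPL) with the internal spinal line (ISL, through the vertebral-body
centroids), and (v) establishing that the annotation step is reliable
across raters — including non-clinician raters — with mixed-effects
models, intraclass correlations, equivalence tests and an a-priori power
analysis. `spinalign` implements this whole chain in R, together with a
seeded synthetic cohort generator (parametric scoliotic spines, biplanar
parallel projections, posture perturbation, per-rater annotation noise) so
that every stage is testable without access to clinical images.

## The core quantities

* **Rigid registration (Kabsch/SVD).** Given paired marker sets, find the
  proper rotation R and translation t minimizing Σ‖R s_i + t − d_i‖²; the
  reflection branch of the SVD is corrected so det(R) = +1.
* **Cobb angle from a centerline.** On a smoothed curve u(y), the tangent
  inclination θ(y) = atan u′(y) is computed from the analytic spline
  derivative; consecutive extrema of θ play the role of the most tilted
  endplates and the Cobb angle is the largest |θ_i − θ_j| between
  consecutive extrema. The generator's single-period sinusoid of amplitude
  A and wavelength λ has the closed form Cobb = 2·atan(2πA/λ).
* **Posture-alignment error.** RMSE and SD of the pointwise difference
  between the lateral back outlines of the two acquisitions on a common
  height grid.
* **SPL–ISL correlation.** Option 1: Pearson correlation of the transverse
  coordinates per anatomical plane. Option 2: the ISL is first superposed
  onto the SPL by a Procrustes fit restricted to rotation + translation
  (no scaling), with arc-length point correspondence, making the result
  independent of global pose.
* **Reliability statistics.** REML mixed models (`lme4`), adjusted ICC of
  the crossed patient × rater model with a parametric-bootstrap CI,
  Shrout–Fleiss ICC(2,1) per rater, CI-inclusion equivalence tests
  (90% CI inside ±5°), and the equivalence-power simulation over a grid of
  patient/rater/repetition effect sizes.

## Worked example

```r
library(spinalign)

# one synthetic patient: moderate scoliosis with rotation coupling
m <- generate_spine("moderate", seed = 3)
implied_cobb(m)
#> [1] 29.02475

crv <- sample_curves(m, n_samples = 250)
cobb_coronal(project_plane(crv$ISL, "coronal"))$angle
#> [1] 29.02471

# full inter-/intrarater experiment: 7 patients, 16 raters, 3 repetitions
res <- run_iir_experiment(cohort_config(seed = 11), curvatures = "coronal")
nrow(res$records)                      # 336 coronal ratings
res$interrater                         # crossed ICC with bootstrap CI
res$equivalence$ci                     # 90% CI of the clinician-student diff
```

On this seed the interrater ICC is 0.967 with bootstrap CI [0.87, 0.99] —
comparable to reliability values reported for Cobb-angle annotation — and
the clinician–student 90% CI is [−1.9°, 0.7°], well inside ±5°, i.e. the
two rater classes are equivalent. `run_protocol_comparison()` ranks acquisition
protocols by posture-alignment error and SPL–ISL correlation; a thin CLI
(`inst/scripts/spinalign`) exposes the same pipelines from a shell.

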