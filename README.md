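# ssmreg

Statistical shape models of bone surfaces from triangulated meshes, via
groupwise Gaussian-mixture L2 registration.

## The problem

Population studies of bone geometry (and implant design derived from
them) need a *statistical shape model*: a mean shape plus orthogonal
modes of variation learned from a cohort of 3D surfaces — for example
CT-segmented tali exported as STL meshes.  The obstacle is dense
correspondence: PCA over shapes requires every subject to be sampled by
the same points in the same order.  `ssmreg` builds that correspondence
by groupwise non-rigid registration and provides the downstream model
and comparison tools:

* **STL geometry**: binary/ASCII reader and writer, left-to-right
  mirroring, rigid ICP pre-alignment, grid-average subsampling, mesh
  volumes and volume matching.
* **Registration**: each cloud is a Gaussian mixture
  $D_i(x) = \tfrac1{n_i}\sum_j N(x; p_{ij}, \sigma)$; a thin-plate
  spline $T(x)=x+\phi(x)\theta$ (3D kernel $U(r)=r$) deforms the
  reference to minimize
  $\int (D_i - D_j)^2\,dx \;+\; \lambda\,\mathrm{tr}(\theta^\top\phi^\top\phi\,\theta)$
  by L-BFGS with analytic gradients, nearest-neighbour-truncated sums,
  and iterative refinement of points whose closest-point distance
  exceeds a tolerance (defaults: $\sigma=I$ mm², 6 neighbours,
  $\lambda=10^{-11}$, 0.4 mm, ~1,360/~2,000 points).
* **Shape model**: covariance PCA on raw coordinates (size stays in the
  data, so PC1 captures scale), mode synthesis at chosen ±kσ, variance
  fractions, connectivity transfer for visualization.
* **Deviation analysis**: signed point-to-triangle distances (winding
  number sign), threshold percentages, volume-matched comparisons,
  plane-section circumference checks.
* **Synthetic populations**: a seeded talus-like shape generator with
  planted scale/bump modes and full ground truth, so the entire pipeline
  is validated against known answers.

## Worked example

```r
library(ssmreg)

# a seeded synthetic population of 6 talus-like bones (~36,000 mm^3)
spec <- population_spec(n_subjects = 6, seed = 42)
pop  <- generate_population(spec)
meshes <- mapply(function(m, mir) if (mir) mirror_mesh(m, "x") else m,
                 pop$meshes, pop$truth$mirrored, SIMPLIFY = FALSE)

# groupwise registration: first subject is the reference
rs <- groupwise_register(meshes[[1]], meshes, registration_config())
rs
#> registered_set: 6 subjects, 1360 reference points, errors 0.163-0.212 mm

# PCA shape model over the corresponded clouds
model <- build_shape_model(rs, cohort_label = "demo")
model
#> shape_model 'demo': 6 subjects, 1360 points, 5 modes
#>   variance explained (%): 74.7, 8.7, 6.3, 5.3, 5

cor(model$scores[, 1], pop$truth$scale)
#> [1] 0.9990259
```

Every subject registered to about 0.2 mm mean closest-point error
(the published operating tolerance for talus-scale clouds is 0.4 mm);
the first principal mode carries ~75% of the variance and its scores
track the planted size factors essentially perfectly — in bone cohorts
PC1 is size.  `synthesize_shape(model, c(3))` returns the "+3σ" PC1
shape; `deviation_report()` quantifies how far such a mode shape
deviates from the mean, and `plane_sections()` compares cross-section
circumferences.

A YAML-driven pipeline with the same stages (plus manifest hashing) is
available as `run_pipeline()` / the `exec/ssmreg` command-line script.

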