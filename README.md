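# geoadditive

Bayesian geo-additive logistic regression for spatially indexed binary
health outcomes — the model family used in disease-mapping analyses of
childhood anaemia, where interest lies simultaneously in categorical risk
factors, nonlinear effects of continuous covariates, and a residual spatial
surface attributable to unmeasured contextual factors.

## The model

For child *j* in region *i* with binary outcome
*y<sub>ij</sub>* ~ Bernoulli(*p<sub>ij</sub>*), the full model is

    logit(p_ij) = z' β + f_1(u_1) + ... + f_p(u_p) + f_spatial(s_i)

with four nested forms: **M0** fixed effects only, **M1** adds the
nonlinear smooths, **M2** adds the spatial term only, **M3** has both.

* **Fixed effects** `z' β`: effect-coded categorical covariates (each
  non-reference level an indicator, the reference level −1 in every column),
  flat prior.
* **Smooths** `f_k`: P-splines — cubic B-spline bases at equally spaced
  knots, second-order random-walk priors on the coefficients, i.e. Gaussian
  priors with precision `K / τ²` where `K = D'D` is a difference penalty and
  each smoothing variance `τ²` carries an inverse-gamma(0.001, 0.001)
  hyperprior.
* **Spatial term** `f_spatial`: a two-dimensional tensor-product P-spline
  over region centroid coordinates with a Kronecker-sum penalty
  (`K₁⊗I + I⊗K₂`), or alternatively an intrinsic Markov random field prior
  whose precision is the Laplacian of the 4-nearest-neighbour region graph.
* **Inference**: blockwise Gibbs sampling with Pólya-Gamma augmentation
  (`ω ~ PG(1, η)` makes every full conditional Gaussian or inverse-gamma;
  no tuning, reproducible from a single seed). Models are compared by
  `DIC = D̄ + p_D` with `p_D = D̄ − D(posterior mean)`; region effects are
  classified positive / insignificant / negative by whether their 80% and
  95% equal-tailed posterior credible intervals exclude zero.

Because the survey data such analyses use are access-controlled, the
package ships a synthetic generator (`default_truth()`,
`generate_dataset()`) with a fully known truth — documented fixed effects,
closed-form nonlinear curves (child-age decay; U-shaped mother's-age effect;
breastfeeding effect with minimum at 29 months), and a smooth spatial
surface on a 6×6 lattice of 36 regions — so that every stage is testable by
parameter recovery.

## Worked example

```r
library(geoadditive)

sim <- generate_dataset(default_truth(n_children = 8000L, seed = 1L))
sim
#> synthetic_dataset: 8000 children, 36 regions, prevalence 57.5% (seed 1)

prevalence_by(sim$data, "mother_anaemic")
#>     group    n n_anaemic  percent
#> 1      No 4691      2465 52.54743
#> 2     Yes 3309      2134 64.49078
#> 3 Overall 8000      4599 57.48750

smooth <- list(child_age  = list(n_segments = 10L, degree = 3L, order = 2L),
               mother_age = list(n_segments = 10L, degree = 3L, order = 2L),
               breastfeed = list(n_segments = 10L, degree = 3L, order = 2L))
fit0 <- fit_geoadd(sim$data, model_spec("M0"),
                   mcmc = mcmc_config(2000, 500, seed = 2L))
fit3 <- fit_geoadd(sim$data, model_spec("M3", smooth = smooth),
                   centroids = sim$geography$centroids,
                   mcmc = mcmc_config(2000, 500, seed = 2L))

compare_models(list(M0 = fit0, M3 = fit3))
#>   model     dbar       pd      dic preferred
#> 1    M3 10177.34 49.13366 10226.47      TRUE
#> 2    M0 10730.46 17.25905 10747.72     FALSE
```

The full model wins by ~520 DIC units: the deviance drop buys far more than
the ~32 extra effective parameters cost. Its fixed-effect summaries recover
the generative coefficients (truth: mother anaemic +0.2715, stunted
+0.0999):

```r
fixed_effect_table(fit3)[c(10, 14, 17), ]
#>           coefficient    mean     sd     q10  median    q90 significant
#> 10     wealth:Richest -0.0259 0.0563 -0.0969 -0.0261 0.0462       FALSE
#> 14        stunted:Yes  0.0931 0.0239  0.0624  0.0934 0.1239        TRUE
#> 17 mother_anaemic:Yes  0.2605 0.0245  0.2294  0.2605 0.2919        TRUE

cv <- smooth_curve(fit3, "breastfeed")
cv$x[which.min(cv$mean)]   # truth: 29 months
#> 28.8

classify_spatial(fit3, 0.95)
#> spatial_classification at 95%: 11 positive, 11 negative, 14 insignificant of 36 regions
```

`run_pipeline()` drives the same stages from a YAML config (simulate or
load CSV/GeoJSON, filter, describe, fit M0–M3, compare, summarise, and
write the classified spatial effects back onto the GeoJSON for mapping).

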