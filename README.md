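# hdeeg

High-dimensional tests for stimulus-induced change in multichannel
time-series recordings (EEG-style data: rows = time points, columns =
channels). The package is aimed at statisticians and neuroimaging analysts
who need to ask two questions of epoched recordings where the channel count
p rivals or exceeds the epoch length:

1. **Did the mean signal change?** Classical Hotelling's T² needs the
   inverse of the pooled covariance, which does not exist when p > n − G.
   The ridge-regularized statistic

   RIHT = Σ_g n_g (X̄_g − μ̂)′ (S_n + λI)⁻¹ (X̄_g − μ̂),  λ > 0,

   is always defined, and its null distribution is standardized with trace
   functionals of (S_n + λI)⁻¹Σ estimated purely from the spectrum of S_n
   via its Stieltjes transform — no knowledge of Σ and no Gaussianity
   beyond four matched moments is required. A two-step procedure
   (omnibus test across all epochs, then adjacent-pair tests gated on
   rejection) localizes change points.

2. **Did the connectivity change?** Channel dependence is modelled by
   Gaussian graphical models: zero entries of the precision matrix
   Θ_g = Σ_g⁻¹ are absent conditional dependencies. The fused graphical
   lasso estimates all groups jointly,

   min Σ_g { tr(S_g Θ_g) − log det Θ_g } + λ₁ Σ_g ‖Θ_g⁻‖₁
       + λ₂ Σ_{g<g'} ‖(Θ_g − Θ_{g'})⁻‖₁,

   solved by an ADMM with a closed-form positive-definite update (compiled
   core). Penalized estimates are then de-biased,
   Θ̃ = 2Θ̂ − Θ̂SΘ̂, and each entry of a linear combination
   Σ_g a_g Θ̃_g is z-tested (the MPDe test); with a = (1, −1) this asks,
   per channel pair, whether the conditional dependence changed between
   pre- and post-stimulus. Hyperparameters come from an AIC grid search or
   a learned single-trajectory rule; lasso channel screening and
   degree-centrality summaries of the significant-change network round out
   the workflow, and seeded generators reproduce all the validation
   designs.

## Worked example

```r
library(hdeeg)
set.seed(42)

# two epochs, 63 channels: baseline and a shifted post-stimulus interval
baseline <- matrix(rnorm(100 * 63), 100, 63)
post     <- matrix(rnorm(40 * 63, mean = 0.25), 40, 63)

riht_test(grouped_samples(list(baseline, post)), lambda = 1)
#> RIHT test: T = 12.25  p = 1.782e-34  (reject)
#>   RIHT = 115.438  lambda = 1  groups: 100, 40  [plug-in calibration]
```

The raw quadratic form (115.4) is standardized by the plug-in mean
e₂·tr₁ = 35.0 and variance 2e₂·tr₂ = 43.2 into T = 12.25, far beyond the
1.96 threshold: the 0.25-unit mean shift across 63 channels is detected
decisively even though the post epoch has only 40 time points.

```r
# precision-matrix change between two populations drawn from one truth
dat <- gen_scenario("I", seed = 7)   # p = 50, sparsity 0.1, n = 200 each
problem <- empirical_covariances(list(dat$X1, dat$X2))
fit <- fit_fgl(problem, fgl_hyper(lambda1 = 0.2, lambda2 = 0.1))
fit
#> <fgl_fit> G = 2  p = 50  lambda1 = 0.2  lambda2 = 0.1
#>   iterations: 304 (converged)  relative change: 9.91e-10

mpde_test(debias_fit(fit), a = c(1, -1))
#> <mpde_result> p = 50  coefficients: 1, -1  n_eff = 400
#>    15 significant edge(s) at p < 0.01

support_metrics(fgl_support(fit), dat$Theta0)
#> # A tibble: 1 × 3
#>      R1    R0 accuracy
#> 1  56.6  94.4     90.6
```

Both samples share one precision matrix, so the 15 flagged edges out of
1225 pairs are false positives running at about the nominal 1% rate; the
support metrics say the penalized fit recovered 56.6% of the true edges
while correctly zeroing 94.4% of the true non-edges. Results carry
broom-style `tidy()`/`glance()` methods and `autoplot()` visualizations;
`run_framework()` chains epoch slicing, the mean test, the connectivity
test and the channel analyses into one reproducible report, and
`inst/cli/hdeeg.R` exposes the same steps as a command-line tool.

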