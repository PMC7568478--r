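# quantherit

Quantile-specific heritability from family phenotype data.

Classical family studies summarize the resemblance between relatives with a
single regression slope, and therefore a single narrow-sense heritability
(h²). For right-skewed traits such as plasma adiponectin, the genetic effect
size can instead depend on where an individual sits in the phenotype
distribution ("quantile-dependent expressivity"): the offspring–parent slope
at the 90th percentile of the offspring distribution may be twice the slope
at the 10th. `quantherit` implements the full analysis pipeline for
detecting and quantifying this phenomenon in nuclear-family data, together
with a synthetic cohort generator with known latent genetics that serves as
its test bed.

## What it computes

Starting from long-format phenotype tables (one row per individual per
examination), the pipeline:

1. **Adjusts** phenotypes for age and sex per examination stratum by OLS on
   `[1, female, age, age², female·age, female·age²]` and averages residuals
   over an individual's available examinations.
2. **Builds relative pairs**: offspring–parent pairs (weight ½ per pair
   when both parents are phenotyped, 1 when only one is),
   offspring–midparent pairs, spouse pairs, and double-entry full-sib pairs,
   with family-aware degrees of freedom (Σkᵢ − 2 for offspring–parent and
   midparent, Σ(kᵢ − 1) for sibships).
3. **Fits simultaneous quantile regressions** of dependent on predictor at a
   grid of quantiles τ (default the 91 percentiles 0.05…0.95) by exactly
   minimizing the weighted check loss Σ wᵢ ρ_τ(yᵢ − a − b xᵢ),
   ρ_τ(r) = r(τ − 1[r<0]), as a linear program; the joint covariance of the
   slope curve comes from a family-cluster bootstrap.
4. **Transforms slopes to heritability** with Falconer's formulas:
   h² = 2β_OP/(1 + r_spouse) from offspring–parent slopes, h² = β_OM from
   midparent slopes, and h² = (√(1 + 8 r_spouse β_FS) − 1)/(2 r_spouse)
   from full-sib slopes, with bootstrap (and delta-method) standard errors.
5. **Tests trends** across percentiles with orthogonal-polynomial contrasts
   (constant vs linear/quadratic/cubic in the percentile).
6. **Remaps group-specific curves** (e.g. sons vs daughters) onto a common
   concentration axis with empirical quantile–quantile mapping, so groups
   can be compared at matched concentrations rather than matched
   percentiles.

## Worked example

Simulate a Framingham-like cohort whose latent heritability is 0.5 but whose
observed scale is exponential (so raw-scale slopes rise with the
percentile), then run the core analysis:

```r
library(quantherit)
cfg <- cohort_config(n_families = 1500, transform = "exp", seed = 7)
cohort <- generate_cohort(cfg)
adjusted <- adjust_phenotypes(cohort$pedigree, cohort$phenotypes)
r_sp <- spouse_correlation(cohort$pedigree, adjusted)
pairs <- build_offspring_parent(cohort$pedigree, adjusted)
fit <- sqreg(pairs, taus = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
             B = 200, seed = 7)
fit
#> simultaneous quantile regression (offspring_parent): 7 quantiles, 4198 pairs, B = 200, df = 2943
#>   tau  slope boot_se
#>  0.10 0.0278  0.0102
#>  0.25 0.0543  0.0091
#>  0.50 0.1085  0.0155
#>  0.75 0.2227  0.0455
#>  0.90 0.4571  0.0938
h2_curve(fit, "offspring_parent", r_spouse = r_sp)
#> quantile-specific heritability (offspring_parent, r_spouse = -0.008160941, df = 2943)
#>  percentile    h2    se
#>          10 0.056 0.021
#>          25 0.109 0.018
#>          50 0.219 0.031
#>          75 0.449 0.092
#>          90 0.922 0.189
trend_test(fit)
#> trend across percentiles (slope scale, df = 2943)
#>     degree estimate       se    t        p
#>     linear 0.005661 0.001269 4.46 8.44e-06
#>  quadratic 0.207500 0.074440 2.79 5.34e-03
#>      cubic 0.101400 0.053730 1.89 5.91e-02
#> linear estimate is per one-percent increase of the distribution
```

The slope curve rises from 0.028 at the 10th percentile to 0.457 at the
90th, heritability rises with it, and the linear trend (0.0057 per
one-percent increase of the distribution, p ≈ 8×10⁻⁶) flags the
quantile dependence. With `transform = "identity"` the same pipeline
produces a flat curve and a null trend test. (The spouse-correlation
estimate, here −0.008 against a generating value of 0.04, is itself noisy
at this cohort size.)

The same stages are scriptable from the shell via `inst/cli/quantherit`
(`simulate`, `adjust`, `pairs`, `fit`, `h2`, `trend`, `remap`, `report`,
`all`), each reading and writing plain CSV/JSON/YAML artifacts.

## Documentation

The methods vignette (`vignettes/quantile-specific-heritability.Rmd`)
documents the statistical model, the solver, every tunable parameter, what
the synthetic generator does and does not emulate, and the package's design
decisions and limitations.
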