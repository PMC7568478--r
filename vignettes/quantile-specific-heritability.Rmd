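---
title: "Quantile-specific heritability: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-specific heritability: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantherit)
```

## The problem

Narrow-sense heritability (h²) is classically estimated from a single
regression slope between relatives, which presumes the genetic effect size
is the same everywhere in the phenotype distribution. For skewed traits —
plasma adiponectin is the motivating case — the resemblance between
relatives can instead grow (or shrink) with the percentile at which it is
measured. `quantherit` estimates the whole curve h²(τ) for τ between the
5th and 95th percentile, tests whether it is constant, and provides the
machinery needed to interpret group differences (e.g. sex differences) that
are driven purely by groups sitting at different concentrations.

## Estimators

**Adjustment.** Phenotypes are adjusted per examination stratum by OLS on
`[1, female, age, age², female·age, female·age²]`, and each individual's
adjusted value is the mean of their per-exam residuals. Strata are
`(cohort, exam)` when a cohort column exists (here, the two generations),
pooling parents and offspring that belong to the same stratum; whether real analyses of this design pooled generations within an exam is
rarely documented, and pooling is the simpler convention. Residuals are *not* re-standardized:
analyses run in raw residual units.

**Relative pairs.** Offspring–parent pairs carry weight ½ each when both
parents are phenotyped and 1 when only one is, so each offspring
contributes total weight 1. Midparent pairs exist only in families with
both parents. Full sibs (sharing both parents; half-sibs excluded) enter by
double entry — all k(k−1) ordered pairs — which forces both pair members
onto one marginal distribution, making the sib regression slope equal the
sib correlation (an invariant the tests assert). Degrees of freedom follow
the family-adjusted rules Σkᵢ − 2 (offspring–parent, midparent) and
Σ(kᵢ − 1) (sibships), with every family contributing at least one pair
counting its kᵢ in the sum.

**Quantile regression.** At each τ the fit minimizes the weighted check
loss Σ wᵢ ρ_τ(yᵢ − a − b xᵢ). Because ρ_τ is positively homogeneous, the
weighted problem is the unweighted problem on rows scaled by wᵢ. The solver
(C++, `src/rq.cpp`) runs a primal-dual interior-point method on the
bounded-variable LP dual with Mehrotra predictor-corrector steps, then
applies a *vertex polish*: an optimal basic solution of the LP passes
through two data points, so the lines through pairs of the eight
smallest-residual points are enumerated and the best exact objective is
kept. The polish set is deliberately small so the production solver never
degenerates into the brute-force enumeration the test suite uses as an
independent oracle. When the Newton system turns numerically singular
(degenerate active sets under bootstrap resampling) the solve is
regularized with a tiny ridge and, failing that, the current iterate is
accepted and the polish finishes the job — point estimates remain exact
vertices; replicate slopes only feed variances. Tie-breaking is
deterministic: the first-enumerated candidate wins equal objectives, and
degenerate-case tests compare objectives, not coefficients. Quantile
crossing is possible and is neither corrected nor hidden.

**Bootstrap.** The joint covariance of the slope curve across the τ grid
comes from refitting all quantiles on B resamples. The resampling unit is
the *family* by default: double entry and the ½ weights create
within-family dependence that observation resampling (the convention of
common software) ignores; an observation mode is provided for
compatibility. Resamples with a constant predictor are redrawn and counted;
more than 1% redraws is an error. All randomness flows through R's RNG, so
a seed reproduces replicate matrices bit for bit.

**Falconer transforms.** h² = 2β_OP/(1 + r_spouse), h² = β_OM, and
h² = (√(1 + 8 r_spouse β_FS) − 1)/(2 r_spouse) with the analytic limit
2β_FS as r_spouse → 0 (the closed form and its algebraic inverse
β = h(1 + r h)/2 round-trip to 1e−10 in the tests). The spouse correlation
enters as a plug-in constant (it is not resampled), the standard plug-in
convention for these formulas; estimates outside [0, 1] warn rather than error, because the
estimator legitimately exceeds the parameter range on noisy data.
Heritability-scale standard errors use the SD of the transformed bootstrap
replicates as the primary output — exact under the bootstrap, no
linearization error for the square-root transform — with the delta-method
SE reported alongside; full-sib replicates with a negative discriminant are
flagged invalid rather than made imaginary.

**Trend tests.** Orthogonal-polynomial contrasts over the percentile grid
(Gram–Schmidt against the constant, via `poly()`) test constancy against
linear, quadratic and cubic alternatives. The linear contrast is scaled so
its estimate reads "per one-percent increase of the distribution"; higher
degrees keep the orthonormal scaling, which leaves their t and p values
unchanged. Contrast variances use the bootstrap covariance and Student t
with the pair-set df. Trends are computed on the slope curve and on the
transformed heritability curve; for the offspring–parent relationship the
two differ exactly by the factor 2/(1 + r_spouse) (the transform is
linear), for full sibs the replicate route is the honest one.

**Q-Q remapping.** The empirical quantile function interpolates linearly
between order statistics at plotting positions pᵢ = (i − ½)/n (clamped to
the extreme order statistics outside), and its inverse uses the same rule,
so F(Q(p)) = p on the interior. The rule is fixed and documented so results
are bit-stable; no single convention is standard for such plots. To compare groups at matched
concentrations, each group's curve value at reference percentile p is read
off at its own percentile F_g(Q_ref(p)); points leaving the group's fitted
5th–95th percentile support are masked, never extrapolated. The reference
distribution is the combined unadjusted sample of both groups. Group
difference SEs assume independent groups (distinct offspring strata), with
remapped SEs taken as the SD of remapped replicate curves.

## The synthetic cohort: the stated world

The generator draws nuclear families under a fully additive latent model:

* parent latent phenotypes standard bivariate normal with correlation
  `r_spouse_target` (direct sampling, not iterative assortative-mating
  simulation — the simplest mechanism with the exact target correlation);
* parental genetic values with Var(G) = h², Cov(G, P) = h²; offspring
  G = midparental G plus segregation variance h²/2; offspring latent
  P = G + C_fam + E with shared-sibship variance c² and environmental
  variance 1 − h² − c²;
* observed value per exam = transform(P) + age/sex model + N(0, σ_exam²).

Age and sex effects are added *after* the monotone transform, so the
pipeline's linear adjustment removes them exactly in expectation and the
adjusted residual is transform(P) + noise up to a constant. With
`transform = "identity"` every downstream slope curve is flat; with
`transform = "exp"` raw-scale slopes rise in τ while the latent genetics
are unchanged — the cleanest possible caricature of a right-skewed trait
with quantile-dependent expressivity. Analyzing the log of an
exp-transformed cohort restores the latent-normal world, so the trend
flattens; reported log-transform sensitivity analyses of real adiponectin
show a *decreasing* trend, which requires stronger-than-log curvature in
the real trait, so the package asserts the direction (trend collapses
toward zero) rather than a sign flip.

Defaults are chosen once, from the design the package emulates, and are not
tuning knobs: sibship sizes 1–5 with truncated-geometric probabilities
∝ 0.55^(k−1) (mean sibship ≈ 2, mean sibship among size-≥2 sibships ≈ 2.5;
the true Framingham sibship-size distribution is not public);
`p_both_parents = 0.42` (in the Framingham adiponectin sample 1232 of 2950
offspring had both parents phenotyped); `r_spouse_target = 0.04`; `h2_latent = 0.5` (mid-range of
published adiponectin heritabilities); `c2_shared = 0` so Falconer's
narrow-sense formulas are the exact estimand; parents ~N(60.5, 9.5²) years
and offspring ~N(40, 8.7²), truncated at 16; an age/sex mean model with a
female excess of about 4 concentration units and a small positive age
slope, mirroring the Framingham sample characteristics; two examinations
with σ_exam = 0.1 (assay CV of a few percent against a phenotype SD of
about 1.3 on the exp scale). Dominance, epistasis, X-linkage, selection and
longitudinal aging are *not* simulated — Falconer's formulas are the
estimand, so a green test establishes that the pipeline recovers the
additive world it was given, not that those formulas describe any real
trait.

For sex comparisons the generator can shift female *offspring* latent
values by `sex_shift_latent` before the transform. With a convex transform
this yields daughters whose concentrations run higher than sons' while the
conditional law of offspring given parent differs only through that shift —
under the exp transform the two sexes' slope curves differ by the factor
e^shift at matched percentiles but nearly coincide at matched
concentrations. The coincidence is exact only in the limit of a
concentration-indexed slope law; for the bivariate lognormal it holds to
within a factor e^{shift(1−α)} with α close to 1, well inside bootstrap
bands at the tested sizes, which is precisely the qualitative phenomenon
the remapping is meant to expose (and is asserted qualitatively, not to a
tolerance).

The independent calibration oracle `expected_quantile_slope_oracle()`
estimates quantile slopes of transformed bivariate-normal pairs by
Nelder–Mead minimization of the exact check loss on simulated pairs — a
deliberately different algorithm from the production LP solver, so
generator and solver validate each other.

## Numerical choices

* Interior-point tolerances: relative duality gap 1e−9, feasibility 1e−7,
  at most 60 iterations; the vertex polish makes reported objectives exact
  (the acceptance suite checks equality with brute-force enumeration at
  1e−9 on hundreds of random small datasets).
* Quantile grid: percentiles below the 5th and above the 95th are excluded
  by default (unstable tails); any user grid must contain the five headline
  percentiles 10/25/50/75/90. Equally spaced grids make the
  orthogonal-polynomial basis symmetric, but the construction works on any
  grid with at least degree + 1 distinct points.
* Simulation-based acceptance tests run at their stated cohort sizes
  (n_families = 2000, B = 100) but on the reduced grid
  {0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95} so the suite fits a
  25-minute budget on one CPU: grid size affects neither the null
  calibration of the trend test nor the trend construction; replicate
  counts, seeds and tolerances are unchanged.
* Degenerate inputs fail loudly with typed conditions: validation errors
  (exit code 2 from the CLI) for impossible configurations, rank-deficient
  adjustment designs (the offending collinear columns are named), constant
  predictors, mismatched grids; numerical errors (exit code 3) for
  non-PSD covariance input, negative Falconer discriminants and degenerate
  bootstrap runs.

## Limitations

* Heritability here is the Falconer plug-in estimand: offspring–parent
  estimates absorb shared environment, and full-sib estimates absorb shared
  environment and dominance. The package neither separates these components
  nor corrects for assortative mating beyond the spouse-correlation term.
* The spouse correlation is treated as known when transforming slopes; its
  sampling noise is not propagated (a co-resampling flag would be the
  extension point).
* Q-Q remapping compares fitted curves through interpolation; it does not
  refit at matched concentrations, and masked tails mean group comparisons
  cover only the overlap of the distributions.
* The generator's families are independent and demographically stationary;
  ascertainment, cohort effects and genotype-level simulation are out of
  scope.
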