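# onsetmix

Admixture analysis of age at onset (AAO) in clinical cohorts, built for the
bipolar-disorder use case: do the observed onset ages decompose into early-
and late-onset subgroups, where is the boundary between them, and do the
subgroups differ clinically?

The package is aimed at psychiatric epidemiologists and methodologists who
want the full published pipeline — mixture fitting, cut-off derivation,
distribution comparison, clinical-correlates testing — as tested, seeded,
reusable functions rather than a one-off script.

## What it computes

**Mixture model.** Onset ages are modelled as a univariate Gaussian mixture
with unequal component variances,

```
f(x) = Σⱼ πⱼ φ(x; μⱼ, σⱼ²),
```

fitted by EM (`fit_em`) with a deterministic quantile start plus seeded
random restarts. The number of components is chosen over a range (1–9 by
default) by maximizing `BIC = 2·logL − (3k−1)·log n` (`scan_components`),
the model-based-clustering convention in which larger is better.

**Onset cut-off.** For a two-component fit, the weighted component
densities cross at the roots of a quadratic (`posterior_boundaries`); the
crossing above the early component's mean defines the subgroup boundary,
and `integer_cutoff` returns the smallest integer age at which the late
component's posterior responsibility strictly exceeds 0.5. That age and
everything above it is late onset (EO < c ≤ LO); `assign_subgroups` labels
a cohort accordingly.

**Distribution comparison.** `ks_mixture` evaluates the Kolmogorov–Smirnov
distance D between two *fitted* mixture CDFs (grid plus local refinement);
`ks_empirical` is the classical two-sample test on raw ages.

**Clinical correlates.** Uncorrected Pearson chi-square, pooled
equal-variance t (from raw data or published summary cells), cross-product
odds ratios with Wald CIs, backward stepwise logistic regression (Wald
removal at α = 0.05), Pearson correlation, and Cohen's kappa — the exact
conventions needed to reproduce published clinical tables
(`run_correlates` orchestrates the battery on a labelled cohort).

**Synthetic cohorts.** `default_specs()` / `generate_cohort()` simulate
cohorts with the published mixture parameters, subgroup covariate
prevalences, course-type distributions and illness-duration structure, so
every stage is testable without patient data. Covariates are drawn
conditional on the true generating component, so posterior-label analyses
are attenuated by misclassification exactly as in a real cohort.

## Worked example

```r
library(onsetmix)

cohort <- generate_cohort(default_specs()$BD2, seed = 42)  # n = 279
scan <- scan_components(cohort$aao, k_min = 1, k_max = 4, seed = 1)
scan
#> Mixture model scan, k = 1 to 4
#>  k     BIC best
#>  1 -2236.3
#>  2 -2174.2    *
#>  3 -2184.4
#>  4 -2199.9
```

BIC selects two components: a one-component model loses 62 BIC points, and
three or four components are penalized back below the two-component model.

```r
best <- scan$fits[[as.character(scan$best_k)]]
best
#> Gaussian mixture fit: k = 2 components
#>      mean      sd weight
#> 1 19.7745  3.7500 0.4008
#> 2 36.7905 12.5958 0.5992
#> logLik = -1073.027, BIC = -2174.209 (n = 279, params = 5)

assign_subgroups(cohort, integer_cutoff(best))
#> Onset subgroups at cut-off 26 years (EO < 26 <= LO)
#>   EO: 134 (48.0%)   LO: 145 (52.0%)
```

At n = 279 the fitted components (19.8/36.8 years) scatter around the
generating values (20.9/38.2), and the derived cut-off lands at 26 rather
than the generating mixture's 28 — sampling noise a single real cohort
would show too. The correlates battery on the labelled cohort then flags
the alcohol-dependence excess in the early-onset group (χ² = 6.5, p =
0.011 for this seed) alongside the expected interview-age and
illness-duration differences.

Comparing two published mixture solutions directly:

```r
bd1 <- mixture_fit(c(22.6, 35.1), c(4.8, 10.1), c(0.669, 0.331))
bd2 <- mixture_fit(c(20.9, 38.2), c(4.1, 11.8), c(0.44, 0.56))
ks_mixture(bd1, bd2, nA = 224, nB = 279)
#> Kolmogorov-Smirnov distance between mixture CDFs
#>   statistic = 0.173201, p = 0.001158
#>   n = 224 / 279
#>   note: supremum at x = 33.1633; p approximate (asymptotic, effective n)
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/bd-admix.R` (subcommands `simulate`, `fit`, `assoc`).

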