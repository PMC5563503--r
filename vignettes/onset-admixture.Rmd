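---
title: "Admixture analysis of age at onset: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture analysis of age at onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetmix)
```

## The problem

Age at onset (AAO) in bipolar disorder is heterogeneous: cohorts repeatedly
show that the observed AAO distribution is better described as a mixture of
two (sometimes three) normal sub-distributions than as a single one. The
early-onset subgroup so identified tends to carry a distinct clinical
profile — higher familial load, comorbid alcohol dependence, particular
illness-course patterns — which makes the mixture-derived cut-off between
"early" and "late" onset a clinically meaningful quantity rather than an
arbitrary threshold.

`onsetmix` implements this analysis end to end: mixture fitting with model
selection, cut-off derivation, distribution comparison, the univariate and
multivariate clinical-correlates battery, and a synthetic-cohort generator
that reproduces the statistical structure the analysis assumes so the whole
pipeline can be exercised without patient data.

## The mixture model

AAO values $x_1, \dots, x_n$ (years; treated as continuous even though they
are recorded as integers) are modelled as

$$f(x) = \sum_{j=1}^{k} \pi_j \, \phi(x;\, \mu_j, \sigma_j^2),
\qquad \sum_j \pi_j = 1,$$

with *unequal* per-component variances — the published component tables
report distinct SDs per component, so the equal-variance model family is
not used. The free-parameter count is $3k - 1$.

Fitting is by expectation–maximization (`fit_em()`):

* **Initialization.** Restart 0 partitions the sorted data into $k$
  contiguous quantile blocks. Further restarts (10 by default) place
  component means at random quantiles of the sorted data with a common
  inflated/deflated SD and equal weights. All random starts depend on the
  data only through its order statistics, so a permutation of the input
  cannot change the fit — a property the test suite checks.
* **Convergence.** A restart stops when the relative log-likelihood change
  falls below `tol` ($10^{-8}$), or when the Aitken-accelerated estimate of
  the asymptotic log-likelihood is within `tol`·|logLik| of the current
  value. EM approaches its limit geometrically, so the Aitken stop
  recognises convergence long before the raw increments vanish; without it,
  heavily overlapping large-$k$ fits crawl to the iteration cap while the
  parameters are already stationary for practical purposes.
* **Variance floor.** Component SDs are floored at $10^{-3}$ times the
  sample SD. A fit that ends on the floor is flagged (`floor_hit`) rather
  than silently accepted: a floored component is a spike fitting one data
  point, not a subgroup.
* **Restart selection.** The restart with the highest log-likelihood wins.

Model selection (`scan_components()`) fits each $k$ in a range (1–9 by
default) and picks the $k$ maximizing

$$\mathrm{BIC} = 2 \log L - (3k-1) \log n,$$

the model-based-clustering sign convention in which *larger is better* and
printed BIC values of real cohorts are negative. Exact ties break toward
the smaller $k$ (parsimony). A $k$ that fails to fit (for example $n < 3k$)
is dropped from the selection with a warning rather than aborting the scan.

```{r}
bd2 <- mixture_fit(mean = c(20.9, 38.2), sd = c(4.1, 11.8),
                   weight = c(0.44, 0.56), n = 279)
bd2
```

## From posteriors to an integer cut-off

Given a fitted two-component mixture, the posterior responsibility of
component $j$ at age $x$ is
$\tau_j(x) = \pi_j \phi_j(x) / \sum_l \pi_l \phi_l(x)$.
The weighted densities of two components with unequal variances are equal
at the roots of a quadratic, so `posterior_boundaries()` solves it in
closed form. There are generally **two** crossings: the classification
boundary between the means, and a second low-age crossing where the wider
late component dominates again far in the left tail. Only the upper
crossing defines the early/late cut-off; the low-age crossing is reported
but plays no classification role (for the default type-2 parameters it
lies near 9–10 years, below any realistic onset).

The published cut-offs are integers, so `integer_cutoff()` returns the
smallest integer age, above the early component's mean, at which the late
component's responsibility *strictly* exceeds 0.5. That age itself belongs
to the late-onset group: EO $< c$, LO $\ge c$. The strictness matters at
exact ties: for equal-weight, equal-SD components at 20 and 30 the
densities cross exactly at 25, where the responsibility is exactly 0.5 —
not yet a late-onset majority — so the cut-off is 26.

```{r}
posterior_boundaries(bd2)
integer_cutoff(bd2)
```

`assign_subgroups()` applies the cut-off to a cohort and writes the labels
back as an `onset_group` column.

## Comparing two onset distributions

`ks_mixture()` computes the Kolmogorov–Smirnov distance
$D = \sup_x |F_A(x) - F_B(x)|$ between two *fitted* mixture CDFs on a
10,001-point grid spanning both mixtures to ±6 SD, refined by local
optimization between the grid neighbours of the argmax (the reported $D$ is
accurate to about $10^{-6}$). When the two cohort sizes are supplied, an
approximate p-value is taken from the asymptotic Kolmogorov distribution at
the effective size $n_A n_B / (n_A + n_B)$; this treats estimated CDFs as
if they were empirical and is labelled an approximation in the output.
`ks_empirical()` is the classical two-sample test on raw ages (asymptotic
p), for when samples rather than fits are to be compared. The theoretical
version is the pipeline default because the comparison of interest is
between the *estimated* onset distributions, not the raw samples.

## The clinical-correlates battery

Conventions are those of the clinical literature this battery mirrors:

* **Chi-square** (`pearson_chi2()`): uncorrected Pearson statistic; no
  Yates continuity correction (with the correction the published table
  statistics are not reproduced). Sparse tables (expected count < 5) are
  flagged but still tested — course-type tables legitimately contain rare
  categories.
* **t-test** (`pooled_t_from_summary()`, `pooled_t_raw()`): pooled
  equal-variance Student's t with $df = n_1 + n_2 - 2$, oriented as
  (second group − first group); the Welch variant reproduces none of the
  published statistics, the pooled one reproduces all four. The two routes
  (summary cells vs raw vectors) agree to machine precision by
  construction.
* **Odds ratios** (`odds_ratio_2x2()`): cross-product OR with a log-scale
  Wald CI; zero cells get the Haldane–Anscombe +0.5 correction and a flag.
* **Logistic regression** (`logistic_fit()`, `backward_stepwise()`):
  maximum likelihood via IRLS; backward elimination removes the covariate
  with the largest Wald p-value until all remaining p < α (0.05), refitting
  after each removal and keeping a removal trace. Wald is the default
  criterion because it is what the clinical packages of the period used; a
  likelihood-ratio criterion is available by flag. Perfect separation and
  singular designs raise errors instead of returning divergent estimates.
* **Missingness**: pairwise deletion per variable, with the effective n
  reported per row.
* **Collinearity rule**: age at interview is excluded from the
  multivariate model whenever illness duration qualifies, because duration
  is computed as interview age minus onset age and the two are nearly
  collinear.
* No multiple-testing adjustment is applied anywhere, mirroring the
  analysis this package reproduces.

## The synthetic cohort generator

`generate_cohort()` emulates the features of a real onset cohort that the
pipeline's statistics are sensitive to:

* AAO from the per-diagnosis two-component mixture, rounded half-up to
  whole years and floored at 5 (onsets below ~5 are not reliably
  diagnosable; left truncation is not otherwise modelled).
* Binary covariates (family histories, comorbidities, suicidality, sex)
  drawn per subgroup at the published early/late prevalences — but
  conditional on the **true generating component**, not the posterior
  label. Classifying by the fitted cut-off therefore mislabels a fraction
  of patients and attenuates every association exactly as imperfect
  classification would in a real cohort. This is intentional: it makes
  power checks honest. It also means the univariate battery detects a
  printed effect (such as the early-onset alcohol-dependence excess) in
  fewer seeds than the unattenuated effect size would suggest.
* Course type from per-subgroup multinomials; episode counts from negative
  binomials with the published subgroup means and approximately the
  published SDs (Poisson when not over-dispersed). Mixed-episode moments
  are not tabulated for the type-2 subgroup, so the default type-2 spec
  reuses the type-1 values as a plausible stand-in.
* Illness duration as a per-subgroup Gamma draw matched to the published
  duration means/SDs (floored at 0.5 y), and age at interview = onset +
  duration, capped at 90 y.

One structural limitation is worth stating precisely. With durations drawn
independently of onset age within subgroup, the correlation between
interview age and illness duration is about 0.95 inside the narrow
early-onset component but only ~0.65 cohort-wide, because the late
component's wide onset spread (SD ~12 y) enters the interview age but not
the duration. No generator calibrated to the published subgroup SDs can
push the cohort-wide correlation near 1: the published interview-age,
onset and duration SDs jointly imply (via
$\mathrm{var}(I) = \mathrm{var}(A) + \mathrm{var}(D) + 2\,\mathrm{cov}$)
a negative onset–duration covariance in the late subgroup and a
correlation ceiling well below the near-perfect value reported for the
real cohort. We keep the moment calibration and document the ceiling
rather than distort the printed SDs.

Other things the generator deliberately does not emulate: within-subgroup
dependence between AAO and covariates (conditional independence given the
component is assumed), family structure, centre effects, birth-cohort
trends, and recall bias. Passing tests therefore demonstrate that the
pipeline recovers the structure it assumes — not that real cohorts satisfy
those assumptions.

All generation is seeded through a local RNG scope, so identical spec +
seed give byte-identical tables and package calls never disturb the
caller's random stream.

## Numerical choices and test problem sizes

* EM tolerance $10^{-8}$ (relative), max 1,000 iterations, 10 restarts by
  default; boundary roots are closed-form (quadratic), checked to $10^{-6}$
  relative density agreement.
* KS grid 10,001 points plus local refinement; dense-grid brute force at
  $10^6$ points serves as the oracle in tests.
* The test suite uses n = 5,000 for parameter-recovery checks (the ±0.5 y /
  ±0.03 recovery band is roughly a 2-SE band at that size), 20 simulated
  cohorts of n = 279 with 5 EM restarts for the model-count selection
  check, 200 null simulations of n = 2,000 for the stepwise type-I
  property, and n = 10,000 for generator calibration — sizes chosen to make
  the stochastic bands meaningful while keeping a full run in minutes.

## Limitations

* Single EM implementation; no second-package replication of the fits
  (an independent model-based-clustering fit is used as a cross-check
  oracle in the tests only).
* No truncation-corrected likelihoods: cross-sectional designs right-truncate
  AAO and unreliable early diagnosis left-truncates it, and both can change
  the selected number of components. This package fits the observed data
  as-is.
* The asymptotic p-value attached to the theoretical KS comparison is an
  approximation; exact small-sample p-values are out of scope.
* Exact logistic regression and Firth correction are out of scope;
  separation raises an error instead.
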