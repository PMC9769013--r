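---
title: "Housing deprivation indices and mortality inequality: methods"
author: "housemort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Housing deprivation indices and mortality inequality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(housemort)
```

## The problem

Area-level deprivation indices are a standard instrument of social
epidemiology: individual records of material conditions (here, housing
quality) are aggregated to small administrative areas, combined into a
single score, and the areas are ranked into deciles. Mortality can then be
contrasted across deciles to ask how much of a population's death toll is
statistically associated with living in the most deprived areas.

`housemort` implements that full chain for housing deprivation:

1. **Index construction** — impute missing binary housing indicators,
   compute sector-level prevalences, fit a one-factor maximum-likelihood
   model, score and rank sectors into deciles (decile 1 = most deprived).
2. **Mortality stratification** — deaths and person-years by 5-year age
   group, sex, decile and multi-year period; direct age- and
   sex-standardization per 100,000 person-years.
3. **Inequality measures** — adjusted Lorenz curves and Gini coefficients;
   counterfactual expected deaths under the least deprived decile's rates,
   yielding a population attributable fraction (PAF) and excess deaths,
   with Monte Carlo confidence intervals.
4. **Life-table measures** — abridged period life tables per sex × decile ×
   period, Arriaga decomposition of the extreme-decile life-expectancy gap,
   and potential years of life lost (PYLL) before age 75.

Because register microdata of this kind are almost always
access-restricted, the package also contains a first-class synthetic
registry generator with a known latent deprivation gradient. Every
downstream stage is validated against that ground truth.

## The synthetic registry

`generator_config()` fixes the study conditions once:

* **Geography.** `n_sectors = 18000` sectors; populations log-normal with
  median `median_sector_pop = 300` and log-scale SD 1, giving the strong
  size heterogeneity and fat right tail typical of statistical sectors.
  A single log-normal cannot simultaneously match that median and a large
  share of near-empty sectors, so very small sectors (the ones removed by
  the >10-inhabitant filter) are rarer here than in real sector geographies
  — the filter is still exercised, just on fewer sectors.
* **Latent deprivation.** One standard-normal score per sector. Ground-truth
  deciles rank this score (1 = most deprived).
* **Households and indicators.** Household sizes i.i.d. from
  `household_size_dist` (mean ≈ 2.55); all members share the sector's
  indicator probabilities. Indicator `k` is Bernoulli with probability
  `plogis(intercept_k + loading_k × latent)`. The five defaults span
  loadings 0.6–1.0 and intercepts giving population prevalences of roughly
  6% ("no toilet") to 33% ("no central heating"), i.e. deprivation-coded
  binaries at realistic prevalences.
* **Missingness.** Each indicator value is masked with probability
  `missing_rate = 0.08`. With probability `block_missing_prob = 0.5` a
  household is masked as a block (household imputation then has no donor
  and profile imputation must work); otherwise members are masked
  independently and a fully-masked household of ≥2 keeps one unmasked
  member, so household donors exist. The marginal masking rate is
  `missing_rate` in the block branch and negligibly below it in the
  independent branch.
* **Mortality.** The generator needs an explicit mechanism (an observational
  register does not supply one): a Gompertz baseline hazard
  `a·exp(b·age)` with `a = 5e-5` per person-year at age 0 and `b = 0.085`
  per year of age — life expectancy at birth in the high 70s — a male/female
  hazard ratio of 1.5, a multiplicative decile effect declining linearly
  from 1.4 (decile 1) to 1.0 (decile 10, the reference), and a period
  factor declining 10% per decade so change-over-time reporting has signal.
  Extreme-decile standardized-rate ratios land around 1.3–1.4, in the range
  reported for housing-based indices. Deaths per
  sector × sex × age × year cell are Poisson with mean
  `person-years × hazard`. The proportional form is a modelling stand-in,
  chosen as the simplest age gradient that makes standardization, life
  tables and the Arriaga decomposition non-trivial.
* **Ground truth.** `true_paf` is computed analytically from expected (not
  sampled) deaths: `1 - sum(E_ref)/sum(E)` over all strata, with the
  reference rates those of the least deprived decile.

What the generator does **not** emulate: real geography or spatial
autocorrelation, migration and sector-boundary changes between censuses,
household-level (as opposed to sector-level) deprivation correlation beyond
shared sector probabilities, cause-specific mortality, and non-response
that is selective on deprivation. Passing tests therefore demonstrate that
the estimators recover known gradients under the stated mechanism — not
that any particular real population follows it.

## Index construction choices

* **Imputation order and rules.** Household first: a missing value takes
  the modal observed value among the other household members. Then
  profile: donors are sector-mates agreeing on at least 75% of the
  indicators observed by both (`share_threshold = 0.75`, a strict ≥ at the
  boundary, so 8/10 qualifies and 7/10 does not); pooled donors' modal
  value is used. Both steps resolve ties toward "deprived" — conservative
  for a deprivation index — never overwrite observed values, and use only
  pre-imputation observations as donor values, so results are independent
  of row order. Values with no qualifying donor stay missing and are
  simply excluded from prevalence denominators.
* **Factor model.** One factor (a single deprivation construct), no
  rotation (meaningless for one factor), fitted by maximum likelihood on
  the correlation — not covariance — matrix of sector prevalences, the
  standard choice when indicators have very different prevalences. Sectors
  are weighted by their person counts (`weights = "persons"`), so the
  correlation structure reflects people rather than areas; `"equal"` is
  available. Scores use the regression (Thomson) method and are oriented
  so that higher score = more deprived (positive correlation with mean
  indicator prevalence); the decile assignment is invariant to the raw
  sign returned by the optimizer.
* **Degenerate inputs.** A singular correlation matrix (e.g. perfectly
  collinear indicators) falls back to principal-axis loadings and
  first-component scores with a warning; uniquenesses at the optimizer's
  floor raise a Heywood-case warning. Indicators that are constant across
  sectors are an error.
* **Deciles.** Equal *sector* counts (±1), not equal population — deciles
  then hold varying population shares, which is what makes the Lorenz
  population axis informative. Ties are broken by sector id (stable).
  Sectors with ≤ `min_inhabitants = 10` inhabitants (strictly more than 10
  are kept) or with an indicator never observed are excluded and logged.

## Rates, Lorenz and PAF choices

* **Age groups.** Default 0–4, 5–9, …, 95+ (20 groups). The grid is a
  parameter (`age_breaks`), so a 21-group variant splitting 0–4 into <1
  and 1–4 — which changes the `a_x` convention automatically — is equally
  runnable.
* **Person-years.** The sum of annual mid-year counts over a period's
  years (each mid-year count ≈ one person-year).
* **Standardization.** Direct: `per × Σ w_a D_a/PY_a`, Poisson variance
  `per² × Σ w_a² D_a/PY_a²`, normal-approximation 95% CI truncated at
  zero. Weights renormalize within each output group, so sex-specific
  rates use within-sex weights, pooled rates joint age×sex weights, and
  the rate is invariant to rescaling all weights. The standard population
  defaults to the simulated population of the latest year, mirroring the
  use of a recent national structure.
* **Lorenz/Gini.** Deciles accumulate in deprivation order (most → least),
  not re-sorted by observed rate; the numerator is standardized deaths
  (decile rate × decile person-years; crude available behind a flag).
  Gini is the trapezoid polygon on the 11-point curve, checked in the
  tests against an independent shoelace-area oracle to 1e-12.
* **PAF and Monte Carlo.** Expected deaths apply the reference (least
  deprived) decile's age/sex/period rates to every decile's person-years;
  the reference decile's excess is exactly zero, and decile-level excess
  sums to the overall excess. The CI resamples *every* stratum's death
  count as Poisson with mean equal to its observed count — the reference
  strata included, so the counterfactual is re-estimated per replicate —
  and takes percentile bounds over (default) 10,000 replicates.

## Life-table choices

* `a_x = n/2` for closed intervals except the first: 2.0 for a 0–4 group
  (deaths concentrate in infancy), 0.1/1.4 for a <1 / 1–4 split; the open
  interval uses `q = 1`, `L = l/m`. The radix is 100,000. A zero death
  rate in the open interval is an error (the table cannot close).
* The Arriaga decomposition runs most → least deprived without symmetric
  averaging; its age contributions sum to the e0 gap by construction, and
  the tests require that identity to 1e-9 years on random table pairs.
* PYLL is computed on the life-table cohort: `Σ d_x (75 − (x + a_x))/l_0`
  over groups closing at or before the cutoff, i.e. years per person born
  — the reading that yields per-capita magnitudes of a few years. The
  attributable PYLL of a decile subtracts the reference decile's value;
  sex-level summaries weight deciles by person-years. Using observed death
  counts instead of life-table deaths is a different (cohort-free)
  convention, deliberately not mixed in here.

## Numerical and testing notes

Tolerances: the life-table recursion and the Arriaga identity are checked
against independently coded loop oracles to 1e-9; Gini against the polygon
oracle to 1e-12; standardization against an explicit loop to 1e-12. The
Monte Carlo machinery is checked for seeded reproducibility, null coverage
(the PAF interval covers zero in ≥90% of null-gradient runs) and the
1/√(deaths) scaling of interval width.

The validation suite and the reproduction script run the full model at
reduced problem sizes — hundreds to 2,000 sectors instead of 18,000, and
1,000 Monte Carlo replicates instead of 10,000 — chosen so that parameter
recovery is still sharp (index–latent Spearman correlation ≈ 0.99 at 1,000
sectors) while a complete run stays in the tens of seconds. All sizes are
ordinary function arguments, so nothing changes structurally at full scale
beyond memory and time.

## Known limitations

* The factor model assumes one latent dimension; multi-domain deprivation
  (income, education, crime, …) is out of scope.
* Profile imputation compares full observed profiles; it does not model
  missing-not-at-random mechanisms, and remaining missingness simply
  shrinks prevalence denominators.
* No confidence intervals on life expectancy or PYLL are produced, and no
  spatial smoothing or shrinkage is applied to small-sector prevalences
  beyond the population filter.
* The generator's proportional-hazards mortality is an assumption, not an
  estimate; real deprivation gradients vary by age and cause.
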