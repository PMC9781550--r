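---
title: "Modelling pharmacogenetic dose adjustments with global-local shrinkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pharmacogenetic dose adjustments with global-local shrinkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxdose)
```

## The problem

Carriers of reduced- or increased-function *CYP2C19* alleles clear many
psychotropic drugs at different rates than extensive metabolizers (EM), so
equalizing drug exposure across metabolizer phenotypes requires a
quantitative dose adjustment. The published evidence is awkward for the
traditional approach of averaging each (substance, phenotype) cell
separately: group sample sizes run from 1 to several hundred, many
substances are covered by a single exploratory study, some substances turn
out not to be CYP2C19 substrates at all, and older study designs pooled
genotypes across phenotype boundaries (most importantly \*17/\*17 carriers
reported inside the RM group). `pgxdose` implements a model-based
alternative: estimate, per substance, one slope of percent dose adjustment
on a CYP2C19 *activity score*, pooling evidence across phenotypes, while
shrinkage priors keep weakly supported slopes prudentially close to zero.

## The model

The observational unit is a *sampling point*: one study's reported percent
dose adjustment for a (substance, phenotype) pair, relative to the EM
reference (EM = 0; adjusted dose = 100 + adjustment). Stacking sampling
points into `y`, the model is the no-intercept linear model

```
y = X beta + R theta + e
```

* `X` has one column per substance; the entry in row `i` is the activity
  score of row `i`'s phenotype if the column is its substance, else 0.
  `beta[j]` is therefore the slope of adjustment on activity score for
  substance `j`, in percentage points per activity-score unit, and the
  predicted adjusted dose for any score `s` is `100 + beta[j] * s`. There
  is no intercept (the EM reference is pinned at 100%) and no shared
  main-effect column: each slope must earn its distance from zero on its
  own evidence, which is what lets non-substrates shrink all the way to 0.
* `R` holds study-design confounders — by default the RM-pooling flag —
  whose coefficients `theta` are always estimated without shrinkage.
* The residual for a sampling point with group size `n` has variance
  `sigma_w^2 / n + sigma_b^2` (`sampling_point_variance()`). The first
  component weights points by sample size; the second bounds the precision
  any single study can reach, however large, and both scales carry
  informative log-normal(4, 0.25) priors (median 55 percentage points) that
  keep either component from collapsing to zero.

Four prior regimes for the slopes are compared (`fit_adjustment()`,
`compare_regimes()`):

| regime | prior on `beta[j]` | hyperpriors |
|---|---|---|
| `fixed` | N(0, 1000^2) | — |
| `gaussian` | N(0, tau^2) | `tau ~ C+(0, 1)` |
| `horseshoe` | N(0, tau^2 lambda_j^2) | `tau ~ C+(0, 0.1)`, `lambda_j ~ C+(0, 1)` |
| `reg_horseshoe` | N(0, tau^2 xi_j^2) | `xi_j^2 = c^2 lambda_j^2 / (c^2 + tau^2 lambda_j^2)`, `c ~ half-t(df 8, scale 2.5)` |

The horseshoe approximates a two-population model — slopes that are
essentially zero and slopes that are free — which matches a literature
where roughly half the investigated drugs turn out to be substrates. The
regularized variant caps the prior scale of large slopes at `c / tau`
(`regularized_xi_sq()`), preventing extreme estimates from tiny studies;
when `c^2 >> tau^2 lambda^2` it reverts to the plain horseshoe. The
`fixed` regime estimates each substance essentially separately, and the
`gaussian` regime is the classical meta-analytic random effect.

A Student-t slope population (3–4 df) is expressible through the same
machinery but is not part of the headline comparison; in practice it
behaves almost identically to the Gaussian regime.

## Activity scores

Scores are estimated from the data rather than assumed
(`fit_phenotype_factor()`, `derive_activity_scores()`):

1. A factorial model estimates the mean adjustment of each phenotype group
   (EM excluded and pinned at 0), with unshrunk pooling confounders, a
   study-level random effect (half-Cauchy(0, 25) scale), and the same
   two-component variance. Non-substrate substances are excluded first.
2. The RM-pooling flag has a large, identifiable upward bias on reported
   RM adjustments, so the score *scale* is derived from a refit that
   excludes RM-pooled rows.
3. Each group's raw score is its mean adjustment divided by the absolute
   IM mean (computed per posterior draw, so IM is exactly −1 with a
   degenerate interval and EM is exactly 0). The score of one \*17 allele
   averages the RM estimate and half the UM estimate; the final working
   map rounds to one decimal and sets UM = 2 × RM exactly. The default map
   is PM −2, IM −1, EM 0, RM 0.8, UM 1.6. The unrounded derivation is kept
   alongside the rounded map.

Because the raw scores are ratios against the IM estimate, they are
exactly invariant to rescaling all adjustments by any positive constant —
a property the tests assert rather than assume.

Two diagnostics guard the linearity assumption. `check_linearity()` adds
quadratic and cubic score terms, and a separate extra slope for
\*17-carrying phenotypes, all with flat priors; a term whose 90% interval
excludes zero flags a deviation. `check_log_transform()` refits the factor
model on `100 * log(dose/100)` (units comparable to percentage points) and
compares posterior-mean residual skewness across scales; the raw scale is
kept unless its residuals are clearly asymmetric (|skewness| > 0.5, a fixed
numeric proxy for what is usually a visual judgement) and the log scale
improves on it.

`screen_study_properties()` asks the complementary question for slope-level
biases: for each study property (pooling of \*17 carriers into EM, AUC/CL
versus Css readouts, healthy versus patients, single versus multiple dose)
it estimates a property-by-score interaction; a property is recommended
for the confounder set only when its interval excludes zero. The
RM-pooling flag is always retained regardless, since its group-level bias
is established upstream. The default final confounder set is `pool_rm17`
alone.

## Computation

All models are sampled by Gibbs (JAGS via `rjags`). Half-Cauchy and half-t
hyperpriors are expressed through their inverse-gamma scale-mixture
representations, which give conjugate updates and mix far better than
sampling truncated scales directly; a test checks the represented priors
against the closed-form half-Cauchy and half-t quantile functions. Two
numerical choices matter:

* **Funnel starts.** A Gibbs chain started near `tau = 0` can stay stuck
  there, because small `tau` keeps the slopes near zero and near-zero
  slopes keep `tau` small. Chains are therefore started with overdispersed
  global scales (tau0 cycling through 30, 5, 100, 15, 60), so sticking
  shows up as disagreement between chains rather than a silently narrow
  posterior.
* **Reliability flag.** A fit is flagged non-reliable when the split-chain
  convergence statistic exceeds 1.01 on any slope, confounder effect or
  variance scale. Downstream consumers (`predict()`, the pipeline
  manifest) surface the flag instead of silently using the draws.
  Gradient-based samplers report divergent transitions as an additional
  signal; a Gibbs sampler has no analogous event, so the flag rests on
  convergence statistics and effective sample sizes.

Defaults are 3 chains, 1000 adaptation + 1000 warmup iterations and 2000
retained draws per chain; chain RNG seeds derive deterministically from
one integer seed, so identical configurations reproduce identical tables
bit for bit.

## The synthetic generator and what it does (not) show

`simulate_sampling_points()` draws datasets from exactly the generative
process the model assumes: per-substance slopes that are zero with
probability 0.5 and otherwise N(20, 10); study counts between 1 and 8 per
substance; group sizes log-uniform on 1–507 (the mix of tiny panels and
large TDM cohorts); residuals from the two-component variance with true
scales sigma_w 55 and sigma_b 20; \*17 genotyping in half the studies,
with RM-pooling in a quarter of those and a true pooling bias of +38
percentage points (IM inclusion +2); and a true \*17 allelic activity of
0.79, so the generated RM/UM effects are weaker than the PM/IM effects.
EM rows are emitted with adjustment 0 to exercise the exclusion logic.
`simulate_example_dataset()` instantiates a fully synthetic stand-in for
the psychotropic CYP2C19 literature with 18 named substances and the
published per-substance study counts; the strongest slopes sit on the
SSRI-class substrates and the four known non-substrates have slope exactly
zero.

Recovery tests on these data show that the estimation machinery inverts
the assumed generative process; they cannot show that real studies follow
it. In particular the generator draws independent Gaussian residuals with
a common sigma_w — real designs differ systematically in precision beyond
sample size — and emits adjustments directly rather than deriving them
from pharmacokinetic readouts.

Three calibration facts, established while designing the validation suite,
are worth recording:

* Under the regime's own population assumption (all slopes drawn from a
  zero-centred Gaussian), the `gaussian` regime's 90% intervals cover the
  truth at the nominal rate (90.0% over 320 slopes in the design run).
* Under the literature-like default truth — a spike at zero mixed with
  slopes centred at +20 — the same intervals *undercover* nonzero slopes
  (~70%): the global scale adapts to the pooled spread of a mixture the
  Gaussian population does not describe, and zero-centred shrinkage biases
  the estimates downward. That is the deliberately prudential behaviour of
  shrinkage, not a sampler defect, and it is quantified separately by the
  shrinkage benchmark (a lone n = 8 study with a large raw effect is
  shrunk by about a third under the regularized horseshoe).
* The plain horseshoe's heavy tails let a single large lone signal escape
  shrinkage almost entirely; the slab of the regularized variant is what
  moderates such cases. This is why the regularized horseshoe is the
  preferred reporting regime.

## Problem sizes used in the validation suite

The test suite and `scripts/acceptance.R` use a stand-in with 16
substances sharing a slope of 25, 8 studies per substance and constant
group sizes of 50 (about 290 modelled sampling points) for score and
pooling recovery; a 20-substance mixed-density benchmark for the shrinkage
ordering; 60–100 replicates of an 8-substance configuration for interval
calibration; and a 30-point three-substance design with known residual
scales for the closed-form GLS cross-check. These sizes keep every posterior
quantity's Monte-Carlo error well below the effect sizes being checked.

## Known limitations

* Conversion from primary pharmacokinetic readouts (AUC, clearance, Css
  ratios) to percent adjustments happens upstream; the package stores the
  readout type only as a screening covariate.
* Phenotypes are the five discrete groups; allele-resolved diplotype
  modelling is out of scope, though `predict()` accepts any intermediate
  activity score.
* The between-study variance is modelled as exchangeable across designs;
  the single- versus multiple-dose contrast is screened as a diagnostic
  but not given its own variance component.
* Whether zotepine belongs with the four excluded non-substrates is
  genuinely ambiguous in the source literature;
  `non_substrate_substances(include_zotepine = TRUE)` makes the wider set
  available, and the default keeps the narrower one.
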