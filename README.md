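# pgxdose

Quantitative pharmacogenetic dose adjustment from published pharmacokinetic
study data, for clinical pharmacologists and biostatisticians working on
CYP2C19-dependent dosing.

Published evidence on how *CYP2C19* metabolizer phenotypes (PM, IM, EM, RM,
UM) change drug exposure is sparse and heterogeneous: group sizes run from
1 to 507, many substances have a single exploratory study, and older
designs pooled genotypes across phenotype boundaries. Averaging each
(substance, phenotype) cell separately — the traditional "means model" —
cannot extrapolate to unobserved phenotypes and overreacts to small
studies. `pgxdose` instead models, per substance, one slope of percent
dose adjustment on a CYP2C19 *activity score* (EM = 0, one inactive allele
= −1), pooling evidence across phenotypes:

    y = X beta + R theta + e,   e_i ~ N(0, sigma_w^2 / n_i + sigma_b^2)

where `y` stacks the reported percent adjustments ("sampling points"),
`X` carries activity scores per substance (no intercept: the EM dose is
pinned at 100%), `R` holds study-design confounders (unshrunk coefficients
`theta`, by default the RM-pooling flag), and the two-component residual
variance weights each point by its group size `n_i` while bounding the
precision any single study can attain. Per-substance slopes `beta_j` are
estimated under four prior regimes — fixed effects, a Gaussian random
effect (`beta_j ~ N(0, tau^2)`, `tau ~ C+(0,1)`), the horseshoe
(`beta_j ~ N(0, tau^2 lambda_j^2)`, `lambda_j ~ C+(0,1)`,
`tau ~ C+(0,0.1)`), and the regularized horseshoe, whose slab scale
`c ~ half-t(df 8, scale 2.5)` caps the local variance at
`xi_j^2 = c^2 lambda_j^2 / (c^2 + tau^2 lambda_j^2)` and so prevents
extreme slopes from tiny studies. Activity scores themselves are estimated
from the data by a phenotype-factor model and rescaled so IM = −1, with
the \*17 allelic score averaged from the RM and UM groups. Sampling is by
Gibbs (JAGS), with half-Cauchy/half-t hyperpriors represented as
inverse-gamma scale mixtures.

The package also ships the traditional weighted-means baseline, linearity
and log-transformation diagnostics, study-property screening, a synthetic
sampling-point generator with ground truth for recovery and calibration
studies, and a reproducible end-to-end pipeline. See
`vignettes/dose-adjustment-methods.Rmd` for the full model account.

## Worked example

The per-sampling-point tables behind published adjustment studies are
rarely redistributable, so the package includes a fully synthetic stand-in
emulating the structure of the psychotropic CYP2C19 literature (18
substances, published per-substance study counts, known true slopes):

```r
library(pgxdose)
sim <- simulate_example_dataset(seed = 2022)
pts <- apply_exclusions(sim$points, drop_em = TRUE,
                        drop_substances = non_substrate_substances())
fit <- fit_adjustment(pts, prior = "reg_horseshoe", seed = 1)
print(fit)
#> Dose-adjustment model (reg_horseshoe prior), 97 sampling points, 14 substances
#> Per-substance slopes (percentage points per activity-score unit,
#> 90% credibility intervals):
#>           term median  lower upper
#>  amitriptyline  15.99   6.54 25.21
#>     citalopram  16.44   5.20 28.28
#>   clomipramine   3.97  -6.39 16.38
#>      clozapine   8.74  -2.51 20.83
#>       diazepam   8.44  -5.34 24.28
#>       doxepine  17.45   1.01 35.57
#>   escitalopram  26.77  18.49 34.34
#>       etizolam   9.59  -4.13 25.17
#>     imipramine   8.15  -1.06 18.01
#>    moclobemide   0.83 -17.11 19.90
#>     sertraline  14.29   2.82 25.67
#>   trimipramine   6.93  -3.16 18.46
#>    venlafaxine  27.78  13.66 42.17
#>       zotepine   4.62 -11.94 25.04
```

A slope is the change in adjusted dose per activity-score unit: the
escitalopram slope of ≈ 27 percentage points (true generating value 32)
says a poor metabolizer (score −2) needs roughly half the label dose,
and the interval is tight because eleven studies back it. Substances with
a lone small study (diazepam, etizolam) keep wide intervals straddling
zero — shrinkage refuses to promote them. Doses follow directly from the
slope draws:

```r
predict(fit, "escitalopram")
#> Adjusted dose (% of label dose):
#>     substance phenotype score dose_pct lower upper
#>  escitalopram        PM  -2.0     46.5  31.3  63.0
#>  escitalopram        IM  -1.0     73.2  65.7  81.5
#>  escitalopram        RM   0.8    121.4 114.8 127.5
#>  escitalopram        UM   1.6    142.8 129.6 154.9
```

`compare_regimes()` sets the four regimes side by side on identical data,
`fit_phenotype_factor()` + `derive_activity_scores()` estimate the score
map itself, and `run_pipeline(pipeline_config(...))` executes the whole
sequence and writes CSV/JSON outputs with a reproducibility manifest.

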