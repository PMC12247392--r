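# mrpraking

Small-area prevalence estimation by **multilevel regression with raking**:
a hybrid of MRP (multilevel regression and post-stratification) and
iterative proportional fitting for the common situation where the census
releases only *marginal* population distributions — e.g. a joint age × sex
table plus one-way education and race/ethnicity tables — rather than the
full joint distribution that classical MRP requires.

Who this is for: biostatisticians and public-health analysts who need
county-level (or other small-area) prevalence estimates from a survey that
covers only a few large areas, such as metro-area surveillance subsamples
of a state telephone survey.

## The method

A random-intercept logistic model is fitted (unweighted) to the survey
microdata:

```
logit(p_ij) = x_ij' β + z_i' η + μ_i,   μ_i ~ N(0, σ_μ²)
```

with `x_ij` the dummy-coded individual stratification factors, `z_i`
continuous area covariates (e.g. percent below poverty), and `μ_i` an area
random intercept, estimated by exact adaptive Gauss–Hermite quadrature.
Then for each target area `i`:

1. predict the outcome probability `p̂_i(jk…)` for every stratification
   cell (posterior-mode random effect for sampled areas, `μ* = 0` or the
   population-averaged probability for unsampled ones);
2. estimate joint cell population counts `N̂_i(jk…)` by raking a seed
   table to the area's known margins — margins may sit on arbitrary factor
   subsets, cells with no sampled respondents included;
3. post-stratify: `p̂_i = (1/N_i) Σ N̂_i(jk…) · p̂_i(jk…)`;
4. attach stratified case-resampling bootstrap percentile intervals
   (respondents resampled within areas; census counts held fixed).

When the full joint is supplied as a single margin, step 2 copies it and
the estimator reduces exactly to classical MRP. Validation helpers compute
MSE, mean absolute difference, Pearson/Spearman correlations, quartile
summaries, and CI-containment checks against direct survey estimates.

## Worked example

Everything below runs offline: the package ships a generator that
simulates a state-scale study (dependent stratification factors, a
logistic outcome model with county random effects, and a survey that
observes only the largest areas). Here the fast 6-area profile:

```r
library(mrpraking)

cfg   <- tiny_generator_config(seed = 42)
study <- simulate_study(cfg)          # population, margins, survey, truth

est <- bootstrap_ci(study$survey, study$covariates, study$spec,
                    cfg$scheme, study$margins, B = 200, seed = 1)
cbind(round(as.data.frame(est)[2:4] * 100, 1), N = est$N)
#>        estimate ci_lower ci_upper    N
#> area01     34.5     24.7     39.8 9924
#> area02     51.5     42.6     60.2 3770
#> area03     28.7     20.6     36.5 5995
#> area04     52.0     43.5     60.6 6861
#> area05     36.7     32.1     49.2 6120
#> area06     26.0     17.4     35.1 4742
```

Only three of these six areas were surveyed (n = 150/120/100), yet every
area gets an estimate; the intervals are 95% bootstrap percentile
intervals. Comparing with the simulated truth:

```r
truth <- study$truth
compare_estimates(setNames(100 * est$estimate,      est$area_id),
                  setNames(100 * truth$prevalence,  truth$area_id))
#> Validation over 6 areas
#>   MSE 16.2  MAD 2.9
#>   Pearson 0.963  Spearman 0.943
#>         Min  25% Median  75%  Max  IQR Range
#> model  26.0 30.2   35.6 47.8 52.0 17.6    26
#> direct 26.6 36.1   39.2 49.1 54.6 13.0    28
#>   model range 26.0–52.0%, direct range 26.6–54.6%
```

The estimates recover the cross-area ranking (Spearman 0.94) with a mean
absolute error of 2.9 percentage points at these small sample sizes.

The same validation machinery reproduces a published five-metro internal
validation shipped with the package — model-based versus direct survey
estimates of adult past-year dental visits:

```r
tab <- mmsa_benchmark()
compare_estimates(setNames(tab$model_est,  tab$area_id),
                  setNames(tab$direct_est, tab$area_id),
                  direct_ci = data.frame(area_id = tab$area_id,
                                         lower = tab$direct_lower,
                                         upper = tab$direct_upper))
#> Validation over 5 areas
#>   MSE 4.0  MAD 2.0
#>   Pearson 0.994  Spearman 1.000
#>         Min  25% Median  75%  Max IQR Range
#> model  62.8 65.0   68.3 69.6 71.0 4.6   8.2
#> direct 64.8 66.6   70.9 71.4 72.9 4.8   8.1
#>   model range 62.8–71.0%, direct range 64.8–72.9%
#>   model estimates inside direct CI: 5 of 5
```

MSE 4.0, mean absolute difference 2.0 percentage points, and all five
model-based estimates inside the direct estimates' 95% CIs.

## Command line

A thin CLI wraps the same functions (`inst/cli/mrpraking`):

```sh
inst/cli/mrpraking simulate --profile tiny --seed 5 --out demo/
inst/cli/mrpraking rake --scheme demo/scheme.yaml \
    --margins demo/margins.csv --out demo/raked.csv
inst/cli/mrpraking estimate --config config.yaml   # fit→rake→poststratify→bootstrap
inst/cli/mrpraking validate --model est.csv --direct direct.csv --out report.json
```

`estimate` is driven by a single YAML config (survey/margins/covariates
paths, model spec, raking and bootstrap options) and writes
`estimates.csv` plus a machine-readable run manifest recording seeds,
tolerances and convergence. File schemas are documented in
`?read_survey`, `?read_margins`, `?read_covariates`.

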