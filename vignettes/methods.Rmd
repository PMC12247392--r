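---
title: "Small-area prevalence estimation by multilevel regression with raking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area prevalence estimation by multilevel regression with raking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpraking)
```

## The estimation problem

Health surveillance surveys such as the BRFSS are designed for national and
state estimates; their metro-area subsamples cover only a handful of large
counties, yet health departments need estimates for *every* county.
Multilevel regression and post-stratification (MRP) addresses this by
fitting a hierarchical outcome model to the survey, predicting the outcome
probability for every demographic cell of every county, and averaging those
predictions with census cell counts as weights. Its Achilles heel is the
weights: classical MRP needs the full *joint* population distribution of
the stratification factors in every area, while census products typically
release only *margins* — for example a joint age × sex table plus one-way
education and race/ethnicity tables.

`mrpraking` implements a hybrid estimator that closes this gap. The joint
cell counts are *estimated* from the available margins by raking (iterative
proportional fitting), and post-stratification proceeds against the raked
counts. The pipeline is:

1. fit a random-intercept logistic model to the survey microdata;
2. predict the outcome probability for each cell of each target area;
3. rake each area's margins to estimated joint cell counts
   $\hat N_{i(jk\ldots)}$;
4. post-stratify:
   $\hat p_i = \frac{1}{N_i}\sum_{jk\ldots}\hat N_{i(jk\ldots)}\,
   \hat p_{i(jk\ldots)}$;
5. attach bootstrap confidence intervals and validate against direct
   survey estimates where available.

## The outcome model

For respondent $j$ in area $i$ with binary outcome $y$,

$$\operatorname{logit}(p_{ij}) = \mathbf{x}_{ij}'\boldsymbol\beta +
  \mathbf{z}_i'\boldsymbol\eta + \mu_i, \qquad
  \mu_i \sim \mathcal N(0, \sigma_\mu^2),$$

where $\mathbf{x}_{ij}$ dummy-codes the individual stratification factors
(the first declared level of each factor is the reference — any full-rank
coding yields identical predictions), $\mathbf{z}_i$ holds continuous
area-level covariates such as the percent of population below poverty, and
$\mu_i$ is an area random intercept. The fit is *unweighted*: every
respondent counts once; survey weights present in the input are ignored
with a warning.

### Estimation

Because the model has a single scalar random intercept, the marginal
likelihood is a product of one-dimensional integrals, one per sampled
area. `fit_multilevel_logistic()` maximizes it directly:

* each area's integral is evaluated by **adaptive Gauss–Hermite
  quadrature** (default 15 nodes): nodes are centered at the area's
  posterior mode (found by a safeguarded scalar Newton iteration, the
  integrand being globally log-concave) and scaled by the local curvature;
* the optimizer is `nlminb` with analytic gradients; design columns are
  scaled to $O(1)$ internally so continuous covariates do not dominate the
  curvature, and coefficients are mapped back afterwards;
* $\sigma_\mu$ is optimized as $\log\sigma_\mu$ with a floor of $10^{-4}$;
  a fit at that floor is the boundary case and then reproduces an ordinary
  logistic regression;
* convergence requires the optimizer's own criterion (relative tolerance
  $10^{-10}$, iteration cap 500) or, when the optimizer reports a spurious
  code on a flat ridge (common in $\log\sigma_\mu$ when the random effect
  is weakly identified), a stationarity check on the score with tolerance
  $\max(10^{-3},\,10^{-4} n)$ — the score being a sum of $n$ terms; one
  cold restart from the ordinary-logistic solution is attempted first;
* fits with any coefficient beyond $\pm15$ on the scaled design, or with a
  degenerate outcome (all $y$ equal), abort with a separation error;
* standard errors come from a central-difference Hessian of the analytic
  gradient (observed information).

The number of quadrature nodes barely matters on realistic data (the test
suite checks 7 versus 25 nodes agree to $10^{-4}$); 15 is a conservative
default. Setting `random_intercept = FALSE` in `model_spec()` switches to
the fixed-effect variant — area indicator dummies fitted by `glm` — in
which area-level covariates are dropped as collinear and predictions exist
only for sampled areas.

### Predicting unsampled areas

Estimates are produced for all target areas, but only a few are surveyed.
For a sampled area the random-effect term in the cell prediction is its
posterior mode. For unsampled areas no data-informed prediction of
$\mu_i$ exists, and `predict_cell_probabilities()` exposes three policies:

* `conditional_blup` (default): $\mu^\ast = 0$, the conventional best
  predictor for an unobserved group;
* `conditional_zero`: $\mu^\ast = 0$ for every area;
* `marginal`: the population-averaged probability
  $\int \operatorname{logit}^{-1}(\cdot + u)\,\phi(u; 0, \hat\sigma_\mu^2)\,du$,
  computed by quadrature. Because the inverse logit is nonlinear these are
  not identical; `marginal` shrinks predictions toward one half by an
  amount growing with $\hat\sigma_\mu$.

Which convention real analyses use is rarely reported; both are available
and the default is the conditional one, which degenerates to `marginal`
exactly when $\hat\sigma_\mu = 0$.

## Raking with margins on arbitrary factor subsets

`rake()` starts from a seed table over the full cell grid and cyclically
scales it to match each margin in declared order. A margin may cover any
subset of factors — one-way tables and multi-way joints mix freely, which
is exactly the census situation (a joint age × sex table plus one-way
education and race tables). Details that matter:

* **Convergence**: iteration stops when the maximum absolute deviation of
  every fitted margin from its target is below `tol * N_i` (default
  `tol = 1e-8`, tight enough that post-stratified estimates are insensitive
  at six decimals) or after `max_iter = 1000` cycles. Non-convergence —
  possible when independently rounded margins are mutually infeasible —
  returns the final iterate flagged `converged = FALSE` with a warning,
  never an exception: estimates should degrade gracefully and visibly.
* **Structural zeros**: cells inside a zero-count margin slice are fixed
  at exactly 0 before iterating, avoiding 0/0 rescaling.
* **Seeds**: the default `uniform` seed gives every non-structurally-zero
  cell mass 1, so the method covers *all* weighting cells, including those
  with no sampled respondents — the key extension over approaches that
  rake only the observed cells. The alternative
  `sample_counts_plus_epsilon` policy seeds with the area's observed
  survey cell counts plus $\varepsilon = 0.5$, pulling the solution toward
  the empirical composition while still giving empty cells mass.
* With a uniform seed the fixed point is the minimum-discrimination-
  information table consistent with the margins; when margins partition
  the factors this is the product (independence) table, and when the full
  joint is supplied as a single margin raking degenerates to a copy — the
  pipeline then *is* classical MRP, which the test suite verifies to
  $10^{-10}$.
* Margin totals must agree across margins of one area within relative
  $10^{-6}$ (census margins are often independently rounded); the
  `rescale` option proportionally reconciles each margin to the mean total
  instead of erroring.

All tables share one canonical cell order — row-major over the declared
factor order (last factor fastest) — so no silent transposition is
possible between the raking, prediction and post-stratification stages.

## Post-stratification and aggregation

`poststratify()` is the count-weighted mean above; it checks that the
prediction and count tables cover identical (area, cell) sets and reports
the symmetric difference otherwise. `aggregate_areas()` combines areas
into larger reporting units (e.g. counties into metro areas for internal
validation) with population weights $N_i$ taken from the raked
(census-derived) totals — the only weighting consistent with the
post-stratification logic, since survey sample sizes reflect design, not
population.

## Bootstrap confidence intervals

`bootstrap_ci()` resamples *respondents with replacement within each
sampled area* (area sample sizes fixed), refits the model, re-predicts,
and post-stratifies against the *fixed* raked counts; the interval is the
percentile interval of the replicate estimates. Design choices:

* census counts are treated as known constants, matching their role as
  external population totals, so raking is not repeated per replicate;
* areas are fixed strata: resampling areas would break the survey's
  design structure and with five sampled areas would be hopelessly coarse;
* the percentile interval is the simplest interval consistent with a
  stated confidence level; BCa would be a possible refinement;
* one master seed spawns per-replicate sub-seeds, recorded in the output
  metadata, so intervals are bit-reproducible;
* replicates whose refit fails are dropped and counted; more than 10%
  failures is an error unless explicitly tolerated.

**Known limitation.** For *unsampled* areas the point prediction sets
$\mu^\ast = 0$, and no amount of respondent resampling reflects the
unobserved area's own random-effect draw. The resulting intervals for
unsampled areas are narrower than the true predictive uncertainty by
roughly $\sigma_\mu/4$ on the probability scale, and the coverage
simulation in the test suite shows exactly this pattern: near-nominal
coverage for sampled areas, undercoverage for unsampled ones. Repairing
this would require a parametric bootstrap that redraws $\mu_i$, which is
deliberately out of scope here; users quoting intervals for unsampled
areas should treat them as conditional on $\mu_i = 0$.

## The synthetic-data generator

Real inputs for this class of analysis are restricted-access, so the
package ships a generator (`generator_config()`, `simulate_study()`) that
reproduces the *statistical structure* the method assumes, making every
stage testable offline:

* **Population composition**: per-area joint cell counts are drawn
  multinomially from a log-linear model with area-specific main effects
  and shared pairwise interactions of strength `dependence` (default 0.3).
  The interactions make the factors *dependent*, so the independence
  product of the margins is measurably wrong — without this, raking would
  never be tested against its reason for existing. The test suite checks
  that raking's cell-count error against the true joint shrinks to the
  multinomial noise floor as `dependence` goes to 0.
* **Outcome model**: true cell probabilities follow the logistic model
  with intercept 0.4 (baseline prevalence ≈ 60%, a realistic dental-visit
  rate), evenly spaced factor effects between −0.3 and 0.3 on the logit
  scale, a strong area-covariate effect (`eta = -0.05` per percentage
  point of poverty, with poverty spanning roughly 3–30%), and a modest
  residual area effect `sigma_mu = 0.15`. The split between covariate and
  residual variation mirrors analyses in which the poverty covariate
  explains most of the cross-county spread; it also determines how hard
  the estimation problem is (see below).
* **Survey**: the five largest areas are surveyed — metro-area
  surveillance in miniature — with default sample sizes
  (3400, 830, 1512, 882, 533), a total of $n = 7157$. Respondents are
  drawn across cells proportionally to the true counts, optionally tilted
  by an unequal-probability factor (the default profile tilts by
  education, emulating a telephone survey's education skew); outcomes are
  Bernoulli draws from the true cell probabilities. When an area's sample
  size equals its population the draw is the exact census of that area.
* **Margins**: exact sums of the true joint over the configured subsets
  (default: joint age × sex, one-way education, one-way race).
* A **tiny profile** (`tiny_generator_config()`: 6 areas, 3 sampled,
  2 × 2 × 2 cells, sample sizes 150/120/100) is the unit-test default.

Everything is a deterministic function of one master seed.

What the generator does *not* emulate: telephone-frame nonresponse,
multilingual interviewing, design weighting, and geographic crosswalks
between survey and target geographies. Passing tests therefore demonstrate
that the *estimator* behaves as designed under its own assumptions — not
that those assumptions hold for any particular real survey.

### A fragility worth knowing about

The area-level coefficient $\eta$ is identified from as many observations
as there are *sampled areas* — five, in the flagship configuration. Its
standard error is roughly
$\sqrt{\sigma_\mu^2 + 4/\bar n}\,/\,(\mathrm{sd}(z)\sqrt{5})
\approx 0.03$ under the default settings, against a true value of 0.05:
in a small fraction of simulated studies the estimated poverty effect
flips sign, and because 53 of 58 areas are ranked almost entirely by their
covariate value, those studies produce badly inverted area rankings. This
is not an artifact of the implementation (the exact-likelihood fit is
verified against an independent GLMM implementation to $10^{-5}$) but a
real feature of estimating an area-level slope from five areas; analysts
should check the sign and standard error of $\hat\eta$ before trusting
cross-area rankings dominated by a covariate.

## Simulation sizes used by the test suite

The acceptance-style tests run, as this package's own choice of problem
sizes: coefficient recovery over 100 tiny-profile replicates; area-ranking
recovery over 20 state-scale replicates (58 areas × 240 cells,
$n \approx 7157$); bootstrap calibration over 40 tiny-profile datasets at
$B = 200$ resamples; and raking-oracle equivalence over 20 random two- and
three-factor fixtures. A full-scale bootstrap for production use would
conventionally take $B = 1000$.

## Other conventions

* Quartiles and percentile intervals use linear interpolation between
  order statistics (`quantile` type 7), so summary tables are exactly
  reproducible.
* Validation metrics (`compare_estimates()`) are computed on the scale of
  their inputs; use the percentage scale to match conventional reporting
  (MSE then carries %²-units but is conventionally printed with a percent
  sign). Spearman uses average ranks for ties; zero-variance series yield
  an explicit "undefined correlation" flag, never a silent 0.
* CI containment checks (`containment_check()`) use closed intervals: an
  estimate exactly on a bound counts as contained.
* Survey records with levels outside the scheme are rejected, not
  imputed.
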