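---
title: "Small-area estimation of district disease prevalence from two-stage cluster surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-area estimation of district disease prevalence from two-stage cluster surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(districtsae)
```

## The estimation problem

National household health surveys such as India's NFHS sample a few
dozen clusters (villages or census enumeration blocks) per district and
a few dozen eligible adults per cluster.  Raw district proportions of a
binary outcome -- here hypertension and diabetes among adults aged
15--49, classified from measured biomarkers -- are therefore dominated
by sampling noise, and the noise differs wildly between districts.
Small-area estimation stabilises these estimates by borrowing strength
across the survey's full nesting: individuals within clusters within
districts within states.

`districtsae` implements the complete workflow: outcome classification
from biomarker readings, a four-level random-intercept Bayesian
logistic model fitted by exact Gibbs sampling, precision-weighted
cluster predictions averaged into district prevalences, and the
between-wave comparison analytics (percentage-point changes, change
bands, baseline-by-direction quadrants, cross-outcome correlation).  A
calibrated synthetic survey generator with known ground truth makes
every stage testable without access to restricted survey microdata.

## Outcome definitions

Classification uses the WHO cutoffs, inclusive, invariant to age and
sex:

* hypertension: systolic blood pressure $\ge$ 140 mmHg and/or
  diastolic $\ge$ 90 mmHg;
* diabetes: random blood glucose $\ge$ 200 mg/dL.

Blood pressure is measured three times per participant.  How three
readings become one is a protocol choice the survey documentation
settles but analysis reports rarely state; the package default follows
the DHS biomarker convention of averaging the 2nd and 3rd readings
(the first reading is systematically elevated), with `mean_all` and
`last` available through `combine_bp_readings(rule = )`.  The choice is
surfaced in the configuration and logged in pipeline manifests because
prevalence near the cutoff is sensitive to it.

Eligibility is age 15--49 inclusive at both ends.  Persons missing the
required biomarkers are excluded and tallied by reason
(`filter_eligible()`); treated-but-controlled individuals are *not*
reclassified as positive -- the definitions are purely biomarker-based,
which makes estimates conservative where medication control is common.

`weighted_prevalence()` reproduces descriptive survey-weighted
prevalence: the point estimate is $100\sum w_i y_i / \sum w_i$ and the
95% interval uses first-stage PSU linearization (influence values
summed within clusters, between-cluster variation estimating the
variance), the standard complex-survey approach when the analysis
report does not state its interval method.  With all weights equal the
estimate reduces exactly to the unweighted proportion.

## The four-level model

For person $i$ in cluster $j$, district $k$, state $l$:

$$\mathrm{logit}\,P(y_{ijkl} = 1) = \beta_0 + u_{jkl} + v_{kl} + f_l,$$

$$u_{jkl} \sim N(0, \sigma^2_u), \quad v_{kl} \sim N(0, \sigma^2_v),
\quad f_l \sim N(0, \sigma^2_f),$$

with mutually independent random intercepts.  $\sigma^2_u$ is
within-district between-cluster variation, $\sigma^2_v$ within-state
between-district variation, $\sigma^2_f$ between-state variation.  The
person level contributes the standard-logistic residual with fixed
variance $\pi^2/3 \approx 3.29$ (`level1_variance()`), the yardstick
against which the variance components are read.  There are no
covariates: the model is an intercept-plus-nesting smoother, fitted
separately per outcome, sex and survey wave, so that no cell borrows
strength from another.

### Sampling

`hlogit4()` runs an exact Gibbs sampler via Polya-Gamma data
augmentation: one auxiliary $\omega_i \sim PG(1, \psi_i)$ per person
(drawn with the alternating-series rejection sampler, validated in the
tests against the closed-form moments) turns every full conditional
Gaussian, and each variance component has an inverse-gamma full
conditional.  Because the model has no covariates, all persons of a
cluster share one linear predictor and the auxiliary draws enter the
conditionals only through per-cluster sums; the implementation uses
this to run the whole cycle on cluster aggregates.

Defaults, all configurable:

* priors: improper flat on $\beta_0$; Inv-Gamma(0.001, 0.001) on each
  variance component -- the conventional diffuse default of multilevel
  MCMC software.  This prior is known to pull small variance components
  toward zero; with only 15 states in the validation design the
  state-level posterior can concentrate well below a small truth for
  unlucky realisations, which is visible (and quantified) in the
  parameter-recovery results rather than hidden by a tighter prior.
* chain: 500 burn-in, 5000 monitored iterations, thinning 1, single
  chain.  Split-half $\hat R$, autocorrelation-time ESS and Monte-Carlo
  standard errors are reported by `summary()` / `mcmc_diagnostics()`.
* starting values: intercept at the empirical log-odds (clamped to
  $\pm\,\mathrm{logit}(1/(n+1))$ for degenerate all-0/all-1 responses),
  residuals at zero, variances at 0.1 -- an approximate-mode start.
  Starting values only affect burn-in, not the stationary distribution,
  so a generous burn-in substitutes for a preliminary quasi-likelihood
  fit.
* update order is fixed ($\omega$, $\beta_0$, $u$, $v$, $f$,
  variances) and the model data are put in canonical person-ID order
  before any draw, so a seeded fit is bit-reproducible and invariant to
  input row order.

### Correctness reference

`quad_reference()` computes posterior means for the smallest instance
(one state, one district, one cluster) by deterministic numerical
integration: the variance components are integrated out analytically
(giving scaled-t marginals for the residuals and a closed-form
conditional mean for each $\sigma^2$), the prior density of
$u + v + f$ is built by grid convolution, and the remaining
two-dimensional integral is evaluated on a fine trapezoidal grid.  It
involves no Monte Carlo, so agreement of the Gibbs posterior means
within Monte-Carlo error (checked in the acceptance tests at 3 MCSE) is
a genuine two-route validation.  The reference requires a proper prior
with `prior_a > 1/2`; the tests use Inv-Gamma(3, 2), under which all
posterior means exist.

## Precision-weighted predictions and district prevalence

The posterior mean of each random intercept is its precision-weighted
(shrunken) estimate: a cluster observed with little information is
pulled strongly toward its district's level, and so on up the
hierarchy.  `predict()` returns cluster-level probabilities; the
default plug-in form is

$$\hat p_{jkl} = \mathrm{logit}^{-1}(\bar\beta_0 + \bar u_{jkl} +
\bar v_{kl} + \bar f_l),$$

matching the tradition of the multilevel-modelling software this
workflow descends from.  The alternative `type = "draws"` averages
$\mathrm{logit}^{-1}$ over the retained draws; the two agree closely
when cluster posteriors are tight (checked in the tests at 0.5
percentage points under large-cluster, modest-variance conditions) and
the draw-averaged form is preferable when posteriors are wide and the
inverse-logit nonlinearity matters.

`district_prevalence()` is deliberately simple: the district estimate
(in %) is the *unweighted* mean of its member clusters' predicted
probabilities.  Clusters count equally regardless of size because the
size-related uncertainty has already been absorbed by shrinkage at the
cluster level.  `distribution_summary()` reports median, quartiles,
IQR and 1.5 x IQR box-plot fences; quartiles use the
linear-interpolation convention (R `quantile` type 7), stated
explicitly because published IQR values depend on the convention.

## Two waves, crosswalk, trends

District boundaries change between survey waves.  Comparability is
restored by a supplied cluster-to-district crosswalk onto a common
target frame (`apply_crosswalk()`, validated by
`validate_crosswalk()`); the package never derives the crosswalk from
GIS polygons -- that linkage is an input.

`compute_change()` gives exact percentage-point differences (wave 2
minus wave 1) over the shared district set.  `change_band()` uses the
inclusive stable band $[-2.49, 2.49]$ -- the published legend
thresholds verbatim, not rounded to 2.5.  `quadrant_analysis()`
classifies districts by baseline side (above the *unweighted mean* of
wave-1 district prevalences -- the district-level average, which
differs from the person-weighted prevalence) and direction of change.
Two tie rules are explicit rather than silent: districts exactly at the
baseline mean count as not-above, and exact-zero changes are tallied
separately instead of being forced into a direction.  The published
counts they mirror do not themselves tile the frame for every cell
(one sex-outcome cell sums to 718 of 720 districts), so the package
reports complete tallies and leaves reconciliation to the reader.
`cross_outcome_correlation()` reports Pearson (optionally Spearman)
correlation between two outcomes' district prevalences over shared
districts.

## The synthetic survey generator

`sim_config()` / `simulate_two_waves()` emulate the features of the
real design that matter to the estimator, with every ground-truth
quantity known:

* nesting and PPS-like size heterogeneity: cluster target sizes are
  log-normal truncated to [10, 60] persons (an analysis-sample take on
  DHS cluster yields); defaults of 15 states x 8 districts x 10
  clusters x ~30 persons give the validation design used throughout
  the tests;
* true components $\sigma^2_u = 0.3$, $\sigma^2_v = 0.2$,
  $\sigma^2_f = 0.1$ -- ordered as in practice (clusters vary most,
  states least) and sized to be hard but estimable at this scale;
* wave intercepts default to $\mathrm{logit}(0.092)$ and
  $\mathrm{logit}(0.098)$, the published women's hypertension weighted
  prevalences of the two rounds;
* biomarker mode: per person, a latent systolic pressure (normal,
  population mean 118, sd 12), a correlated diastolic pressure
  (mean 76, sd 9, correlation 0.7) and log-normal glucose
  (median 105 mg/dL) are mean-shifted so that the probability of
  crossing the WHO cutoffs -- applied to the mean of readings 2-3 --
  equals the model probability exactly (the shift solves the
  threshold-crossing equation, tabulated once and interpolated).
  Three readings are the latent value plus independent 4 mmHg noise
  with a +3 mmHg first-reading elevation, reproducing the
  first-reading artifact that motivates the default combination rule.
  Binary mode skips all of this and draws the outcome directly; it is
  the fast default for sampler validation;
* weights are log-normal with mean 1 (the descriptive stage uses them;
  the model does not); item missingness is completely at random at a
  default 2%; sex is a configuration-level stratum because the real
  analysis fits sexes separately;
* a configurable fraction of wave-1 districts (default 2%, the
  observed share of split districts between the two real rounds) is
  split in two for wave 2, with wave-1 clusters allocated alternately
  to the successors and a full crosswalk emitted.

What the generator does *not* emulate: informative missingness,
household rosters and response propensity, true PPS weight
construction, and spatial correlation between neighbouring districts.
Passing recovery tests therefore demonstrate the estimator's
correctness under its own assumptions, not robustness to the
violations real data may carry.

## Validation results and problem sizes

The test-suite and the acceptance script compute, at the validation
design above (36,000 persons per replicate, 500 + 5000 iterations):

* oracle agreement: Gibbs posterior means of $\beta_0$ and all three
  variance components within 3 MCSE of `quad_reference()` on a
  four-latent-dimension instance;
* parameter recovery over replicated datasets: 95% central posterior
  intervals covering the generating values, and posterior-mean bias
  under 25% of truth, for all four parameters (20 replicates in the
  acceptance suite);
* end-to-end recovery: correlation of at least 0.8 between estimated
  and true district prevalences;
* full-pipeline determinism: byte-identical output tables under a
  repeated seed.

These sizes were chosen as the smallest design at which the
between-level variance decomposition is genuinely contested (15 states
is deliberately few) while each replicate remains a routine fit.

## Known limitations

* The state level is weakly identified with few states; the diffuse
  inverse-gamma default can concentrate $\sigma^2_f$ near zero when a
  realised state spread is small.  Users with few top-level units
  should consider a milder prior (`prior_a`, `prior_b` are arguments,
  not constants).
* No covariates and no age-standardisation: estimates are crude
  prevalences for the 15-49 frame.
* District point estimates only; posterior uncertainty per district is
  available from the draws (`keep_effects = TRUE`) but is not part of
  the reported tables.
* Single-chain defaults; split-half $\hat R$ is a within-chain
  surrogate, and multiple independent seeded runs are the honest
  between-chain check.
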