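---
title: "Building chronological-age and mortality clocks from DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building chronological-age and mortality clocks from DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the models it
fits, the assumptions behind them, the knobs that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The two clocks

A **cAge clock** predicts chronological age from methylation beta
values. Its value is not the prediction of a number everyone already
knows, but the residual structure: how far an individual's methylome
sits from the age-typical profile. A **bAge clock** goes after that
residual directly by training on time to all-cause mortality, and is
reported through the **age-acceleration residual** — the bAge score
with its chronological-age expectation regressed out — whose hazard
ratio per standard deviation is the headline association statistic.

## Scales: beta values and M-values

Methylation arrives as beta proportions $\beta \in [0,1]$. Association
testing happens on the variance-stabilised M-value scale
$M = \log_2(\beta/(1-\beta))$; clock *features* stay on the beta scale
(squared features are squared beta values). The two scales are linked
exactly through the logistic map, and the synthetic generator works on
the M-value scale for the same reason: both representations of a
simulated CpG are then consistent by construction. Before the log
transform, beta values at or beyond the open interval are clipped to
$[10^{-3}, 1-10^{-3}]$ — the source studies are silent on this edge
case; the bound keeps M-values finite while moving no proportion by
more than 0.1%.

## The EWAS layer

Per CpG, the package fits ordinary least squares with **age as the
outcome** — `age ~ z(M) (+ z(M²)) + covariates` — rather than the more
common methylation-as-outcome direction. This orientation is a design
commitment, not an accident: coefficients and standard errors differ
between the two directions, and everything downstream (ranking,
pre-selection sizes) inherits it. A nested F-test compares the linear
to the quadratic model per CpG. The mortality EWAS fits one Cox
proportional-hazards model per standardised CpG.

Covariate adjustment (sex, batch, smoking status as a 5-level factor
with "never" as reference and "unknown" a level of its own, pack years,
six cell-type proportions, optionally the top methylome principal
components) is implemented by projecting the outcome and every CpG
column onto the orthogonal complement of the covariate span once
(Frisch–Waugh–Lovell). The per-CpG problem then collapses to a one- or
two-variable regression with the correct residual degrees of freedom;
tests assert exact equality with the full design fitted by `lm`.

Numerical edge cases: a CpG with zero variance, or collinear with the
covariates, is flagged `degenerate` and reported as `NA` (Cox: HR 1,
p 1) rather than aborting a 10⁵-CpG scan. The Cox fitter is
Newton–Raphson on the Breslow partial likelihood with step-halving
whenever a step would decrease the likelihood, a 50-iteration cap, and
convergence at max |score| < 10⁻⁸; runaway coefficients (monotone
likelihood) are flagged. Breslow tie handling is the package-wide
convention; with continuous simulated times ties are rare, and the
choice is validated against `survival::coxph(ties = "breslow")` to
machine precision in the tests.

The methylome principal components are computed from the standardised
M-values of at most the 20,000 most variable CpGs — a memory bound that
preserves the leading variance structure the components are meant to
absorb.

## Pre-selection and the elastic nets

Clock features are the top-$n$ CpGs by linear-EWAS p plus the top-$m$
by the quadratic term's p (squared beta features, plus their linear
form when absent); ties in p are broken lexicographically by CpG id so
feature lists are reproducible. The reference recipe uses
$n = 10{,}000$ and $m = 300$ at biobank scale; the package treats both
as parameters since the right sizes scale with the EWAS power actually
available.

The Gaussian elastic net minimises
$\frac{1}{2n}\sum_i (y_i - b_0 - x_i^\top b)^2 +
\lambda\left(\alpha\|b\|_1 + \tfrac{1-\alpha}{2}\|b\|_2^2\right)$
with $\alpha = 0.5$ by default, the epigenetic-clock convention.
Implementation choices that matter:

* **Internal standardisation** uses n-denominator standard deviations
  (the coordinate-descent convention); returned weights are
  back-transformed to the raw beta scale so serialized weight tables
  apply directly to new data.
* **Path**: 100 log-spaced $\lambda$ values from the smallest
  all-zero $\lambda$ down to 0.001 of it, warm-started.
* **Convergence**: cyclic coordinate descent with active sets stops at
  a maximum coefficient change below $10^{-7}$ on the standardised
  scale — but a beta value and its square are correlated at 0.99+, and
  on such near-collinear designs plain descent crawls along almost-flat
  directions. Each $\lambda$ is therefore finished by an **exact
  active-set solve**: with the active set and signs fixed, the problem
  is the ridge system $(G_{AA} + \lambda(1-\alpha)I)\,b_A = c_A -
  \lambda\alpha\,s_A$, solved directly, dropping coordinates whose sign
  flips. The polish is accepted only if it lowers the penalized
  objective, and it brings the Karush–Kuhn–Tucker residual to machine
  precision; the test suite certifies KKT at every returned solution
  and checks the objective against an independent proximal-gradient
  oracle.
* **Cross-validation**: folds are grouped (all samples of one technical
  batch share a fold), $\lambda$ minimises mean CV squared error
  (minimum rule, not 1-SE), and for the Cox net maximises mean held-out
  Harrell's C. The intercept is never penalized; the Cox model has no
  intercept at all (absorbed by the baseline hazard).

The Cox elastic net wraps the same weighted coordinate-descent core in
an outer iteratively-reweighted quadratic approximation to the Breslow
partial likelihood (diagonal Hessian weights floored at $10^{-5}$),
with step-halving toward the previous iterate whenever the penalized
objective would rise. Agreement with an independent implementation
(`glmnet`) along entire paths is asserted to $10^{-5}$ in the tests.

## The hybrid log(age) rule

Two cAge models are trained on identical features: outcome age, and
outcome $\log(\text{age})$. Prediction uses the age model first; when
its output is **20 years or younger (inclusive)** the log-model
prediction is exponentiated and used instead, and the branch is
recorded per sample. The inclusive threshold follows the source
recipe's wording ("20 years or younger"). Log-model predictions are
exponentiated without a smearing correction — the reference is silent
on one, and on clock-scale data the retransformation bias is far below
the noise floor. The log model is trained on the same pre-selected
feature set as the age model. Missing model CpGs at prediction time are
a hard error: silent zero-filling would shift predictions invisibly.

## EpiScores and the bAge clock

A protein EpiScore is a published linear combination of beta values
standing in for a plasma protein level. The package treats EpiScores as
first-class weight tables (`project_episcores()` is a plain dot
product, no scaling), and the synthetic panel stands in for published
panels whose weights are external. The bAge feature set —
chronological age, sex, a smoking score, protein EpiScores — is
**z-scored within the dataset being scored**, the fitted linear
predictor is z-scored again, and the clock is therefore cohort-relative
by contract; applying it to a single new sample requires a reference
cohort, a property inherited from the published design rather than a
limitation added here. Age acceleration is the simple-least-squares
residual of the clock on chronological age, orthogonal to age by
construction.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the pipeline
assumes:

* ages uniform on \[18, 99\] years — matching the recruitment span of
  the anchor cohort and keeping every power calculation analytic;
* CpG trajectory classes: null, linear, quadratic, log(age), smoking.
  Each signal CpG's trajectory SD over the cohort equals
  $|N(0,\sigma_b)| \cdot \mathrm{sd(age)}$ with
  $\sigma_b$ = `effect_size_sd` (default 0.02 per year on the M scale),
  so the classes are comparably powered. The quadratic class is
  anchored at the young edge of the age range,
  $M = a + c\,(\text{age}-\text{age}_{\min})^2$: a monotone,
  accelerating trajectory of the kind described for developmental CpGs.
  An age-*symmetric* parabola would carry no linear information about
  age and would be undetectable in the age-as-outcome EWAS — a
  deliberate design decision, not an oversight;
* technical structure: per-batch M-value offsets (20 batches, SD 0.05)
  on every CpG, and white-cell-composition loadings on a random 20% of
  CpGs. Both are independent of age, so null-CpG calibration holds with
  or without adjustment;
* residual noise: i.i.d. Gaussian M-value noise, SD 0.1 — chosen so
  that at the default effect scale EWAS power at genome-wide
  significance is neither 0 nor 1 for a 2000-sample cohort (the source
  does not publish its effect-size distribution);
* survival: a Weibull-baseline Cox model (shape 1.1, scale 160 years)
  with linear predictor
  $0.09\,(\text{age}-\bar a) + \sum_k \theta_k\, z(\text{EpiScore}_k)$
  and administrative censoring at 15 years — roughly a decade of
  follow-up with mortality doubling every ~8 years of age. Centring age
  at the range midpoint only rescales the baseline; the EpiScore
  signals driving the hazard are the projections of the *observed* beta
  matrix, so the truth record's hazard is exactly recoverable from the
  data;
* the **population/cohort seed split**: CpG classes, coefficients, cell
  loadings and the EpiScore panel derive from `population_seed`;
  sampling, technical structure and survival from `seed`. Cohorts
  sharing a population seed share one methylome-age map — the property
  that makes leave-one-cohort-out validation meaningful — and
  `effect_shift_sd` perturbs one cohort's map to emulate
  distribution shift (e.g. another tissue).

What the generator does **not** emulate: array-level artifacts (probe
cross-hybridisation, dye bias, detection failures), genetic and family
structure, age-dependent noise, competing risks, and real
cell-composition drift with age. Passing tests therefore demonstrate
that the estimators and the pipeline logic are correct and calibrated
under the stated model — not that a clock trained on real arrays will
reach the same accuracy.

## Evaluation conventions

`regression_metrics()` reports Pearson r, RMSE, and **MAE as the
median absolute error** — the clock literature's convention and an easy
trap; the mean absolute error is reported separately under
`mean_abs_error`. Harrell's C counts a pair comparable when the
strictly earlier time is an event and scores ties 0.5. Survival
associations use Wald confidence intervals, matching standard
survival-package reporting. The proportional-hazards diagnostic is the
Grambsch–Therneau score test on scaled Schoenfeld residuals with the
Kaplan–Meier time transform by default (identity and rank available);
it reproduces `survival::cox.zph` to 10⁻⁸ in the tests. The LOCO
harness logs, for every round, exactly which cohorts trained the model,
and supports an anchor cohort that is never held out (the large
training cohort of the reference design).

## Problem sizes used in the shipped tests

The acceptance-style tests run the full pipeline at 2000 training
samples × 5000 CpGs with 200 true clock CpGs, pre-selecting 500 linear
+ 50 quadratic features and cross-validating over 8 grouped folds and a
50-point λ grid; mortality-clock recovery uses 20 simulations of 2000
samples with 20 candidate proteins (~10% event rate, 5 folds). These
sizes were chosen as the smallest at which the statistical claims are
stable, and are documented here as the package's own reproducibility
contract. The "noise floor" for the pipeline's prediction error is
defined as the held-out median absolute error of an ordinary
least-squares oracle given the *true* clock CpGs, fitted on the
training samples — the best linear-in-beta predictor available under
the truth record.

## Known limitations

* The elastic-net path at very small λ on heavily collinear designs is
  not unique; two feature orderings can return different (equally
  optimal) coefficient vectors. KKT certificates hold either way, and
  CV never selects that regime in practice.
* The Cox machinery assumes at most moderate tie mass (Breslow); heavy
  grouping of event times would favour the Efron estimator, which is
  not implemented.
* bAge is cohort-relative by contract; no calibration to an external
  reference population is provided.
* The EWAS orientation (age as outcome) means an age-symmetric
  nonlinear CpG is invisible; the quadratic term captures monotone
  curvature only.
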