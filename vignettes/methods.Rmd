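---
title: "Methods: separating retest effects from developmental change in RT inconsistency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating retest effects from developmental change in RT inconsistency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtiburst)
```

## Why a measurement-burst design

Repeated cognitive testing changes the thing it measures: prior exposure to
materials and procedures improves (or stabilizes) performance, and in an
equal-interval longitudinal design this retest effect is perfectly collinear
with aging. A measurement-burst design nests bursts of closely spaced
sessions (here biweekly; five at baseline, four in each later year, up to 17
sessions over four years) inside annual waves. Within a burst, age-related
change is negligible, so within-burst trends identify retest effects;
across-year trends, with the weekly trend modeled separately, identify
development. `rtiburst` applies this logic to response-time inconsistency
(RTI) — the residualized intraindividual SD of trial latencies — a
dispersion measure that is sensitive to cognitive status, relatively immune
to floor and ceiling effects, and responsive to practice.

## The outcome: residualized ISD, T-scored

**Trial screening** (`screen_trials()`): a trial is dropped if missing, if
incorrect, if faster than 150 ms, or if it exceeds its person x task x year
x session cell mean by 3 or more SDs. Three choices deserve comment:

* *Single pass.* Cell means and SDs are computed once, over non-missing
  correct trials, before any bound-based removal. Iterating the ceiling
  would remove progressively more trials and is not part of the procedure
  this implements; single-pass screening also makes the operation idempotent
  under cached cell statistics.
* *Boundary.* "3 or more SDs" is read inclusively: a trial exactly at
  mean + 3 SD is removed.
* *Scope.* The ceiling's cell is per session by default
  (`qc_rules(scope = )` offers pooling over sessions within a year), since
  a measurement occasion in this design is a session.

Cells left with fewer than two usable trials have no defined SD; their
trials are retained with a warning rather than silently dropped.

**Residualization** (`residualize_trials()`): dispersion scores should not
be inflated by systematic trends — a person whose latencies drift down
across trials would otherwise look inconsistent. Latencies are demeaned
within absorption cells (person x task x year x session by default) and a
pooled linear trial-index trend is removed by least squares. Absorbing cell
means removes between-person speed differences and occasion-level change;
the trial regressor removes within-session practice. The estimator is
deterministic fixed-effects least squares rather than a random-effects fit:
it removes the same named confounds, is exactly testable against a
normal-equations oracle, and cannot fail to converge. Additional regressors
(session, year, age) become identifiable under the looser `absorb =
"person"` setting; collinear terms are dropped with a warning.

**ISD and T scores** (`compute_isd()`, `t_standardize()`): the RTI score is
the n−1 sample SD of the residuals in each cell (cells with fewer than two
residuals propagate as missing and are simply absent from the likelihood
downstream). Scores are mapped to T units, `t = 50 + 10 (isd − m) / s`,
with `(m, s)` estimated once per task on a fixed reference distribution —
the Year-1 Session-1 scores pooled across persons — and applied to all
occasions. This is a genuine design decision: standardizing within every
occasion (offered as `reference = "per_occasion"`) would pin each occasion's
mean at exactly 50 and annihilate the very change slopes the model
estimates. A fixed baseline reference is the only reading under which
nonzero weekly and yearly fixed effects are estimable, so it is the
default; the per-occasion variant is retained for comparison only.

## The three-level model

Sessions (level 1) nest in years (level 2) nest in persons (level 3):

$$y_{ijk} = \gamma_{000} + \gamma_{100}\,\mathrm{Week}_{ijk} +
\gamma_{010}\,\mathrm{Year}_{jk} + \gamma_{001}\,\mathrm{Age}_k +
\gamma_{002}\,\mathrm{Sex}_k + \upsilon_{00k} + \upsilon_{01k}\mathrm{Year}_{jk} +
\upsilon_{10k}\mathrm{Week}_{ijk} + \mu_{0jk} + \mu_{1jk}\mathrm{Week}_{ijk} +
\varepsilon_{ijk}$$

* Week and year are 0-based at baseline; the week covariate advances by the
  session spacing (2 weeks by default, so "per week" units are real time;
  `week_spacing = 1` gives a plain session index). The week clock resets at
  each year's first session — the within-burst trend is the retest effect.
* Age is centered at 74 years; sex is 0 = male / 1 = female. Age x year and
  sex x year products are available (`include_interactions = TRUE`) but off
  by default: the default model is the plain main-effects change model.
* Random effects: person-level intercept, year slope and week slope with an
  unstructured 3x3 covariance; person-year intercept and week slope with
  diagonal covariance; i.i.d. occasion residual. The person-level week
  slope gets its own effect ($\upsilon_{10k}$), distinct from the year
  slope's.

**Estimation.** Full maximum likelihood (not REML), so missing occasions
are handled by simply omitting them from each person's block under the
missing-at-random assumption. The implementation profiles both the fixed
effects (GLS) and the residual variance out of the Gaussian marginal
likelihood and optimizes the remaining variance *ratios* with `nlminb` on a
log-Cholesky parameterization (level-3) and log variances (level-2) —
covariances stay positive semi-definite by construction and the search is
unconstrained. Persons sharing an identical (week, year) layout share one
marginal covariance, so each likelihood evaluation performs one Cholesky
factorization per layout rather than one per person; a fully balanced
304-person fit evaluates in well under a millisecond and converges in a few
hundred evaluations.

Numerical details: convergence is `nlminb`'s relative tolerance at 1e-10
with one restart from the incumbent when the first pass reports singular
convergence (a flat direction, typical when a variance sits near zero);
the profiled residual variance is floored at 1e-12 so that exactly
noise-free data (a legitimate degenerate input — see the zero-noise checks)
yield exact GLS fixed effects rather than an error; if the unstructured
level-3 covariance fails to converge the fit falls back to diagonal and
then intercept-only, recording the structure used. Wald standard errors for
the fixed effects come from the GLS information block
$\sigma^2 (X' V_0^{-1} X)^{-1}$ at the ML variance estimates.

`marginal_loglik()` exposes the same likelihood as a plain function of
user-supplied parameters, evaluated person block by person block; the test
suite holds it to a dense pairwise-covariance oracle at 1e-8 and the full
fit to `lme4` on the same model family.

**Random effects** (`extract_random_effects()`): empirical-Bayes (BLUP)
estimates $\hat b_k = G Z_k' V_k^{-1} \hat r_k$, the conjugate-Gaussian
posterior means at the ML parameters, verified against a dense oracle.
Person-specific slopes are fixed effect plus person-level deviation:
short-term $\hat\gamma_{100} + \hat\upsilon_{10k}$, long-term
$\hat\gamma_{010} + \hat\upsilon_{01k}$. Covariate contributions are
deliberately excluded — the slopes are later entered in outcome models
*alongside* age and sex, and folding the covariates into the slopes would
count them twice. The weekly slope supports a configurable multiplicative
rescale (recorded in the output) because per-unit odds ratios on a
T-units-per-week predictor are awkward to read; the default is 1.

## Cognitive status and outcome models

Five domain scores per assessment year are z-scored against a 2 x 2 x 5
normative table (age band 65–74/75+ at the classification year; education
band 0–12/13+ years, baseline throughout). A domain with z ≤ −1.5 is a
deficit (boundary inclusive; both choices exposed in `status_rules()`):
zero deficits is HC, one is CIND-S, two or more is CIND-M. Person-years
with a missing domain are unclassifiable and excluded with a count.

Follow-up status (HC referent) is regressed on one slope predictor plus
centered age and sex by multinomial logistic regression — one predictor per
model, since short- and long-term slopes of the same task are strongly
correlated. The engine is Newton–Raphson on the multinomial log-likelihood
with step-halving, run on centered and scaled predictors for conditioning
and mapped back exactly; it converges to gradient norms near machine
precision, which the tests exploit (a 2 x 2 reduction must reproduce the
cross-product odds ratio to 1e-10). Perfect separation is detected as a
diverging standardized coefficient norm and raised as an error rather than
reported as a huge finite OR. Wald intervals are computed on the log-odds
scale; the likelihood-ratio test in `compare_baseline_predictor()`
contrasts a baseline predictor (e.g. MMSE) against the covariates-only
model.

## What the synthetic generator does and does not emulate

`generating_params()` encodes the study conditions: 304 persons aged 64–92
(mean 74.02, SD 5.95), 208 female / 96 male, education 7–24 years (mean
15.15); a 136/88/80 HC/CIND-S/CIND-M mixture; attrition hazards of
11%/3.5%/4.5% between burst years and 26% before the long-term follow-up
(missing at random, independent of the latent process); per-task
incorrect-response rates of 1.43% (CRT) and 10.46% (BRT), missingness of
0.13%/0.20%, and planted-outlier rates of 1.78%/2.42%; latent level
variances of 34/3/13 (CRT) and 37.5/3.5/9 (BRT) T-units², i.e.
between-person shares of 68% and 75%; weekly/yearly fixed slopes of
−0.02/0.15 (CRT) and −0.06/−0.09 (BRT) with age effects 0.21/0.34 and sex
effects −0.24/0.25. The latent intercept is anchored at the T-score center
(50). Where the emulated conditions left quantities open, the package fixes
them once:

* *Latent-to-trial link.* A dispersion measure is defined by how it is
  computed, not by a generative model, so the generator must invent one:
  trial latency SD in ms is linear in the latent T score
  (`sd = a + b t`, default `a = 0`, `b = 2`, floored at 5 ms). Linearity
  makes the link invertible, so downstream scores are an affine image of the
  latent process and ground-truth ordering is checkable.
* *Trial distribution.* Latencies are drawn normal around a person-specific
  mean by default, with a lognormal option (`rt_distribution`). Real RT
  distributions are right-skewed; the normal default is chosen so the
  planted trial SD is exactly the generating quantity, keeping
  recovery tests sharp. The QC and RTI stages are distribution-agnostic.
* *Planted outliers* sit 5–10 cell SDs above the mean (80%) or below the
  150 ms floor (20%) — gross errors such as attention lapses or double key
  presses — far enough out that single-pass screening reliably flags them
  even though the planted values themselves inflate the screening SD.
* *Group structure.* Latent status shifts the RTI intercept (0/+2/+4 T
  units for HC/CIND-S/CIND-M); impaired groups carry 1 or 2 persistent
  deficit domains shifted −2 cell SDs with unit-SD noise (so classification
  is realistically labile; `domain_noise = 0` makes it deterministic).
  Baseline MMSE is group-dependent (29.0/28.7/28.3, SD 1.0/1.1/1.5,
  truncated 24–30).

The generator does **not** emulate: apparatus timing error, time-of-day or
session-content effects, non-linear change trajectories, informative
dropout, or etiology-specific impairment subtypes. Passing recovery tests
therefore show that the estimators recover the parameters of *this* class
of generating process at the study scale — not that real RT data satisfy
its assumptions. Two consequences are worth knowing. First, the trial stage
adds ISD sampling noise (an SD estimated from 60 trials is itself noisy) on
top of the latent occasion residual, so a pipeline-level variance
decomposition shows a larger week-level share than the latent 68/6/26
structure; decomposition recovery is therefore checked at the latent level
(`simulate_rti()`), where the generating model and the fitted model
coincide. Second, BLUP slopes are shrunken and noisy versions of the latent
slopes, so slope correlations at the pipeline level are attenuated or
inflated relative to the latent random-effect correlation; the correlation
machinery is calibrated on directly simulated slope pairs instead.

## Replicate budgets and problem sizes

The test suite and the acceptance script run recovery checks at the study
scale (304 persons, 17 sessions) with 20 seeded replicates per quantity —
enough that Monte-Carlo standard errors of replicate means are an order of
magnitude below the tolerances used — and pool Wald-coverage counts across
the five fixed effects of each replicate (100 intervals per check, giving
1-percentage-point resolution on a quantity whose target band is 90–99%).
Cross-implementation checks (`lme4`, `nnet`) and dense-oracle identities
use smaller instances (≤ 80 persons, ≤ 50 cells) where the reference
computation is exact.

## Known limitations

* The residual structure is i.i.d. at level 1; autocorrelated or
  heteroscedastic occasion residuals are not modeled.
* Change is linear in week and year; non-linear retest decay (often
  steepest between the first two exposures) needs a spline or
  log-occasion extension.
* The level-2 covariance is diagonal by default; an unstructured
  person-year covariance is not currently offered.
* Wald inference for fixed effects uses normal quantiles, appropriate at
  these sample sizes but anti-conservative for very small person counts.
* `fit_unconditional()` requires at least two persons, years, and weeks;
  the conditional model additionally needs complete age/sex covariates.
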