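# rtiburst

Dissociating short-term retest (practice) effects from long-term
developmental change in **response-time inconsistency (RTI)** using
longitudinal **measurement-burst** designs and three-level mixed models — and
using the separated change slopes to predict prospective cognitive status.

## The problem

In longitudinal studies of cognitive aging, every retest occasion both
measures change and causes it: prior exposure to the materials and procedure
("retest" or "practice" effects) biases developmental trend estimates, and in
conventional equal-interval designs the two are perfectly confounded. A
measurement-burst design breaks the confound by nesting bursts of closely
spaced sessions (e.g. five biweekly sessions at baseline, four in each later
year) inside widely spaced annual waves: meaningful age-related change cannot
occur within a burst, so within-burst trends index retest effects while
across-year trends index development.

`rtiburst` implements the full analysis chain for trial-level reaction-time
data from such designs, for researchers in cognitive aging and
quantitative methods:

1. **Trial QC** — drop missing and incorrect responses, screen latencies
   against a 150 ms floor and a person-specific mean + 3 SD ceiling, remove
   the one-back task's unanalysable lead-in trial, and account for every
   trial in an exclusion report.
2. **RTI scores** — residualized intraindividual standard deviations (ISD)
   per person x session, T-standardized (M = 50, SD = 10) against the
   baseline occasion.
3. **Three-level change model** — weekly sessions (level 1) in annual bursts
   (level 2) in persons (level 3), fit by full maximum likelihood.
4. **Person slopes** — empirical-Bayes (BLUP) short-term (weekly) and
   long-term (yearly) slopes per person, and their correlation.
5. **Cognitive status** — HC / CIND-S / CIND-M classification from five
   cognitive domains against age x education norms (1.5 SD deficit rule).
6. **Outcome models** — multinomial logistic regression of follow-up status
   (HC referent) on each slope predictor, adjusted for age and sex, with a
   baseline-MMSE comparison model.
7. **Synthetic data** — a fully seeded generator producing trial tables,
   covariates, domain scores and norms with the statistical structure the
   analysis assumes, for simulation and parameter-recovery studies.

## The model

For T-scored RTI of person *k* in week *i* of year *j*:

```
Level 1:  RTI_ijk = beta0_jk + beta1_jk * Week_ijk + eps_ijk
Level 2:  beta0_jk = delta00_k + delta01_k * Year_jk + mu0_jk
          beta1_jk = delta10_k + mu1_jk
Level 3:  delta00_k = gamma000 + gamma001 Age_k + gamma002 Sex_k + u00_k
          delta01_k = gamma010 + gamma011 Age_k + gamma012 Sex_k + u01_k
          delta10_k = gamma100 + u10_k
```

Week and year are 0-based at baseline, age is centered at 74, sex is coded
0 = male / 1 = female. `gamma100` is the average weekly **retest** slope,
`gamma010` the average yearly **developmental** slope. The person-level
effects `(u00, u01, u10)` carry an unstructured 3x3 covariance, the
person-year effects `(mu0, mu1)` a diagonal one, and `eps` is i.i.d.
Estimation is full-information maximum likelihood over all available
occasions (missing at random); person-specific slopes are
`gamma100 + u10_k` (weekly) and `gamma010 + u01_k` (yearly).

## Worked example

```r
library(rtiburst)

cfg <- run_config(seed = 20, design = burst_design(n_persons = 304))
run <- run_pipeline(cfg)

print(run$exclusions)
#> Trial exclusions (% of possible trials)
#>   CRT: missing 0.12%, incorrect 1.43%, outliers 1.69%, usable 96.75% (n = 280560)
#>   BRT: missing 0.21%, incorrect 10.45%, outliers 1.93%, usable 87.42% (n = 280560)
```

The one-back task (BRT) loses far more trials to incorrect responses than
the four-choice task (CRT) — the generator plants error rates of 1.43% and
10.46%, and the report recovers them from the corrupted trials. The
conditional fit for BRT:

```r
print(run$fits$BRT)
#> Three-level RTI change model (full ML)
#>   observations: 4676 | persons: 304 | person-years: 1093
#>   log-likelihood: -16829.536
#>   level-3 structure: unstructured
#>
#> Fixed effects:
#>   intercept    49.907  [48.594, 51.219]  p = <2e-16
#>   week         -0.132  [-0.233, -0.032]  p = 0.00968
#>   year         -0.209  [-0.447, 0.028]  p = 0.0841
#>   age           0.177  [0.045, 0.308]  p = 0.00861
#>   sex          -0.252  [-1.772, 1.268]  p = 0.745
```

The weekly slope is negative and significant (practice reduces
inconsistency within bursts) while the yearly slope is not — the
dissociation pattern a high-executive-demand task is built to show. The
extracted person slopes feed the outcome models:

```r
print(run$outcomes$year4_brt_short)
#> Multinomial logistic regression (referent = HC)
#>   predictor: short_term | n = HC:108, CIND-S:91, CIND-M:54
#>   CIND-S  OR = 1.37  [0.20, 9.22]  p = 0.748
#>   CIND-M  OR = 2.97  [0.31, 28.39]  p = 0.345
or_percent_increase(2.97)
#> [1] 197
```

so a one-T-unit-per-week increase in short-term BRT inconsistency multiplies
the odds of multi-domain impairment at Year 4 by 2.97 (a 197% increase) in
this synthetic run — wide intervals reflect the small per-unit scale of the
slope predictor. Short- and long-term BRT slopes correlate strongly
(`run$slope_assoc$BRT$r` = 0.99 here).

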