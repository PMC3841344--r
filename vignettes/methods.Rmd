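---
title: "Measuring exposure time when page views can time out"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring exposure time when page views can time out}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timeoutMI)
```

## The problem

Web-delivered behavioural interventions log a timestamp every time a
participant opens or leaves a content page, so the time spent on each page
— and, summed, total exposure to the intervention — can in principle be
read off the navigation log. In practice a substantial fraction of page
views end not with a navigation event but with the platform's inactivity
time-out: after a prespecified period (30 minutes here) the program logs
the participant out, and the close stamp records the forced logout rather
than anything about actual viewing. Designs that allow long page views and
truncate them after the fact create exactly the same situation, so the
package treats both as a "time-out".

The two common fixes are both single, uninformed choices: drop timed-out
views (a complete-case analysis) or assign every one of them the same
arbitrary constant (a degenerate single imputation). Either can bias the
estimated exposure and, through the variance, change the substantive
conclusion of a between-arm comparison. `timeoutMI` implements the
alternative this package is built around: treat the timed-out durations as
missing data, multiply impute them from the observed page views, analyse
each completed dataset, and pool with Rubin's rules.

## Pipeline

1. **Parsing** (`read_event_log()`, `compute_durations()`): elapsed
   open-to-close time below the threshold becomes an observed duration in
   minutes (sub-minute resolution is kept; median observed views are about
   one minute, so rounding would be destructive). Elapsed time at or above
   the threshold, or a missing close stamp altogether (browser killed — a
   case the logging mechanism cannot distinguish from a time-out, so we
   fold it in and log it), yields a missing duration flagged `timed_out`.
   Views are numbered per participant across all visits, because the
   imputation step works on a wide layout of successive views.

2. **Wide format** (`build_wide()`): one row per participant, columns
   `t_1 ... t_K`. The mask distinguishes *impute* cells (the view happened
   but timed out) from *structural* cells (the participant never had a
   k-th view). Only impute cells are ever filled; a participant who never
   accessed the site remains an all-structural row contributing an exact
   zero to total time.

3. **Chained-equations imputation** (`mice_impute()`): each duration
   column with missing entries gets a linear regression on the log-minute
   scale; predictors are the fully observed baseline covariates, the
   randomized arm and stratum, the (working value of the) log minutes on
   the participant's first core-content page, and the page type and
   content section of the target view. Columns are visited from least to
   most missing (ties broken by position), several cycles per dataset.

4. **Analysis per completed dataset** (`total_time()`, `fit_zip()`): total
   minutes are rounded (half-up, configurable to floor) to an integer
   count and modelled with a zero-inflated Poisson: an intercept-only
   logistic part for the never-access point mass at zero, and a log-linear
   Poisson part with arm and stratum. Because every participant shares the
   same observation window, the exponentiated arm coefficient is the ratio
   of mean minutes between arms.

5. **Pooling** (`pool()`, `pool_log_scale()`): the arm coefficient is
   pooled on the log scale across the M fits; the total variance is the
   within-imputation mean squared standard error plus `(1 + 1/M)` times
   the between-imputation variance; the pooled coefficient and interval
   are exponentiated only for reporting.

6. **Sensitivity analysis** (`run_sensitivity()`): the constant-assignment
   alternative is run over a grid of assumed time-out durations (default
   0.00001 then 1–30 minutes) so that the analyst can see how far the
   conclusion depends on the arbitrary constant.

## Proper imputation: what is drawn and why

For the pooled variance to be valid, imputations must carry parameter
uncertainty, not just residual noise. For each column model with
fitting-set size n, rank p, residual sum of squares SSE:

* residual variance `sigma2* = SSE / chi2(n - p)` (a scaled inverse
  chi-square draw);
* coefficients `beta* ~ N(beta_hat, sigma2* (X'X)^{-1})`;
* imputed value `x' beta* + N(0, sigma2*)`, exponentiated back to minutes.

With repeated imputation of the same cell the between-imputation variance
is therefore strictly positive, which the tests assert.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `timeout_min` | 30 | minutes | the platform's inactivity threshold; configurable so post-hoc truncation designs reuse the flag |
| `M` | 5 | datasets | 5–10 imputations are conventionally sufficient; 5 keeps the demonstration cheap |
| `iterations` | 10 | cycles | "several" cycles are needed for stabilization; 10 is comfortably past where the traces flatten here |
| `min_cases` | 25 | observed views | below this a per-position regression is unestimable in practice; sparser positions share one pooled tail model with position index as a covariate |
| `floor_min` | 0.005 | minutes | second-resolution stamps can log 0-minute views; the floor keeps the log transform defined |
| `truncate_at_timeout` | FALSE | — | nothing in the logging mechanism bounds true viewing above the threshold, so imputations are not truncated by default; the switch exists for analysts who prefer the bound |

Two genuinely open design points were decided as follows. First,
high-position columns are sparse and the source methodology does not say
how (or whether) per-position models were pooled; the `min_cases` tail
pooling above is this package's choice. Second, intervals use normal
quantiles without the small-sample degrees-of-freedom correction: the
cohorts in scope are large (hundreds to thousands) and the correction
would be visually indistinguishable here; it is noted as an extension.

## The synthetic world

Trial navigation logs are rarely shareable, so `generate_cohort()` emits a
cohort with the statistical structure the analysis assumes, calibrated to
the published marginals of a two-arm (prescriptive vs motivational tone)
smoking-cessation web trial: 37% of enrollees never access the site; per-
page viewing times are log-normal with median about 1.07 minutes and
sigma 1.17 on the log scale (implied by the printed interquartile range
0.47–2.27); roughly 10.4% of views time out; accessors make on average
1.44 visits of about 3.9 pages (the printed visit and page-view counts
divided through); and the default arm effect multiplies viewing times by
0.87, the size of the published contrast. Covariate effects (stratum, page
type, content section, position) move the conditional mean of log
duration, so the imputation models have real signal; because those effects
and the arm effect are not all centred, the marginal observed median sits
slightly below `exp(mu)` (about 0.93 minutes at defaults), which we accept
rather than re-tuning the location each time a covariate effect changes.

Censoring is missing at random by construction: the time-out probability
depends only on observed covariates (stratum, page type), and the true
duration behind a censored view is drawn from the same conditional model
as observed views. One unavoidable exception: a true duration at or above
the threshold is always censored, because the simulated logger — like the
real one — cannot observe it. At the default sigma this affects ~0.2% of
views and is a small genuinely-NMAR component of the stated world; tests
that need an exact no-censoring identity lower sigma instead of pretending
the logger could see 40-minute views. The `nmar_inflation` switch makes
censored views genuinely longer than observed ones for robustness
experiments; the logged data are identical by construction, which is
precisely the point.

What a green test on this world does *not* establish: real navigation
logs have multi-tab sessions, revisits to the same page, informative
abandonment, and covariate-dependent access patterns that the generator
does not model. The generator supports the methodological claims
(bias of constant assignment, validity of the MI machinery), not clinical
conclusions.

## Numerical choices and degenerate inputs

* Zero-elapsed views are valid observations (duration 0; floored only
  inside the log-scale regression).
* A duplicated (participant, open-time) pair rejects the whole file;
  a close stamp before its open stamp rejects that record with a warning
  and the rejects are kept for reconciliation.
* ZIP fitting maximizes the exact mixture likelihood with analytic
  gradient from two starts (observed zero fraction; positives-only
  Poisson); the zero-inflation logit is bounded at ±15, and data with no
  zeros at all are returned as an explicit boundary fit equal to the
  plain Poisson MLE, with the interval suppressed rather than fabricated.
* All-zero outcomes, rank-deficient designs, and columns with no observed
  values (after tail pooling) are hard, named errors.
* Percentages print half-up to two decimals, matching the convention of
  the cohort-flow counts the reports emulate.

## Direction of the reported ratio

The published account of the motivating trial words the direction of the
tone contrast inconsistently in different places (abstract vs results vs
figure caption). This package fixes the reported quantity as the
**motivational : prescriptive** ratio of mean minutes — arm = 1 is the
motivational tone, and `ratio_of_means()` exponentiates that arm's
coefficient — and leaves the inconsistency documented rather than
silently resolved.

## Known limitations

* Model-based (observed-information) standard errors are used in the ZIP
  fit, as in the reference analysis. Total minutes are far more variable
  than a Poisson count (sums of skewed log-normal views), so on the
  synthetic world the nominal 95% intervals for the arm ratio undercover
  badly (the acceptance suite measures this honestly rather than hiding
  it). A robust or quasi-likelihood variance would fix the coverage but
  is deliberately out of scope because the methodology under study
  specifies the plain ZIP.
* The imputation engine handles continuous log-normal durations only — no
  predictive mean matching, no categorical targets, no joint multivariate
  model.
* Visit structure is flattened: positions are a single sequence per
  participant, matching the wide layout the imputation models assume.
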