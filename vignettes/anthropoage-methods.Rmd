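---
title: "AnthropoAge: model, estimation and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AnthropoAge: model, estimation and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthropoage)
```

## The model

AnthropoAge is a biological-age proxy built from two sex-stratified Gompertz
proportional-hazards mortality models. The hazard is

$$h(t) = e^{xb}\, e^{\gamma t}, \qquad t \text{ in months},$$

so the probability of death within $t$ months is

$$\mathrm{CDF}(t, xb) = 1 - \exp\!\big(-e^{xb}\,\gamma^{-1}(e^{\gamma t}-1)\big).$$

Model 1 uses only chronological age (CA, in years) in the linear predictor:
$xb_1 = \beta_0 + \beta_1\,\mathrm{CA}$, with a single shape $\gamma_0$.
Model 2 adds non-linear anthropometry,
$xb_2 = \text{rate} + \beta_{\mathrm{CA}}\,\mathrm{CA}
      + \beta_{b1}\ln \mathrm{BMI} + \beta_{b2}(\ln \mathrm{BMI})^2
      + \beta_w\,\mathrm{WHtR}^{1/3}$,
and lets the shape $\gamma_j$ differ by race/ethnicity group
$j \in \{\text{White, Black, Hispanic/Latino, Other}\}$.

Setting the two CDFs equal at the 120-month horizon and solving Model 1 for
age gives the closed form implemented in `anthropoage()`:

$$\mathrm{AnthropoAge} =
  \frac{\ln\!\Big(\dfrac{-\ln(1-M)}{\gamma_0^{-1}(e^{\gamma_0 t}-1)}\Big)
        - \beta_0}{\beta_1},$$

where $M = \mathrm{CDF}_2(t, xb_2)$ is the individual's 10-year mortality
risk under the anthropometry model. AnthropoAge is therefore "the age at
which the CA-only model predicts the same 10-year risk that anthropometry
predicts for this person". The inversion is exact: the test suite checks it
against numeric root-finding on 1,000 random parameter draws to $10^{-8}$
years, and the round trip CDF $\to$ inversion returns the input age.

**Units.** The Gompertz time scale is months (horizon $t = 120$), while CA
enters the linear predictors in years. This mixed convention follows the
original model definition; both units are recorded in serialized
coefficient files (`write_gompertz_coefs()`) so a mismatch cannot pass
silently.

**AnthropoAgeAccel** is the residual of AnthropoAge regressed on CA,
separately by sex. The default mode is ordinary least squares with fixed
study intercepts: with a handful of studies, fixed and random study
intercepts agree closely, and OLS residuals have exactly testable
properties (they sum to zero and are orthogonal to CA within sex). The
random-intercept formulation — study only for baseline analyses, study plus
participant for longitudinal data — is available via `mode = "mixed"`.
Accelerated aging is a positive residual; quartiles are unweighted sample
quartiles (linear interpolation) within sex, since no weighting convention
is defined for the cut points.

## Fitting

`fit_gompertz()` maximizes the right-censored log-likelihood

$$\ell = \sum_{\text{events}} \big(xb_i + \gamma_{g_i} t_i\big)
  - \sum_{\text{all}} e^{xb_i}\,\frac{e^{\gamma_{g_i} t_i}-1}{\gamma_{g_i}}$$

by BFGS on $(\log\gamma_1,\dots,\log\gamma_G,\beta)$ with an analytic
gradient; the covariance is the inverse observed information mapped to the
natural scale by the delta method. Parametrizing $\log\gamma$ keeps the
shape positive; a fitted shape below $10^{-9}$ is reported as a boundary
warning, never silently clipped. Strata with zero events are an error. The
polynomial BMI basis uses raw powers $\{\ln\mathrm{BMI},
(\ln\mathrm{BMI})^2\}$; coefficient files carry a basis tag (and, for an
orthogonalized basis, centering/scaling constants) so either convention can
be loaded.

$M$ outside the open unit interval is an error by default. The optional
`clamp = TRUE` flag clamps to $[10^{-12}, 1-10^{-12}]$ and reports how many
values were affected — used in the pipeline where extreme anthropometry can
drive a risk numerically to 1.

## Discrimination, decision curves, survival models

`uno_c()` and `tauc()` implement inverse-probability-of-censoring-weighted
discrimination. The censoring distribution $\hat G$ is a Kaplan-Meier fit
on the pooled sample. Uno's concordance weights each comparable pair
(event $i$ before $\tau$, $t_i < t_j$) by $\hat G(t_i)^{-2}$; the
time-dependent AUC at $\tau$ contrasts cumulative cases
($t_i \le \tau$, weight $1/\hat G(t_i)$) with dynamic controls
($t_j > \tau$). Ties in the predictor count one half. Both reduce to
Harrell's C / empirical AUC without censoring, are invariant to monotone
transforms of the predictor, and are verified against literal $O(n^2)$
double loops in the tests. `compare_auc_bootstrap()` uses a paired
subject-level bootstrap (1,000 resamples by default) with a
normal-approximation two-sided p-value; degenerate resamples are dropped
and more than 10% dropped is an error. The truncation time for Uno's c
defaults to the maximum observed time and is configurable per study
horizon.

Cox models, Kaplan-Meier, log-rank and the Schoenfeld-residual
proportional-hazards test are delegated to the survival package (Efron ties
by default, with a Breslow switch; survey weights are standardized to mean
1 within the analysis sample; identity time transform for the PH test).

`net_benefit()` computes decision curves,
$\mathrm{NB}(p_t) = TP/n - (FP/n)\,p_t/(1-p_t)$, over a default grid of
0.01–0.50 in steps of 0.01 (a mortality-risk context; configurable). For
survival outcomes, `net_benefit_survival()` converts to horizon-binary
status with IPCW — events before the horizon weigh $1/\hat G(t_i)$,
survivors $1/\hat G(\tau)$, subjects censored earlier weigh zero — with a
naive complete-follower variant for comparison, since the censoring
treatment inside decision curves is a genuine design choice.

## Generalized estimating equations

`fit_gee()` is a self-contained GEE solver (Gaussian/Poisson/binomial
variance functions with canonical links, independence or AR(1) working
correlation, robust sandwich covariance). It exists because the package
needs working-correlation GEE with cluster-robust errors and QIC, and it is
validated through exact degenerate-case equivalences: independence Gaussian
GEE equals weighted least squares to machine precision, and singleton
clusters reproduce the GLM with heteroskedasticity-robust (HC0) standard
errors.

AR(1) distances are measured on the integer wave index (visits closer in
time are more correlated); calendar-time distances can be supplied because
wave spacing differs across studies. The correlation $\alpha$ is estimated
from lag-1 products of Pearson residuals and clamped to $(-0.99, 0.99)$.
Weights act as prior weights in the estimating equation, normalized to mean
1. For near-separated binomial outcomes the linear predictor is clamped at
$\pm 25$ and steps are damped; non-convergence is an error, not a silent
result.

QIC follows Pan (2001): $-2\,QL + 2\,\mathrm{tr}(\hat\Omega_I \hat V_R)$
with the quasi-likelihood evaluated at dispersion 1 for every family (for
Gaussian, $QL = -\tfrac12\sum w(y-\mu)^2$). The scale handling of the
Gaussian quasi-likelihood is a convention; accordingly only signs and
differences of QIC are ever asserted, not levels.

`aging_trend()` reads its slope against 1 (one year of biological age per
calendar year) with a $10^{-6}$ numerical margin, so an exact-identity
panel — where the residual variance collapses to zero — is classified
"indeterminate" rather than picking up roundoff as a trend.

## The synthetic cohort

`generate_panel()` emulates a harmonized multinational aging panel so every
downstream stage can be tested against known truth. Default conditions,
chosen once as plausible for this setting:

* five studies with wave schedules 0–12 years at 2–3 year spacing
  (`HRS` 0,2,...,12; `ELSA` 0,4,8; `MHAS` 0,2,11; `CRELES` 0,2,5;
  `CHARLS` 0,2,4), 1,000 subjects per study;
* baseline age $50 + 44\,\mathrm{Beta}(1.5, 3)$ (median near 63, range
  50–94), 55% female, ethnicity mix 55/10/20/15% across
  White/Black/Hispanic-Latino/Other;
* log-BMI and WHtR Gaussian per sex with small negative (BMI) and positive
  (WHtR) age slopes; since per-study anthropometry variances are not
  published, the dispersions were chosen to place medians and IQRs in
  realistic ranges, not fitted to any source;
* Gompertz mortality with shape 0.0045 per month, rate intercept $-12.4$
  and 0.085 per year of age, giving roughly one fifth of subjects dead
  within the 12-year administrative horizon;
* a latent per-subject acceleration $a_i \sim N(0, 3\,\text{years})$ that
  loads negatively on log-BMI and positively on WHtR, enters the true
  hazard through the transformed-anthropometry deviations, and raises the
  odds of every self-reported outcome — so ground truth for
  AnthropoAgeAccel recovery exists by construction;
* survey weights $\mathrm{Gamma}(4, 4)$ (positive, mean 1); education,
  smoking and alcohol drawn as inert covariates for adjustment tiers.

Death times are drawn in continuous time by CDF inversion and reported
rounded to the month, mimicking approximate dates of death; follow-up is
computed from those dates, not from waves. Anthropometry is generated on
the transformed scales, back-transformed, and clipped to the plausibility
ranges with the clipping fraction logged in the truth sidecar. Each study
draws from its own RNG substream (master seed plus a fixed stride), so
appending a study never perturbs the others — `inject_acceleration()`
exploits the same discipline to regenerate the panel with a hazard
multiplier for latently accelerated subjects while reproducing every other
draw bit for bit.

What the generator does **not** emulate: half-sample anthropometry
rotation, item nonresponse and informative missingness, survey-weight
construction, competing risks, or real between-country anthropometry
differences beyond the configured means. Passing tests therefore
demonstrate internal statistical correctness (parameter recovery,
invariances, oracle agreement), not transportability to any real cohort.

## Problem sizes and numerical choices in the test suite

The suite runs at sizes chosen to balance Monte-Carlo resolution against
desk-scale runtimes: Gompertz coverage uses 100 replicates of 20,000
subjects with roughly 30% administrative censoring; hazard-ratio recovery
injects 1.37 into a 30,000-subject cohort; discrimination oracles use
censored fixtures of 150–200 subjects where the $O(n^2)$ double loop is
exact; the end-to-end determinism check runs the full pipeline twice on the
default 5,000-subject panel and compares table digests byte for byte.
`scripts/acceptance.R` reruns the pipeline and a 15,000-subject recovery
experiment from scratch under a caller-supplied seed.

Known limitations: the GEE solver offers no small-sample corrections and no
random slopes; decision-curve confidence bands and competing risks are out
of scope; the Gompertz fitter assumes administrative-style right censoring
and a correctly specified basis; and the full multi-measurement AnthropoAge
variant (beyond CA + BMI + WHtR) is intentionally not implemented.
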