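# anthropoage

Biological age from routine anthropometry, with the survival and
longitudinal machinery to validate it.

## What this solves

Most biological-age clocks need omics or biochemistry. This package
implements **AnthropoAge**, an age-scale biological-age proxy that needs
only chronological age (CA), measured height, weight and waist
circumference — measurements available in essentially every aging cohort.
It is aimed at epidemiologists and aging researchers working with
harmonized longitudinal panel studies who want a cheap, longitudinal
marker of accelerated aging plus the validation tooling around it.

The core idea: fit two sex-stratified Gompertz proportional-hazards
mortality models, one with hazard
`h(t) = exp(β₀ + β₁·CA)·exp(γ₀t)` (CA only), and one whose linear
predictor adds non-linear anthropometry,
`xb = rate + β_CA·CA + β_b1·ln BMI + β_b2·(ln BMI)² + β_w·WHtR^⅓`, with a
race/ethnicity-specific shape `γⱼ` (time `t` in months). Matching the two
models' CDFs at the 120-month horizon and solving for age gives the closed
form

    AnthropoAge = [ ln( −ln(1−M) / (γ₀⁻¹(e^{γ₀t}−1)) ) − β₀ ] / β₁

where `M` is the individual's 10-year death probability under the
anthropometry model. **AnthropoAgeAccel** is the residual of AnthropoAge
on CA (per sex); a positive residual defines accelerated aging.

Around that core the package provides, behind one consistent interface:

* a synthetic multi-study longitudinal cohort generator with known ground
  truth (`synth_config()`, `generate_panel()`, `inject_acceleration()`);
* anthropometric benchmarks (BRI, WWI, ABSI), functional/comorbidity
  scores, and the eligibility filters (ages 50–94; height 125–200 cm,
  weight 30–150 kg, waist 50–160 cm, BMI 10–60 kg/m²);
* Gompertz PH maximum likelihood with group-specific shapes
  (`fit_gompertz()`), plus a bit-exact coefficient-file round trip;
* IPCW discrimination (Uno's c, time-dependent AUC, paired bootstrap
  comparison), weighted stratified Cox, Kaplan–Meier, log-rank, and a
  Schoenfeld-residual PH test;
* decision curve analysis with IPCW handling of censoring;
* generalized estimating equations (Gaussian/Poisson/binomial, AR(1),
  sandwich errors, QIC) for population aging trends and new-onset outcome
  models;
* an end-to-end pipeline (`run_pipeline()`) producing the full report
  bundle as CSV tables.

## Worked example

```r
library(anthropoage)

cfg  <- synth_config(n_subjects = 500, seed = 42)   # 5 studies x 500 subjects
g    <- generate_panel(cfg)
elig <- apply_eligibility(g$panel)
base <- elig$kept[elig$kept$wave == 0, ]

sexes <- c("female", "male")
ca <- setNames(lapply(sexes, function(s)
  fit_gompertz_ca(base[base$sex == s, ], s)), sexes)
an <- setNames(lapply(sexes, function(s)
  fit_gompertz_anthro(base[base$sex == s, ], s)), sexes)
ca$female
#> Gompertz proportional-hazards fit (female)
#>   time unit: months  n = 1400  events = 320
#>   shape (per months ):
#>      all
#> 0.003318
#>   coefficients:
#>       rate        age
#> -12.646773   0.090409
#>   loglik: -2235.326

base$anthropoage <- anthropoage_batch(base, ca, an)
acc <- anthropoage_accel(base)          # residual on CA, per sex
base$accel       <- acc$accel
base$accelerated <- acc$accelerated
median(base$anthropoage)                # 62.3 years
mean(base$accelerated)                  # 0.498

uno_c(base$age,               base$follow_up_years, base$event)$estimate
#> 0.723
uno_c(base$age + base$accel,  base$follow_up_years, base$event)$estimate
#> 0.759

tb <- cox_table(fit_cox(base, ~ accelerated + age,
                        strata = c("sex", "ethnicity"),
                        weights_col = "svy_weight"))
tb[tb$term == "acceleratedTRUE", c("hr", "ci_low", "ci_high")]
#>     hr ci_low ci_high
#>   2.51   2.11    2.99
```

Reading these numbers: adding age acceleration to CA raises whole-follow-up
discrimination for mortality (Uno's c 0.723 → 0.759 on this synthetic
cohort), and subjects flagged as accelerated have about 2.5 times the
death hazard of their age-, sex- and ethnicity-matched peers — the
generator plants exactly this kind of signal, which is what makes the
recovery testable. The hazard ratio reflects the strength configured in
`synth_config()`, not any real-world effect size.

`run_pipeline(pipeline_config(panel, outdir))` runs the whole study replica
(eligibility accounting → model fits → biological ages → discrimination →
decision curves → Cox/KM → GEE trends → new-onset grid) and writes each
table as CSV with sample size, seed and a configuration hash in the header.

## Layout

* `R/` — implementation (generator, anthropometrics, Gompertz/AnthropoAge,
  survival evaluation, decision curves, GEE, pipeline)
* `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracles for every discrimination metric
* `vignettes/anthropoage-methods.Rmd` — model, assumptions, generator
  design, numerical conventions and limitations
* `scripts/acceptance.R` — the from-scratch reproduction script above
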