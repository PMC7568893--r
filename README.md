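# legcure

Cure-rate ("long-term") survival analysis for cohorts in which a
substantial fraction of subjects never experience the event of interest —
the situation of leukemia patients after bone marrow transplantation
(BMT), where the Kaplan–Meier curve plateaus well above zero and standard
survival models, which force survival to zero, are misspecified.

## The model

Each subject carries a latent number *M* of competing causes,
*M* ~ Geometric(*p*) with support {0, 1, 2, …}, and each cause activates
after an independent Exponential(λ) time; the event time is the minimum of
the *M* activation times, and *M* = 0 means the subject is cured. The
population survival function is

    S_pop(t) = p / (1 − (1 − p) e^(−λt)),

which starts at 1 and plateaus at the cure fraction *p*. Covariates act on
*p* through a logistic link, so exp(β_j) is the odds ratio of being cured.
The package fits (β, log λ) by right-censored maximum likelihood (BFGS
with analytic gradient, multistart), with Wald standard errors from a
finite-difference observed information matrix. Companions: Kaplan–Meier
estimation with Greenwood variances and a plateau-based cure-fraction
read-off, pairwise cure-odds contrasts between factor levels, a calibrated
synthetic BMT cohort generator, and a small file-based reporting pipeline
(`run_pipeline()`, also callable from a shell via `inst/cli/legcure.R`).

## Worked example

Simulate a 427-subject cohort from the default configuration (diagnosis
mix MM/NHL/HD/AML/ALL, 54.8 % male, mean age 38.7 y, mean Hb 10.9 g/dL,
administrative censoring on [731, 3288] days) and fit the model:

```r
library(legcure)
cohort <- generate_cohort(cohort_config(), seed = 1)
fit <- legcure(survival::Surv(time_days, event) ~ diagnosis + sex + bmi_cat +
               age_years + hb_pre + n_recurrence, data = cohort)
summary(fit)
#> LEG cure-rate model: Wald summary (odds ratios of being cured)
#> n = 427, events = 74, log-likelihood = -690.087
#>
#>  term         estimate se   p_value  OR   95% CI
#>  (Intercept)  -1.49    1.24 0.229    0.22 (0.02, 2.57)
#>  diagnosisMM  1.53     0.46 0.0008*  4.61 (1.89, 11.26)
#>  diagnosisNHL 1.31     0.55 0.017*   3.71 (1.26, 10.93)
#>  diagnosisHD  2.27     0.50 4.5e-06* 9.68 (3.67, 25.54)
#>  diagnosisAML 1.18     0.54 0.028*   3.27 (1.14, 9.37)
#>  sexmale      -0.49    0.30 0.1      0.61 (0.34, 1.10)
#>  bmi_catUW    1.49     0.89 0.095    4.43 (0.77, 25.43)
#>  bmi_catNW    0.76     0.45 0.095    2.13 (0.88, 5.18)
#>  bmi_catOW    -0.70    0.43 0.106    0.50 (0.21, 1.16)
#>  age_years    -0.08    0.01 2.1e-11* 0.92 (0.90, 0.94)
#>  hb_pre       0.44     0.09 1e-06*   1.56 (1.30, 1.86)
#>  n_recurrence -0.65    0.31 0.034*   0.52 (0.28, 0.95)
#>
#> lambda = 0.00035 per day (SE 0.00019)
```

Each row is a cure-logit coefficient: the fitted cure odds for HD patients
are 9.68 times those of the reference ALL group, and each additional year
of age multiplies the cure odds by 0.92 (an 8 % decrease). The
nonparametric side:

```r
km <- km_fit(cohort$time_days, cohort$event)
survival_at(km, c(365.25, 1095.75, 1826.25))   # 1-, 3-, 5-year survival
#>      horizon  survival    std_err    ci_low   ci_high beyond_data
#> all   365.25 0.9297424 0.01236842 0.9010472 0.9503451       FALSE
#> all1 1095.75 0.8770050 0.01598926 0.8417150 0.9048730       FALSE
#> all2 1826.25 0.8349901 0.01880409 0.7942597 0.8683300       FALSE
plateau_cure_fraction(km)
#> $cure_fraction      0.789   (KM estimate at the last event, day 2800)
#> $credible           TRUE    (censored follow-up extends past it)
cure_fraction(fit, cohort)$mean_percent
#> 73.9
pairwise_contrast(fit, "diagnosis", "HD", "NHL")
#>   level_a level_b estimate    se    z p_value odds_ratio ci_low ci_high
#> 1      HD     NHL    0.959 0.499 1.92  0.0548       2.61   0.98    6.94
```

So for this realization the 1/3/5-year survival probabilities are 93.0 %,
87.7 % and 83.5 %, the plateau read-off estimates a 78.9 % cure fraction
(the model-based cohort mean is 73.9 %), and the HD-vs-NHL cure odds ratio
is 2.61. With censoring ending before the susceptible distribution
resolves, single-cohort cure-fraction estimates are variable; the methods
vignette (`vignettes/leg-cure-model.Rmd`) discusses identifiability, the
`near_boundary` diagnostic, and the generator's calibration.

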