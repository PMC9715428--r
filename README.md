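# cd34yield

Predicting the first-day apheresis CD34+ harvest from the circulating
CD34+ count in pediatric stem-cell mobilization.

## The problem

Autologous transplant for pediatric cancers (high-risk neuroblastoma,
Ewing sarcoma, some lymphomas) requires collecting 2–5 × 10⁶ CD34+
cells/kg by apheresis. Whether mobilization (G-CSF ± chemotherapy,
rescued by plerixafor in poor mobilizers) has produced enough
circulating cells is read off the peripheral-blood CD34+ concentration
(PB-CD34+, 10⁶ cells/L) measured just before the first apheresis
session. `cd34yield` quantifies the link between that count and the
dose collected the same day (AP-CD34+, 10⁶ cells/kg), and inverts it
into a decision threshold: the smallest PB-CD34+ at which the
probability of reaching the target dose is 0.90.

## The model

A linear yield model with heteroscedastic normal error, fitted by full
maximum likelihood:

    AP = a(x) + b · PB + e,    e ~ N(0, sd(f)²),  f = a(x) + b · PB

with three residual structures: homogeneous `sd = σ`, proportional
`sd = σ|f|`, and combined `sd = σ(κ + |f|)`. The error structure and an
optional intercept-shift covariate (age, sex, mobilization type,
neuroblastoma-vs-other tumor, treatment arm) are selected by AIC; the
linear response scale is compared against `log(AP) ~ log(PB)` by sum of
absolute prediction errors. Given a fitted model, the count needed for
probability γ of collecting at least T is closed-form:

    f* = (T + zσκ) / (1 − zσ),   z = Φ⁻¹(γ),   pb* = (f* − a)/b

(requiring zσ < 1), with 90% confidence intervals from a 1000-replicate
case bootstrap. A synthetic-cohort generator emulating a 45-patient
pediatric mobilization study (2:1 plerixafor+G-CSF vs G-CSF alone)
makes every stage testable without access-controlled patient data; see
`vignettes/yield-model-methods.Rmd` for the model, the generator design
and its deliberate trade-offs.

## Worked example

Published parameter estimates can be used directly. The base model
(intercept 1.63, slope 0.12, combined error σ = 0.49, κ = 1.76) gives
the count needed for a 90% chance of a 2 × 10⁶ cells/kg harvest:

```r
library(cd34yield)
base <- yield_model(intercept = 1.63, slope = 0.12,
                    sigma = 0.49, kappa = 1.76, error = "combined")
invert_threshold(base, threshold = 2, probability = 0.90)
#> [1] 55.9704
```

About 56 × 10⁶ cells/L of circulating CD34+ cells are needed — patients
below that count are candidates for plerixafor rescue.

The full pipeline on the packaged synthetic demo cohort:

```r
cohort <- read_cohort(system.file("extdata", "synthetic_cohort_45.csv",
                                  package = "cd34yield"))
sel <- select_error_structure(cohort)
cov_sel <- select_covariates(cohort, error = sel$chosen)
cov_sel
#> Model selection by aic
#>     covariate n_params     loglik      aic converged
#>        (none)        3 -108.45290 222.9058      TRUE
#>     age_years        4 -107.05869 222.1174      TRUE
#>           sex        4 -108.26746 224.5349      TRUE
#>  mobilization        4 -105.38282 218.7656      TRUE
#>  tumor_binary        4  -98.54457 205.0891      TRUE
#>           arm        4 -108.10788 224.2158      TRUE
#> chosen: tumor_binary
#> tumor_binary AIC 205.09 vs age_years AIC 222.12 (tumor type preferred)

fit <- fit_yield_model(cohort, covariates = cov_sel$chosen,
                       error = sel$chosen)
ci <- bootstrap_inversion_ci(cohort, covariates = "tumor_binary",
                             error = sel$chosen, threshold = 2,
                             newdata = data.frame(tumor_binary = "neuroblastoma"),
                             n_boot = 1000, ci_level = 0.9, seed = 1)
ci
#> PB-CD34+ needed for P(AP >= 2) = 0.90 [neuroblastoma]: 17.30 (90% CI 8.82-24.41)

calibration(fit, cohort)
#>   threshold  n n_observed observed_prop observed_ci_low observed_ci_high
#> 1         2 45         40     0.8888889       0.7594642        0.9629233
#> 2         5 45         25     0.5555556       0.3999735        0.7035561
#>   predicted_prop inside_ci
#> 1      0.8547303      TRUE
#> 2      0.5260491      TRUE
```

Tumor type wins the covariate search by a wide AIC margin (it is
confounded with age — neuroblastoma patients are much younger — and the
report shows that comparison explicitly). For this simulated cohort a
neuroblastoma patient needs ≈17 × 10⁶ cells/L circulating CD34+ for a
90% chance of a 2 × 10⁶ cells/kg first-day harvest, and the
cohort-average predicted exceedance proportions sit inside the exact
95% binomial intervals of the observed proportions at both thresholds —
the model is well calibrated on its own data.

`run_pipeline()` chains all stages (structure selection → covariate
selection → final fit → inversions with bootstrap CIs → calibration)
and writes a JSON manifest; `simulate_cohort(cohort_config(...))`
generates fresh cohorts.

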