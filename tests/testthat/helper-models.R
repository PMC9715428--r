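# Reference models built from the published parameter estimates, and small
# generators used across tests.

base_model <- function() {
  yield_model(intercept = 1.63, slope = 0.12, sigma = 0.49, kappa = 1.76,
              error = "combined")
}

final_model <- function() {
  yield_model(covariate = "tumor_binary",
              intercepts = c(other = 0.01, neuroblastoma = 3.01),
              slope = 0.13, sigma = 0.54, kappa = 0, error = "combined")
}

# Minimal cohort with only the columns the fitting engine needs.
tiny_cohort <- function(pb, ap, tumor = NULL) {
  d <- data.frame(pb_cd34 = pb, ap_cd34 = ap)
  if (!is.null(tumor)) d$tumor_binary <- tumor
  d
}

# Model-consistent draws from the final-model truth (no truncation), for
# recovery and coverage experiments.
final_truth_cohort <- function(n, seed) {
  simulate_cohort(cohort_config(n = n, seed = seed,
                                negative_yields = "keep"))
}

# Mean of N(mean, sd) truncated to [lo, hi): the generator's actual
# conditional age expectation.
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}
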