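# Numerically stable softplus and its inverse; used to keep kappa >= 0
# during unconstrained optimization.
.softplus <- function(x) {
  out <- x
  i <- x <= 30
  out[i] <- log1p(exp(x[i]))
  out
}

.inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  out <- y
  i <- y <= 30
  out[i] <- log(expm1(y[i]))
  out
}

# d softplus / dx
.sigmoid <- function(x) stats::plogis(x)

# Canonical category vocabularies for cohort columns.
.cohort_levels <- list(
  age_group    = c("1-<6", "6-<12", ">=12"),
  sex          = c("female", "male"),
  mobilization = c("G-CSF", "G-CSF/chemotherapy"),
  tumor_type   = c("neuroblastoma", "ewing_sarcoma", "lymphoma", "other"),
  arm          = c("plerixafor+G-CSF", "G-CSF alone"),
  tumor_binary = c("other", "neuroblastoma")
)

.cohort_columns <- c("patient_id", "pb_cd34", "ap_cd34", "age_years",
                     "age_group", "sex", "mobilization", "tumor_type", "arm")

.allowed_covariates <- c("age_years", "sex", "mobilization", "tumor_binary",
                         "arm")
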