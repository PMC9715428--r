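#' Read a cohort CSV
#'
#' Reads a patient-level table with the declared header (`patient_id`,
#' `pb_cd34`, `ap_cd34`, `age_years`, `age_group`, `sex`, `mobilization`,
#' `tumor_type`, `arm`; decimal point, comma separator), validates it, and
#' returns a typed cohort.  Rows with missing or non-numeric counts and
#' unknown category levels are rejected with row-numbered messages.
#'
#' @param path Path to the CSV file.
#' @return A `cd34_cohort` data frame.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  raw <- raw[, .cohort_columns]

  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("missing or non-numeric '", col, "' on row(s) ",
           paste(bad, collapse = ", "))
    v
  }
  pb <- num("pb_cd34")
  ap <- num("ap_cd34")
  age <- num("age_years")
  if (any(pb < 0) || any(ap < 0))
    stop("negative counts on row(s) ",
         paste(which(pb < 0 | ap < 0), collapse = ", "))
  if (any(age <= 0))
    stop("non-positive age on row(s) ", paste(which(age <= 0), collapse = ", "))

  out <- data.frame(patient_id = raw$patient_id, pb_cd34 = pb, ap_cd34 = ap,
                    age_years = age, stringsAsFactors = FALSE)
  for (v in c("age_group", "sex", "mobilization", "tumor_type", "arm")) {
    vals <- raw[[v]]
    bad <- which(!vals %in% .cohort_levels[[v]])
    if (length(bad))
      stop("unknown '", v, "' value '", vals[bad[1]], "' on row ", bad[1])
    out[[v]] <- factor(vals, levels = .cohort_levels[[v]])
  }
  structure(out, class = c("cd34_cohort", "data.frame"))
}

#' Write a cohort CSV (and optional JSON metadata sidecar)
#'
#' @param cohort A `cd34_cohort` (or compatible data frame).
#' @param path Output CSV path.
#' @param metadata_path Optional path for a JSON sidecar recording the
#'   generator seed and configuration when the cohort carries them.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, metadata_path = NULL) {
  df <- as.data.frame(cohort)[, .cohort_columns]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    cfg <- attr(cohort, "config")
    meta <- list(seed = attr(cohort, "seed"), n = nrow(df))
    if (!is.null(cfg)) {
      meta$generator <- list(
        n = cfg$n, pb_median = cfg$pb_median, pb_log_sd = cfg$pb_log_sd,
        covariate_probs = cfg$covariate_probs,
        age_by_tumor = cfg$age_by_tumor, age_range = cfg$age_range,
        truth = list(coefficients = as.list(cfg$truth$coefficients),
                     sigma = cfg$truth$sigma, kappa = cfg$truth$kappa,
                     error = cfg$truth$spec$error,
                     covariates = cfg$truth$spec$covariates))
    }
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Reproduces the analysis sequence end to end on a cohort: (1) select the
#' residual error structure by AIC on the covariate-free base model,
#' (2) select an intercept-shift covariate by AIC at that structure,
#' (3) fit the final model, (4) invert the threshold queries at each level
#' of the selected covariate with case-bootstrap CIs, (5) summarise
#' calibration of the base and final models.  Deterministic given `seed`.
#'
#' @param data A cohort data frame, or `NULL` to simulate one from
#'   `generator`.
#' @param generator A [cohort_config()] used when `data` is `NULL`.
#' @param thresholds Target doses to invert (default `c(2, 5)`).
#' @param probability Target collection probability (default 0.90).
#' @param candidates Candidate covariates for selection.
#' @param n_boot Bootstrap resamples per inversion (default 1000).
#' @param ci_level Bootstrap CI level (default 0.90).
#' @param seed Integer seed driving the bootstrap (and, if `generator`
#'   carries no seed, the simulation).
#' @param output_dir Optional directory; when given, the manifest is
#'   written there as `manifest.json` and the cohort as `cohort.csv`.
#' @return A `cd34_manifest` list with every stage's report.
#' @export
run_pipeline <- function(data = NULL, generator = cohort_config(),
                         thresholds = c(2, 5), probability = 0.9,
                         candidates = c("age_years", "sex", "mobilization",
                                        "tumor_binary", "arm"),
                         n_boot = 1000, ci_level = 0.9, seed = 1,
                         output_dir = NULL) {
  if (is.null(data)) {
    if (is.null(generator$seed)) generator$seed <- seed
    data <- simulate_cohort(generator)
  }
  err_sel <- select_error_structure(data)
  cov_sel <- select_covariates(data, error = err_sel$chosen,
                               candidates = candidates)
  final <- fit_yield_model(data, covariates = cov_sel$chosen,
                           error = err_sel$chosen)
  base <- fit_yield_model(data, error = err_sel$chosen)

  # levels at which to invert: each level of a selected factor covariate,
  # the cohort mean for a continuous one, or the overall model otherwise
  levels_nd <- list(overall = NULL)
  if (length(cov_sel$chosen) == 1) {
    cv <- cov_sel$chosen
    if (cv %in% names(.cohort_levels)) {
      levels_nd <- lapply(.cohort_levels[[cv]], function(l)
        stats::setNames(data.frame(l, stringsAsFactors = FALSE), cv))
      names(levels_nd) <- .cohort_levels[[cv]]
    } else {
      levels_nd <- list(mean_age = data.frame(
        age_years = mean(.prepare_model_data(data, cv)[[cv]])))
    }
  }
  inversions <- list()
  i <- 0L
  for (tv in thresholds) for (lv in names(levels_nd)) {
    i <- i + 1L
    inversions[[paste0("T", tv, "_", lv)]] <- bootstrap_inversion_ci(
      data, covariates = cov_sel$chosen, error = err_sel$chosen,
      threshold = tv, probability = probability,
      newdata = levels_nd[[lv]], n_boot = n_boot, ci_level = ci_level,
      seed = seed + i)
  }
  calib <- list(base = calibration(base, data, thresholds),
                final = calibration(final, data, thresholds))

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("cd34yield")),
    seed = seed,
    n = nrow(data),
    error_structure = list(chosen = err_sel$chosen,
                           candidates = err_sel$candidates),
    covariate_selection = list(
      chosen = if (length(cov_sel$chosen)) cov_sel$chosen else "(none)",
      candidates = cov_sel$candidates,
      tumor_vs_age = cov_sel$tumor_vs_age),
    final_model = list(coefficients = as.list(final$coefficients),
                       sigma = final$sigma, kappa = final$kappa,
                       std_errors = as.list(final$std_errors),
                       loglik = final$loglik, aic = final$aic,
                       n_params = final$n_params,
                       converged = final$converged),
    inversions = lapply(inversions, function(x)
      x[c("pb_star", "clamped", "ci_low", "ci_high", "ci_level",
          "n_boot", "n_boot_failed", "query")]),
    calibration = calib
  ), class = "cd34_manifest")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(data, file.path(output_dir, "cohort.csv"),
                 file.path(output_dir, "cohort_meta.json"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  manifest
}
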