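# Deterministic min-criterion choice: smallest value wins; ties (within
# 1e-9) go to the candidate with fewer parameters, then to earlier
# candidate order.
.select_min <- function(values, n_params, tol = 1e-9) {
  stopifnot(length(values) == length(n_params), length(values) >= 1)
  best <- min(values)
  eligible <- which(values <= best + tol)
  eligible[order(n_params[eligible], eligible)][1]
}

#' Select the residual error structure by AIC
#'
#' Fits the covariate-free base model under the homogeneous, proportional
#' and combined error structures and returns the structure with the lowest
#' AIC.  Non-converged candidates are excluded with a warning; exact ties
#' break to the structure with fewer parameters, then to the candidate
#' order homogeneous, proportional, combined.
#'
#' @param data Cohort data frame.
#' @param covariates Covariates to include while comparing structures
#'   (default none, matching the base-model comparison).
#' @return A `cd34_selection` report: `candidates` table (structure,
#'   n_params, loglik, aic, converged), `chosen`, `criterion`.
#' @export
select_error_structure <- function(data, covariates = character()) {
  kinds <- c("homogeneous", "proportional", "combined")
  fits <- lapply(kinds, function(k)
    tryCatch(fit_yield_model(data, covariates = covariates, error = k,
                             se = FALSE),
             error = function(e) NULL))
  cand <- data.frame(
    structure = kinds,
    n_params = vapply(fits, function(f) if (is.null(f)) NA_integer_
                      else f$n_params, integer(1)),
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_
                    else f$loglik, numeric(1)),
    aic = vapply(fits, function(f) if (is.null(f)) NA_real_
                 else f$aic, numeric(1)),
    converged = vapply(fits, function(f) !is.null(f) && f$converged,
                       logical(1)),
    stringsAsFactors = FALSE)
  usable <- which(cand$converged)
  if (!length(usable)) stop("no error-structure candidate converged")
  if (length(usable) < length(kinds))
    warning("excluded non-converged structure(s): ",
            paste(kinds[!cand$converged], collapse = ", "))
  pick <- usable[.select_min(cand$aic[usable], cand$n_params[usable])]
  structure(list(candidates = cand, chosen = kinds[pick],
                 chosen_fit = fits[[pick]], criterion = "aic"),
            class = "cd34_selection")
}

#' Select an intercept-shift covariate by AIC
#'
#' Exhaustive search over the empty covariate set plus each single
#' candidate covariate, at a fixed error structure; the minimum-AIC
#' specification wins (ties break to fewer parameters, then candidate
#' order, with the empty set first).  When both `tumor_binary` and
#' `age_years` are among the candidates the report records their AIC
#' comparison explicitly, since tumor type and age are confounded in young
#' neuroblastoma populations.
#'
#' @param data Cohort data frame.
#' @param error Error structure fixed during the search.
#' @param candidates Character vector of candidate covariates.  Candidates
#'   that are constant in the cohort are excluded with a warning.
#' @return A `cd34_selection` report with `candidates` table (covariate
#'   `"(none)"` for the empty set), `chosen` (character vector, possibly
#'   empty), `chosen_fit`, and (when applicable) `tumor_vs_age`.
#' @export
select_covariates <- function(data, error = "combined",
                              candidates = c("age_years", "sex",
                                             "mobilization", "tumor_binary",
                                             "arm")) {
  if (!length(candidates)) stop("'candidates' must be nonempty")
  pd <- .prepare_model_data(data, intersect(candidates, .allowed_covariates))
  is_const <- vapply(candidates, function(v) {
    col <- pd[[v]]
    !is.null(col) && length(unique(as.character(col))) < 2
  }, logical(1))
  if (any(is_const)) {
    warning("excluded constant candidate(s): ",
            paste(candidates[is_const], collapse = ", "))
    candidates <- candidates[!is_const]
  }
  if (!length(candidates))
    stop("no usable candidate covariates (all constant)")

  specs <- c(list(character()), as.list(candidates))
  labels <- c("(none)", candidates)
  fits <- lapply(specs, function(cv)
    tryCatch(fit_yield_model(data, covariates = cv, error = error,
                             se = FALSE),
             error = function(e) NULL))
  cand <- data.frame(
    covariate = labels,
    n_params = vapply(fits, function(f) if (is.null(f)) NA_integer_
                      else f$n_params, integer(1)),
    loglik = vapply(fits, function(f) if (is.null(f)) NA_real_
                    else f$loglik, numeric(1)),
    aic = vapply(fits, function(f) if (is.null(f)) NA_real_
                 else f$aic, numeric(1)),
    converged = vapply(fits, function(f) !is.null(f) && f$converged,
                       logical(1)),
    stringsAsFactors = FALSE)
  usable <- which(cand$converged)
  if (!length(usable)) stop("no covariate candidate converged")
  pick <- usable[.select_min(cand$aic[usable], cand$n_params[usable])]

  tumor_vs_age <- NULL
  if (all(c("tumor_binary", "age_years") %in% labels)) {
    a_t <- cand$aic[cand$covariate == "tumor_binary"]
    a_a <- cand$aic[cand$covariate == "age_years"]
    tumor_vs_age <- list(aic_tumor = a_t, aic_age = a_a,
                         tumor_preferred = isTRUE(a_t < a_a))
  }
  structure(list(candidates = cand, chosen = specs[[pick]],
                 chosen_fit = fits[[pick]], criterion = "aic",
                 tumor_vs_age = tumor_vs_age),
            class = "cd34_selection")
}

#' Compare linear and log-transformed response scales
#'
#' Fits the yield model on the natural scale and as
#' `log(AP) = a + b log(PB) + e`, then compares the in-sample sums of
#' absolute prediction errors on the original cells/kg scale (log-model
#' predictions back-transformed by naive exponentiation, without smearing
#' correction).  The model with the smaller sum wins; ties break to the
#' linear scale.  Rows with non-positive AP or PB, which the log model
#' cannot use, are excluded from both fits (with a message) so the two
#' error sums cover the same patients.
#'
#' @param data Cohort data frame.
#' @param error Error structure used for both fits (default homogeneous,
#'   matching a comparison made before any error-structure modelling).
#' @param covariates Optional intercept-shift covariates for both fits.
#' @return A `cd34_selection` report with `candidates` table (scale,
#'   sum_abs_error), `chosen` (`"linear"` or `"log"`), both fits, and
#'   `n_excluded`.
#' @export
compare_linear_log <- function(data, error = "homogeneous",
                               covariates = character()) {
  data <- as.data.frame(data)
  bad <- data$ap_cd34 <= 0 | data$pb_cd34 <= 0 |
    !is.finite(data$ap_cd34) | !is.finite(data$pb_cd34)
  if (all(bad)) stop("no rows with positive ap_cd34 and pb_cd34")
  if (any(bad)) {
    message("excluding ", sum(bad),
            " row(s) with non-positive counts from both fits")
    data <- data[!bad, , drop = FALSE]
  }
  fit_lin <- fit_yield_model(data, covariates = covariates, error = error,
                             response_scale = "linear", se = FALSE)
  fit_log <- fit_yield_model(data, covariates = covariates, error = error,
                             response_scale = "log", se = FALSE)
  pred_lin <- predict_mean(fit_lin, data)
  pred_log <- exp(predict_mean(fit_log, data))
  sums <- c(linear = sum(abs(data$ap_cd34 - pred_lin)),
            log = sum(abs(data$ap_cd34 - pred_log)))
  chosen <- if (sums["log"] < sums["linear"] - 1e-12) "log" else "linear"
  structure(list(
    candidates = data.frame(scale = names(sums),
                            sum_abs_error = unname(sums),
                            stringsAsFactors = FALSE),
    chosen = chosen,
    fits = list(linear = fit_lin, log = fit_log),
    criterion = "sum_abs_error",
    n_excluded = sum(bad)
  ), class = "cd34_selection")
}

#' @export
print.cd34_selection <- function(x, ...) {
  cat("Model selection by", x$criterion, "\n")
  print(x$candidates, row.names = FALSE)
  ch <- if (is.character(x$chosen) && !length(x$chosen)) "(none)"
        else paste(x$chosen, collapse = ", ")
  cat("chosen:", ch, "\n")
  if (!is.null(x$tumor_vs_age))
    cat(sprintf("tumor_binary AIC %.2f vs age_years AIC %.2f (%s preferred)\n",
                x$tumor_vs_age$aic_tumor, x$tumor_vs_age$aic_age,
                if (x$tumor_vs_age$tumor_preferred) "tumor type" else "age"))
  invisible(x)
}
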