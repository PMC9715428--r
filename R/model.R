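#' Construct a yield model from known parameters
#'
#' Builds a `cd34_fit` object directly from parameter values, without
#' fitting.  This is how published parameter estimates (for example an
#' intercept/slope pair with a combined error structure) are turned into a
#' model object usable with [predict_mean()], [threshold_probability()] and
#' [invert_threshold()].
#'
#' The structural model is `AP-CD34+ = intercept + slope * PB-CD34+`, with
#' a zero-mean normal residual whose standard deviation follows the chosen
#' error structure (see [residual_sd()]).  A single categorical covariate
#' can shift the intercept: supply `covariate` and a named `intercepts`
#' vector with one intercept per level (the slope is shared).
#'
#' @param intercept Intercept, 10^6 cells/kg.  Ignored when `intercepts`
#'   is supplied.
#' @param slope Slope, (10^6 cells/kg) per (10^6 cells/L).
#' @param sigma Residual scale parameter, > 0.
#' @param kappa Additive variance component (10^6 cells/kg), >= 0; required
#'   for (and only meaningful with) the combined error structure.
#' @param error Error structure: `"combined"`, `"proportional"` or
#'   `"homogeneous"`.
#' @param covariate Optional name of a single categorical covariate whose
#'   levels get their own intercepts (e.g. `"tumor_binary"`).
#' @param intercepts Named numeric vector of per-level intercepts when
#'   `covariate` is given; the first name is the baseline level.
#' @param response_scale `"linear"` (default) or `"log"`.
#' @return An object of class `cd34_fit`.
#' @examples
#' base <- yield_model(intercept = 1.63, slope = 0.12,
#'                     sigma = 0.49, kappa = 1.76, error = "combined")
#' predict_mean(base, 57.01)
#' @export
yield_model <- function(intercept = NULL, slope, sigma, kappa = NULL,
                        error = c("combined", "homogeneous", "proportional"),
                        covariate = NULL, intercepts = NULL,
                        response_scale = c("linear", "log")) {
  error <- match.arg(error)
  response_scale <- match.arg(response_scale)
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (error == "combined") {
    if (is.null(kappa)) stop("combined error structure requires 'kappa'")
    if (kappa < 0) stop("'kappa' must be >= 0")
  } else if (!is.null(kappa)) {
    stop("'kappa' is only defined for the combined error structure")
  }

  pb_term <- if (response_scale == "log") "log(pb_cd34)" else "pb_cd34"
  resp <- if (response_scale == "log") "log(ap_cd34)" else "ap_cd34"

  if (is.null(covariate)) {
    if (is.null(intercept)) stop("supply 'intercept' (or covariate + intercepts)")
    fml <- stats::reformulate(pb_term, response = resp)
    coefs <- c("(Intercept)" = intercept, slope)
    names(coefs)[2] <- pb_term
    xlev <- list()
    covariates <- character()
  } else {
    if (is.null(intercepts) || is.null(names(intercepts)))
      stop("supply a named 'intercepts' vector, one entry per level of the covariate")
    fml <- stats::reformulate(c(pb_term, covariate), response = resp)
    lev <- names(intercepts)
    coefs <- c(intercepts[[1]], slope, intercepts[-1] - intercepts[[1]])
    names(coefs) <- c("(Intercept)", pb_term, paste0(covariate, lev[-1]))
    xlev <- stats::setNames(list(lev), covariate)
    covariates <- covariate
  }

  structure(list(
    spec = list(covariates = covariates, error = error,
                response_scale = response_scale),
    coefficients = coefs,
    sigma = sigma,
    kappa = if (error == "combined") kappa else NULL,
    terms = stats::terms(fml),
    xlevels = xlev,
    loglik = NA_real_, aic = NA_real_,
    n_params = length(coefs) + 1L + (error == "combined"),
    std_errors = NULL, n_obs = NA_integer_,
    converged = TRUE
  ), class = "cd34_fit")
}

# Coerce input data to the columns a model formula needs: derives
# tumor_binary from tumor_type, applies canonical factor levels, validates
# covariate names.
.prepare_model_data <- function(data, covariates) {
  data <- as.data.frame(data)
  bad <- setdiff(covariates, .allowed_covariates)
  if (length(bad))
    stop("unsupported covariate(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.allowed_covariates, collapse = ", "), ")")
  if ("tumor_binary" %in% covariates && is.null(data$tumor_binary)) {
    if (is.null(data$tumor_type))
      stop("'tumor_binary' requires a 'tumor_type' (or 'tumor_binary') column")
    data$tumor_binary <- ifelse(as.character(data$tumor_type) == "neuroblastoma",
                                "neuroblastoma", "other")
  }
  for (v in intersect(c("sex", "mobilization", "arm", "tumor_binary"),
                      covariates)) {
    vals <- as.character(data[[v]])
    unknown <- setdiff(unique(vals), .cohort_levels[[v]])
    if (length(unknown))
      stop("unknown level(s) in '", v, "': ", paste(unknown, collapse = ", "))
    data[[v]] <- factor(vals, levels = .cohort_levels[[v]])
  }
  data
}

# Build response vector and design matrix (intercept, PB term, covariate
# shifts) for a model spec.  xlev pins factor codings when predicting or
# refitting bootstrap resamples.
.make_model_frame <- function(data, covariates, response_scale,
                              xlev = NULL, require_response = TRUE) {
  pd <- .prepare_model_data(data, covariates)
  pb_term <- if (response_scale == "log") "log(pb_cd34)" else "pb_cd34"
  resp <- if (response_scale == "log") "log(ap_cd34)" else "ap_cd34"
  fml <- stats::reformulate(c(pb_term, covariates),
                            response = if (require_response) resp else NULL)
  tt <- stats::terms(fml)
  mf <- stats::model.frame(tt, pd, xlev = xlev, na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  y <- if (require_response) stats::model.response(mf) else NULL
  list(X = X, y = y, terms = tt,
       xlevels = stats::.getXlevels(tt, mf))
}

#' Model-predicted mean yield
#'
#' Evaluates the structural prediction `f_pred = intercept(covariates) +
#' slope * PB-CD34+` on the model's response scale.
#'
#' @param model A `cd34_fit`.
#' @param newdata A data frame containing `pb_cd34` and any covariates the
#'   model uses, or a bare numeric vector of PB-CD34+ counts for a model
#'   without covariates.
#' @return Numeric vector of predicted mean AP-CD34+ (10^6 cells/kg), on
#'   the log scale for log-response models.
#' @export
predict_mean <- function(model, newdata) {
  stopifnot(inherits(model, "cd34_fit"))
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    if (length(model$spec$covariates))
      stop("model uses covariates; supply 'newdata' as a data frame")
    newdata <- data.frame(pb_cd34 = newdata)
  }
  if (any(newdata$pb_cd34 < 0, na.rm = TRUE))
    stop("'pb_cd34' must be >= 0")
  tt <- stats::delete.response(model$terms)
  pd <- .prepare_model_data(newdata, model$spec$covariates)
  mf <- tryCatch(
    stats::model.frame(tt, pd, xlev = model$xlevels,
                       na.action = stats::na.fail),
    error = function(e) stop("cannot evaluate model on newdata: ",
                             conditionMessage(e), call. = FALSE))
  X <- stats::model.matrix(tt, mf)
  drop(X %*% model$coefficients[colnames(X)])
}

#' Residual standard deviation at a given predicted mean
#'
#' The three residual-error structures give, for a prediction `f`:
#' homogeneous `sigma`; proportional `sigma * |f|`; combined
#' `sigma * (kappa + |f|)`.
#'
#' @param model A `cd34_fit`.
#' @param f_pred Numeric vector of predicted means.
#' @return Numeric vector of residual standard deviations.
#' @export
residual_sd <- function(model, f_pred) {
  stopifnot(inherits(model, "cd34_fit"))
  switch(model$spec$error,
         homogeneous  = rep_len(model$sigma, length(f_pred)),
         proportional = model$sigma * abs(f_pred),
         combined     = model$sigma * (model$kappa + abs(f_pred)))
}

#' Negative log-likelihood of a yield model at given parameters
#'
#' Evaluates `-sum(log phi(y_i; f_i, sd_i^2))` for the Gaussian
#' heteroscedastic model, where `f_i` is the structural prediction and
#' `sd_i` follows the error structure.  Returns `+Inf` when any residual
#' SD is non-positive at the supplied parameters (for example a
#' proportional structure evaluated where a prediction is exactly zero),
#' so optimizers steer away from the region.
#'
#' @param params List with elements `coefficients` (named as in a fitted
#'   model: `"(Intercept)"`, `"pb_cd34"` and covariate shift terms),
#'   `sigma` (> 0) and, for the combined structure, `kappa` (>= 0).
#' @param data Cohort data frame with `pb_cd34`, `ap_cd34` and covariates.
#' @param covariates Character vector of intercept-shift covariates.
#' @param error Error structure kind.
#' @param response_scale `"linear"` or `"log"`.
#' @return A single number (possibly `Inf`).
#' @export
yield_nll <- function(params, data, covariates = character(),
                      error = c("combined", "homogeneous", "proportional"),
                      response_scale = c("linear", "log")) {
  error <- match.arg(error)
  response_scale <- match.arg(response_scale)
  if (any(!is.finite(data$pb_cd34)) || any(!is.finite(data$ap_cd34)))
    stop("non-finite values in 'pb_cd34'/'ap_cd34'")
  mfr <- .make_model_frame(data, covariates, response_scale)
  beta <- params$coefficients[colnames(mfr$X)]
  if (any(is.na(beta))) stop("missing coefficient(s) for design columns")
  f <- drop(mfr$X %*% beta)
  s <- switch(error,
              homogeneous  = rep_len(params$sigma, length(f)),
              proportional = params$sigma * abs(f),
              combined     = params$sigma * (params$kappa + abs(f)))
  if (any(s <= 0)) return(Inf)
  r <- mfr$y - f
  sum(log(s) + r^2 / (2 * s^2)) + length(r) / 2 * log(2 * pi)
}

#' @export
print.cd34_fit <- function(x, ...) {
  cat("Yield model (", x$spec$error, " error, ", x$spec$response_scale,
      " response)\n", sep = "")
  cat("Structural coefficients:\n")
  print(round(x$coefficients, 4))
  cat("sigma =", format(x$sigma, digits = 4))
  if (!is.null(x$kappa)) cat(", kappa =", format(x$kappa, digits = 4))
  cat("\n")
  if (is.finite(x$loglik))
    cat("logLik =", format(x$loglik, digits = 6),
        " AIC =", format(x$aic, digits = 6),
        " (k =", x$n_params, ", n =", x$n_obs, ")\n")
  if (!is.null(x$converged) && !x$converged)
    cat("WARNING: optimizer did not converge\n")
  invisible(x)
}
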