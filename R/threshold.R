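#' Probability of reaching a harvest threshold
#'
#' Under the fitted normal error model, the probability that a patient with
#' predicted mean `f` collects at least `threshold` (10^6 cells/kg) is
#' `1 - pnorm((threshold - f) / sd(f))`.  For log-response models the
#' comparison is made on the log scale.
#'
#' @param model A converged `cd34_fit`.
#' @param newdata Data frame with `pb_cd34` and model covariates, or a
#'   numeric PB-CD34+ vector for covariate-free models.
#' @param threshold Target AP-CD34+ dose, 10^6 cells/kg (> 0).
#' @return Numeric vector of exceedance probabilities.
#' @examples
#' base <- yield_model(intercept = 1.63, slope = 0.12,
#'                     sigma = 0.49, kappa = 1.76, error = "combined")
#' threshold_probability(base, 57.01, threshold = 2)
#' @export
threshold_probability <- function(model, newdata, threshold) {
  stopifnot(inherits(model, "cd34_fit"), threshold > 0)
  if (!isTRUE(model$converged)) stop("model did not converge")
  f <- predict_mean(model, newdata)
  s <- residual_sd(model, f)
  if (any(s <= 0)) stop("residual SD is not positive at the query point")
  tt <- if (model$spec$response_scale == "log") log(threshold) else threshold
  1 - stats::pnorm((tt - f) / s)
}

#' Minimal circulating count attaining a target collection probability
#'
#' Solves for the smallest PB-CD34+ count `pb*` at which
#' `P(AP-CD34+ >= threshold) = probability`.  With `z = qnorm(probability)`
#' the required mean is, in closed form, `f* = threshold + z*sigma`
#' (homogeneous), `f* = threshold / (1 - z*sigma)` (proportional) or
#' `f* = (threshold + z*sigma*kappa) / (1 - z*sigma)` (combined), and
#' `pb* = (f* - intercept) / slope`.  A finite solution requires
#' `z*sigma < 1` for the proportional/combined structures.  A negative
#' `pb*` is reported as 0 with attribute `clamped = TRUE`, meaning the
#' threshold is attainable at any circulating count.
#'
#' @param model A converged linear-response `cd34_fit` with positive slope.
#' @param threshold Target dose, 10^6 cells/kg.
#' @param probability Target probability in (0, 1); default 0.90.
#' @param newdata Optional one-row data frame fixing the covariate level
#'   at which to invert (required when the model has covariates).
#' @param method `"closed_form"` (default) or `"numeric"` (bisection on
#'   the exceedance probability; also used automatically in the corner
#'   case where the closed form would place `f*` below zero).
#' @return The minimal PB-CD34+ count (10^6 cells/L), with attributes
#'   `f_star` (required mean yield), `pb_raw` (the unclamped solution,
#'   negative when the threshold is reachable at any count) and `clamped`.
#' @examples
#' base <- yield_model(intercept = 1.63, slope = 0.12,
#'                     sigma = 0.49, kappa = 1.76, error = "combined")
#' invert_threshold(base, threshold = 2, probability = 0.90)
#' @export
invert_threshold <- function(model, threshold, probability = 0.9,
                             newdata = NULL,
                             method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "cd34_fit"),
            threshold > 0, probability > 0, probability < 1)
  if (!isTRUE(model$converged)) stop("model did not converge")
  if (model$spec$response_scale == "log")
    stop("inversion is defined for linear-response models")
  if (length(model$spec$covariates) && is.null(newdata))
    stop("model uses covariates; supply 'newdata' (one row) to fix the level")
  pb_term <- "pb_cd34"
  slope <- unname(model$coefficients[[pb_term]])
  if (slope <= 0) stop("inversion requires a positive slope")
  nd0 <- if (is.null(newdata)) data.frame(pb_cd34 = 0)
         else { newdata <- as.data.frame(newdata)[1, , drop = FALSE]
                newdata$pb_cd34 <- 0; newdata }
  intercept <- unname(predict_mean(model, nd0))

  z <- stats::qnorm(probability)
  sig <- model$sigma
  kap <- switch(model$spec$error, homogeneous = NA_real_,
                proportional = 0, combined = model$kappa)

  f_star <- if (model$spec$error == "homogeneous") {
    threshold + z * sig
  } else {
    if (z * sig >= 1)
      stop("no finite count attains probability ", probability,
           " (z*sigma >= 1)")
    (threshold + z * sig * kap) / (1 - z * sig)
  }
  # The closed form assumes f* >= 0 (it uses sd(|f|)); fall back to the
  # root-finder in the rare regime (probability < 0.5, large kappa) where
  # it does not.
  if (method == "numeric" || f_star < 0) {
    g <- function(pb) {
      nd <- nd0
      nd$pb_cd34 <- pb
      threshold_probability(model, nd, threshold) - probability
    }
    if (g(0) >= 0) {
      pb <- 0
      attr(pb, "f_star") <- intercept
      attr(pb, "pb_raw") <- 0
      attr(pb, "clamped") <- TRUE
      return(pb)
    }
    up <- max(1, (threshold - intercept) / slope * 2 + 1)
    while (g(up) < 0 && up < 1e12) up <- up * 2
    if (g(up) < 0) stop("no finite count attains probability ", probability)
    pb <- stats::uniroot(g, c(0, up), tol = 1e-12)$root
    attr(pb, "f_star") <- intercept + slope * pb
    attr(pb, "pb_raw") <- pb
    attr(pb, "clamped") <- FALSE
    return(pb)
  }

  pb_raw <- (f_star - intercept) / slope
  clamped <- pb_raw < 0
  pb <- if (clamped) 0 else pb_raw
  attr(pb, "f_star") <- f_star
  attr(pb, "pb_raw") <- pb_raw
  attr(pb, "clamped") <- clamped
  pb
}

#' Bootstrap confidence interval for the threshold inversion
#'
#' Nonparametric case bootstrap: patients are resampled with replacement
#' (resample size = n), the full model is refitted on each replicate and
#' the inversion recomputed; the CI is the percentile interval of the
#' replicate `pb*` values.  Replicates whose refit fails to converge or
#' admits no finite inversion are dropped and counted in `n_boot_failed`.
#' Deterministic given `seed`.
#'
#' @param data Cohort data frame.
#' @param covariates,error Model specification passed to
#'   [fit_yield_model()].
#' @param threshold,probability Inversion query as in [invert_threshold()].
#' @param newdata Covariate level at which to invert (one row), when the
#'   model has covariates.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param ci_level Confidence level of the percentile interval (default
#'   0.90).
#' @param seed Integer seed for the resampling.
#' @param max_fail_frac Error out when more than this fraction of
#'   replicates fails (default 0.2); set to 1 to always tolerate failures.
#' @return An object of class `cd34_inversion`: list with `pb_star`,
#'   `ci_low`, `ci_high`, `ci_level`, `n_boot`, `n_boot_failed`, `query`,
#'   and the replicate values in `boot_values`.
#' @export
bootstrap_inversion_ci <- function(data, covariates = character(),
                                   error = "combined",
                                   threshold, probability = 0.9,
                                   newdata = NULL,
                                   n_boot = 1000, ci_level = 0.9,
                                   seed = NULL, max_fail_frac = 0.2) {
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1)
  data <- as.data.frame(data)
  n <- nrow(data)
  fit <- fit_yield_model(data, covariates = covariates, error = error,
                         se = FALSE)
  if (!fit$converged) stop("full-data fit did not converge")
  pb_hat <- invert_threshold(fit, threshold, probability, newdata)

  # Resampling loop works on the prebuilt design matrix: each replicate
  # refits from the full-data solution (warm start) and inverts in closed
  # form, so a replicate costs one optimizer run and nothing else.
  mfr <- .make_model_frame(data, covariates, fit$spec$response_scale,
                           xlev = fit$xlevels)
  X <- mfr$X
  y <- mfr$y
  tt <- stats::delete.response(fit$terms)
  nd0 <- if (is.null(newdata)) data.frame(pb_cd34 = 0)
         else { nd <- as.data.frame(newdata)[1, , drop = FALSE]
                nd$pb_cd34 <- 0; nd }
  x0 <- stats::model.matrix(
    tt, stats::model.frame(tt, .prepare_model_data(nd0, covariates),
                           xlev = fit$xlevels))[1, colnames(X)]
  slope_col <- match("pb_cd34", colnames(X))
  z <- stats::qnorm(probability)
  invert_raw <- function(beta, sigma, kappa) {
    slope <- beta[slope_col]
    if (slope <= 0) return(NA_real_)
    f_star <- if (error == "homogeneous") threshold + z * sigma
              else {
                if (z * sigma >= 1) return(NA_real_)
                (threshold + z * sigma * kappa) / (1 - z * sigma)
              }
    if (f_star < 0) return(NA_real_)
    max(0, (f_star - sum(x0 * beta)) / slope)
  }

  theta_full <- .ml_starts(X, y, error,
                           start = list(coefficients = fit$coefficients,
                                        sigma = fit$sigma,
                                        kappa = fit$kappa),
                           multi_start = FALSE)[[1]]
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot_pb <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    boot_pb[b] <- tryCatch({
      Xb <- X[idx[b, ], , drop = FALSE]
      yb <- y[idx[b, ]]
      if (any(apply(Xb[, -1L, drop = FALSE], 2, stats::sd) == 0))
        NA_real_
      else {
        rb <- .fit_ml_core(Xb, yb, error, starts = list(theta_full),
                           reltol = 1e-10)
        if (is.null(rb) || !rb$converged) NA_real_
        else invert_raw(rb$beta, rb$sigma, rb$kappa)
      }
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(boot_pb))
  if (n_failed > max_fail_frac * n_boot)
    stop(n_failed, "/", n_boot, " bootstrap replicates failed ",
         "(limit ", max_fail_frac * 100, "%)")
  ok <- boot_pb[!is.na(boot_pb)]
  alpha <- (1 - ci_level) / 2
  ci <- unname(stats::quantile(ok, c(alpha, 1 - alpha)))
  if (as.numeric(pb_hat) < ci[1] || as.numeric(pb_hat) > ci[2])
    warning("percentile interval does not contain the point estimate")
  structure(list(
    pb_star = as.numeric(pb_hat),
    clamped = isTRUE(attr(pb_hat, "clamped")),
    ci_low = ci[1], ci_high = ci[2], ci_level = ci_level,
    n_boot = n_boot, n_boot_failed = n_failed,
    query = list(threshold = threshold, probability = probability,
                 covariate_level = newdata),
    boot_values = boot_pb
  ), class = "cd34_inversion")
}

#' @export
print.cd34_inversion <- function(x, ...) {
  lvl <- if (is.null(x$query$covariate_level)) ""
         else paste0(" [", paste(unlist(x$query$covariate_level),
                                 collapse = ", "), "]")
  cat(sprintf(
    "PB-CD34+ needed for P(AP >= %g) = %.2f%s: %.2f (%d%% CI %.2f-%.2f)\n",
    x$query$threshold, x$query$probability, lvl, x$pb_star,
    round(100 * x$ci_level), x$ci_low, x$ci_high))
  if (x$n_boot_failed > 0)
    cat(sprintf("  (%d of %d bootstrap replicates failed)\n",
                x$n_boot_failed, x$n_boot))
  invisible(x)
}

#' Probability-vs-count curve for one or more thresholds
#'
#' Tabulates [threshold_probability()] over a grid of PB-CD34+ counts,
#' producing the numeric content of a predicted-probability curve.
#'
#' @param model A converged `cd34_fit`.
#' @param pb Numeric grid of PB-CD34+ counts.
#' @param thresholds Vector of target doses (default `c(2, 5)`).
#' @param newdata Optional one-row covariate data frame.
#' @return Long data frame with columns `pb_cd34`, `threshold`,
#'   `probability`.
#' @export
probability_curve <- function(model, pb, thresholds = c(2, 5),
                              newdata = NULL) {
  out <- lapply(thresholds, function(tv) {
    nd <- if (is.null(newdata)) data.frame(pb_cd34 = pb)
          else cbind(as.data.frame(newdata)[rep(1, length(pb)), , drop = FALSE],
                     pb_cd34 = pb)
    data.frame(pb_cd34 = pb, threshold = tv,
               probability = threshold_probability(model, nd, tv))
  })
  do.call(rbind, out)
}
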