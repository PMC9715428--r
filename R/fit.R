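# Internal: negative log-likelihood and gradient on the optimizer scale.
# theta = (beta..., log_sigma [, kappa_raw]) with kappa = softplus(kappa_raw).
# Returns closures sharing X, y to keep bootstrap refits cheap.
.nll_machinery <- function(X, y, error, fix_kappa = NULL) {
  n <- length(y)
  p <- ncol(X)
  has_kappa <- error == "combined" && is.null(fix_kappa)
  const <- n / 2 * log(2 * pi)

  sd_of <- function(f, sigma, kappa) {
    switch(error,
           homogeneous  = rep_len(sigma, n),
           proportional = sigma * abs(f),
           combined     = sigma * (kappa + abs(f)))
  }
  unpack <- function(theta) {
    kappa <- if (error != "combined") 0
             else if (has_kappa) .softplus(theta[p + 2L]) else fix_kappa
    list(beta = theta[seq_len(p)], sigma = exp(theta[p + 1L]), kappa = kappa)
  }
  nll <- function(theta) {
    pr <- unpack(theta)
    f <- drop(X %*% pr$beta)
    s <- sd_of(f, pr$sigma, pr$kappa)
    if (any(s <= 0) || any(!is.finite(s))) return(1e10)
    r <- y - f
    v <- sum(log(s) + r^2 / (2 * s^2)) + const
    if (!is.finite(v)) 1e10 else v
  }
  grad <- function(theta) {
    pr <- unpack(theta)
    f <- drop(X %*% pr$beta)
    s <- sd_of(f, pr$sigma, pr$kappa)
    if (any(s <= 0) || any(!is.finite(s))) return(rep(0, length(theta)))
    r <- y - f
    # dNLL/df = -r/s^2 + (ds/df) * (1/s - r^2/s^3); ds/df = sigma*sign(f)
    # except for the homogeneous structure where it is 0.
    dsdf <- if (error == "homogeneous") 0 else pr$sigma * sign(f)
    dndf <- -r / s^2 + dsdf * (1 / s - r^2 / s^3)
    g_beta <- drop(crossprod(X, dndf))
    g_lsig <- sum(1 - r^2 / s^2)          # s scales with sigma in all cases
    g <- c(g_beta, g_lsig)
    if (has_kappa)
      g <- c(g, .sigmoid(theta[p + 2L]) * pr$sigma * sum(1 / s - r^2 / s^3))
    g
  }
  list(nll = nll, grad = grad, unpack = unpack, has_kappa = has_kappa, p = p)
}

# Internal matrix-level ML core shared by fit_yield_model() and the
# bootstrap loop (which cannot afford model-frame rebuilding per
# replicate).  `starts` is a list of theta vectors on the optimizer scale.
.fit_ml_core <- function(X, y, error, fix_kappa = NULL, starts,
                         reltol = 1e-12) {
  mach <- .nll_machinery(X, y, error, fix_kappa)
  best <- NULL
  for (th0 in starts) {
    op <- tryCatch(
      stats::optim(th0, mach$nll, mach$grad, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (!is.null(best) && best$convergence != 0) {
    op <- tryCatch(stats::optim(best$par, mach$nll, method = "Nelder-Mead",
                                control = list(maxit = 2000,
                                               reltol = reltol)),
                   error = function(e) NULL)
    if (!is.null(op) && op$value <= best$value) best <- op
  }
  if (is.null(best)) return(NULL)
  pr <- mach$unpack(best$par)
  list(theta = best$par, beta = pr$beta,
       sigma = unname(pr$sigma), kappa = unname(pr$kappa),
       loglik = -best$value,
       converged = best$convergence == 0 && best$value < 1e9,
       machinery = mach)
}

# OLS-based starting thetas for .fit_ml_core.
.ml_starts <- function(X, y, error, fix_kappa = NULL, start = NULL,
                       multi_start = TRUE) {
  has_kappa <- error == "combined" && is.null(fix_kappa)
  theta_of <- function(beta, sigma, kappa) {
    th <- c(beta, log(sigma))
    if (has_kappa) th <- c(th, .inv_softplus(max(kappa, 1e-4)))
    th
  }
  ols <- stats::lm.fit(X, y)
  f0 <- drop(X %*% ols$coefficients)
  r0 <- y - f0
  sig0 <- switch(error,
                 homogeneous  = max(stats::sd(r0), 1e-8),
                 proportional = max(stats::sd(r0 / pmax(abs(f0), 1e-6)), 1e-8),
                 combined     = max(stats::sd(r0 / (1 + abs(f0))), 1e-8))
  starts <- list()
  if (!is.null(start)) {
    beta_s <- start$coefficients[colnames(X)]
    if (!any(is.na(beta_s)))
      starts <- c(starts, list(theta_of(
        beta_s, start$sigma,
        if (is.null(start$kappa)) 1 else start$kappa)))
  }
  starts <- c(starts, list(theta_of(ols$coefficients, sig0, 1)))
  if (multi_start)
    starts <- c(starts,
                list(theta_of(ols$coefficients, sig0 * 3, 0.1),
                     theta_of(ols$coefficients, sig0 / 3, 3)))
  starts
}

#' Fit a yield model by maximum likelihood
#'
#' Fits `AP-CD34+ = intercept(covariates) + slope * PB-CD34+ + e` where the
#' residual `e` is zero-mean normal with standard deviation given by the
#' chosen error structure (see [residual_sd()]).  Because the residual
#' variance depends on the structural prediction, the structural and
#' variance parameters are estimated jointly by full maximum likelihood:
#' ordinary least squares supplies starting values, positivity of `sigma`
#' and `kappa` is enforced by log / softplus reparametrisation, and several
#' perturbed starts guard against local optima.  Standard errors come from
#' the observed information (numerical Hessian at the optimum, delta method
#' for `sigma` and `kappa`).
#'
#' @param data Cohort data frame (e.g. from [simulate_cohort()] or
#'   [read_cohort()]) with columns `pb_cd34`, `ap_cd34` and any covariates.
#' @param covariates Character vector of intercept-shift covariates, a
#'   subset of `age_years`, `sex`, `mobilization`, `tumor_binary`, `arm`
#'   (`tumor_binary` is derived from `tumor_type` as
#'   neuroblastoma-vs-other).  Default: none (the base model).
#' @param error Residual error structure.
#' @param response_scale `"linear"` fits AP on its natural scale;
#'   `"log"` fits `log(AP) ~ log(PB)` (all responses must be positive).
#' @param start Optional named list `list(coefficients=, sigma=, kappa=)`
#'   used as the (single) starting point, e.g. to warm-start bootstrap
#'   refits.
#' @param se Compute standard errors (default `TRUE`); disable for speed
#'   in resampling loops.
#' @param multi_start Try several perturbed starting points (default
#'   `TRUE`); with `FALSE` only the supplied/OLS start is used.
#' @param fix_kappa Optionally fix `kappa` at a value (e.g. `0`, which
#'   makes the combined structure identical to the proportional one);
#'   a fixed `kappa` is not counted as a free parameter.
#' @return A `cd34_fit` with elements `coefficients`, `sigma`, `kappa`,
#'   `loglik`, `aic`, `n_params`, `std_errors`, `n_obs`, `converged`.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' fit <- fit_yield_model(cohort, covariates = "tumor_binary")
#' fit
#' @export
fit_yield_model <- function(data, covariates = character(),
                            error = c("combined", "homogeneous",
                                      "proportional"),
                            response_scale = c("linear", "log"),
                            start = NULL, se = TRUE, multi_start = TRUE,
                            fix_kappa = NULL) {
  error <- match.arg(error)
  response_scale <- match.arg(response_scale)
  if (response_scale == "log" && any(data$ap_cd34 <= 0))
    stop("log response requires strictly positive 'ap_cd34'")
  if (any(!is.finite(data$pb_cd34)) || any(!is.finite(data$ap_cd34)))
    stop("non-finite values in 'pb_cd34'/'ap_cd34'")

  mfr <- .make_model_frame(data, covariates, response_scale)
  X <- mfr$X
  y <- mfr$y
  n <- length(y)
  p <- ncol(X)
  n_par <- p + 1L + (error == "combined" && is.null(fix_kappa))
  if (n < n_par + 1L)
    stop("need at least ", n_par + 1L, " observations to fit ", n_par,
         " parameters")
  sds <- apply(X[, -1L, drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stop("singular design: constant column(s) ",
         paste(colnames(X)[-1L][sds == 0], collapse = ", "))

  starts <- .ml_starts(X, y, error, fix_kappa, start, multi_start)
  res <- .fit_ml_core(X, y, error, fix_kappa, starts)
  if (is.null(res))
    stop("optimization failed for all starting points")
  loglik <- res$loglik
  converged <- res$converged

  std_errors <- NULL
  if (se && converged) {
    H <- tryCatch(stats::optimHess(res$theta, res$machinery$nll,
                                   res$machinery$grad),
                  error = function(e) NULL)
    V <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(diag(V) > 0)) {
      se_t <- sqrt(diag(V))
      std_errors <- se_t[seq_len(p)]
      names(std_errors) <- colnames(X)
      std_errors <- c(std_errors, sigma = unname(res$sigma * se_t[p + 1L]))
      if (res$machinery$has_kappa)
        std_errors <- c(std_errors,
                        kappa = unname(.sigmoid(res$theta[p + 2L]) * se_t[p + 2L]))
    }
  }

  beta <- res$beta
  names(beta) <- colnames(X)
  structure(list(
    spec = list(covariates = covariates, error = error,
                response_scale = response_scale),
    coefficients = beta,
    sigma = res$sigma,
    kappa = if (error == "combined") res$kappa else NULL,
    terms = mfr$terms,
    xlevels = mfr$xlevels,
    loglik = loglik,
    aic = 2 * n_par - 2 * loglik,
    n_params = n_par,
    std_errors = std_errors,
    n_obs = n,
    converged = converged
  ), class = "cd34_fit")
}
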