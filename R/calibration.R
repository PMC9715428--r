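# Wilson score interval (no continuity correction); alternative to the
# default exact interval.
.wilson_ci <- function(k, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Observed vs model-predicted proportions reaching harvest thresholds
#'
#' For each threshold `T`, compares the observed fraction of patients with
#' `ap_cd34 >= T` (with an exact Clopper-Pearson binomial CI by default)
#' against the model-predicted proportion, defined as the cohort average
#' of each patient's exceedance probability at their own covariates and
#' PB-CD34+ count.  The model is judged well calibrated at `T` when the
#' predicted proportion falls inside the observed CI.
#'
#' @param model A converged `cd34_fit`.
#' @param data Cohort data frame the comparison is made on.
#' @param thresholds Vector of target doses (default `c(2, 5)`).
#' @param ci_level Level of the binomial CI (default 0.95).
#' @param ci_method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @return Data frame of class `cd34_calibration` with one row per
#'   threshold: `threshold`, `n`, `n_observed`, `observed_prop`,
#'   `observed_ci_low`, `observed_ci_high`, `predicted_prop`, `inside_ci`.
#' @export
calibration <- function(model, data, thresholds = c(2, 5),
                        ci_level = 0.95,
                        ci_method = c("clopper-pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  data <- as.data.frame(data)
  n <- nrow(data)
  if (n == 0) stop("empty cohort")
  rows <- lapply(thresholds, function(tv) {
    k <- sum(data$ap_cd34 >= tv)
    ci <- if (ci_method == "clopper-pearson")
      stats::binom.test(k, n, conf.level = ci_level)$conf.int
    else .wilson_ci(k, n, ci_level)
    pred <- mean(threshold_probability(model, data, tv))
    data.frame(threshold = tv, n = n, n_observed = k,
               observed_prop = k / n,
               observed_ci_low = ci[1], observed_ci_high = ci[2],
               predicted_prop = pred,
               inside_ci = pred >= ci[1] & pred <= ci[2])
  })
  structure(do.call(rbind, rows),
            ci_level = ci_level, ci_method = ci_method,
            class = c("cd34_calibration", "data.frame"))
}

#' Goodness-of-fit table
#'
#' Observed and predicted yields with raw and standardized residuals,
#' where the standardized residual divides by the model's heteroscedastic
#' residual SD at each patient's prediction.  The table backs the two
#' standard diagnostic panels: observed vs predicted (identity line) and
#' standardized residuals vs predicted.
#'
#' @param model A converged `cd34_fit`.
#' @param data Cohort data frame.
#' @return Data frame with columns `observed`, `predicted`, `residual`,
#'   `std_residual`.
#' @export
gof_table <- function(model, data) {
  stopifnot(inherits(model, "cd34_fit"))
  data <- as.data.frame(data)
  f <- predict_mean(model, data)
  y <- if (model$spec$response_scale == "log") log(data$ap_cd34)
       else data$ap_cd34
  s <- residual_sd(model, f)
  data.frame(observed = y, predicted = f, residual = y - f,
             std_residual = (y - f) / s)
}

#' Diagnostic plots: observed vs predicted, residuals vs predicted
#'
#' @param model A converged `cd34_fit`.
#' @param data Cohort data frame.
#' @return Invisibly, the [gof_table()].
#' @export
plot_gof <- function(model, data) {
  g <- gof_table(model, data)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(g$predicted, g$observed,
       xlab = "Predicted AP-CD34+ (10^6 cells/kg)",
       ylab = "Observed AP-CD34+ (10^6 cells/kg)",
       main = "Observed vs predicted")
  graphics::abline(0, 1, lty = 2)
  plot(g$predicted, g$std_residual,
       xlab = "Predicted AP-CD34+ (10^6 cells/kg)",
       ylab = "Standardized residual",
       main = "Residuals vs predicted")
  graphics::abline(h = 0, lty = 2)
  invisible(g)
}
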