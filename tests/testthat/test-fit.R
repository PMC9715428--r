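test_that("homogeneous ML fit equals ordinary least squares", {
  set.seed(101)
  d <- tiny_cohort(pb = runif(6, 5, 100), ap = 2 + 0.1 * runif(6, 5, 100))
  d$ap_cd34 <- d$ap_cd34 + rnorm(6, 0, 0.8)
  fit <- fit_yield_model(d, error = "homogeneous")
  ols <- lm(ap_cd34 ~ pb_cd34, data = d)
  expect_equal(unname(fit$coefficients),
               unname(coef(ols)), tolerance = 1e-6)
  # ML sigma is the sqrt(RSS/n) variant
  expect_equal(fit$sigma, sqrt(sum(resid(ols)^2) / 6), tolerance = 1e-5)
})

test_that("noiseless data recover the generating slope", {
  truth <- yield_model(covariate = "tumor_binary",
                       intercepts = c(other = 0.01, neuroblastoma = 3.01),
                       slope = 0.13, sigma = 1e-6, kappa = 0,
                       error = "combined")
  co <- simulate_cohort(cohort_config(n = 45, truth = truth, seed = 9))
  fit <- fit_yield_model(co, covariates = "tumor_binary",
                         error = "combined")
  expect_lt(abs(fit$coefficients[["pb_cd34"]] - 0.13), 1e-3)
})

test_that("the AIC identity holds for every structure and covariate set", {
  co <- simulate_cohort(cohort_config(n = 80, seed = 13))
  for (err in c("homogeneous", "proportional", "combined"))
    for (cv in list(character(), "tumor_binary", "age_years")) {
      fit <- fit_yield_model(co, covariates = cv, error = err, se = FALSE)
      expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik,
                   tolerance = 1e-9)
      expect_identical(fit$n_params,
                       length(fit$coefficients) + 1L + (err == "combined"))
    }
})

test_that("combined fit with kappa fixed at 0 equals the proportional fit", {
  co <- simulate_cohort(cohort_config(n = 100, seed = 17))
  f_comb0 <- fit_yield_model(co, error = "combined", fix_kappa = 0,
                             se = FALSE)
  f_prop <- fit_yield_model(co, error = "proportional", se = FALSE)
  expect_equal(f_comb0$loglik, f_prop$loglik, tolerance = 1e-6)
  expect_equal(unname(f_comb0$coefficients), unname(f_prop$coefficients),
               tolerance = 1e-4)
  expect_identical(f_comb0$n_params, f_prop$n_params)
})

test_that("the optimum dominates a surrounding parameter grid", {
  co <- simulate_cohort(cohort_config(n = 45, seed = 23))
  fit <- fit_yield_model(co, error = "combined", se = FALSE)
  at_opt <- yield_nll(list(coefficients = fit$coefficients,
                           sigma = fit$sigma, kappa = fit$kappa),
                      co, error = "combined")
  for (da in c(-0.3, 0, 0.3)) for (db in c(-0.02, 0, 0.02))
    for (ds in c(0.85, 1, 1.15)) {
      if (da == 0 && db == 0 && ds == 1) next
      p <- list(coefficients = fit$coefficients +
                  c(da, db, rep(0, length(fit$coefficients) - 2)),
                sigma = fit$sigma * ds, kappa = fit$kappa)
      expect_gte(yield_nll(p, co, error = "combined"), at_opt - 1e-8)
    }
})

test_that("standard errors are finite and scale like 1/sqrt(n)", {
  co_small <- final_truth_cohort(45, 29)
  co_big <- final_truth_cohort(720, 31)
  f1 <- fit_yield_model(co_small, covariates = "tumor_binary")
  f2 <- fit_yield_model(co_big, covariates = "tumor_binary")
  expect_true(all(is.finite(f1$std_errors)))
  expect_lt(f2$std_errors[["pb_cd34"]], f1$std_errors[["pb_cd34"]])
  # slope SE at n = 45 is the same order as the published 0.01
  expect_gt(f1$std_errors[["pb_cd34"]], 0.002)
  expect_lt(f1$std_errors[["pb_cd34"]], 0.05)
})

test_that("estimation bias shrinks as the cohort grows", {
  reps <- c(`45` = 120, `200` = 60, `1000` = 30)
  bias_slope <- bias_sigma <- numeric(0)
  for (n in c(45, 200, 1000)) {
    sl <- sg <- numeric(reps[[as.character(n)]])
    for (i in seq_along(sl)) {
      co <- final_truth_cohort(n, 1000 * n + i)
      ft <- tryCatch(fit_yield_model(co, covariates = "tumor_binary",
                                     se = FALSE), error = function(e) NULL)
      sl[i] <- if (is.null(ft)) NA else ft$coefficients[["pb_cd34"]]
      sg[i] <- if (is.null(ft)) NA else ft$sigma
    }
    bias_slope <- c(bias_slope, abs(mean(sl, na.rm = TRUE) - 0.13))
    bias_sigma <- c(bias_sigma, abs(mean(sg, na.rm = TRUE) - 0.54))
  }
  expect_true(all(diff(bias_slope) < 0))
  expect_true(all(diff(bias_sigma) < 0))
})

test_that("degenerate designs and tiny samples are rejected", {
  co <- simulate_cohort(cohort_config(n = 45, seed = 37))
  co$arm <- factor("plerixafor+G-CSF",
                   levels = c("plerixafor+G-CSF", "G-CSF alone"))
  expect_error(fit_yield_model(co, covariates = "arm"), "singular|constant")
  expect_error(fit_yield_model(co[1:3, ], error = "combined"),
               "at least")
  co_neg <- co
  co_neg$ap_cd34[4] <- 0
  expect_error(fit_yield_model(co_neg, response_scale = "log"), "positive")
})
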