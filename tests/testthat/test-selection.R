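test_that("combined error structure is selected when it generated the data (large n)", {
  truth <- yield_model(intercept = 1.63, slope = 0.12, sigma = 0.49,
                       kappa = 1.76, error = "combined")
  co <- simulate_cohort(cohort_config(n = 500, truth = truth, seed = 42,
                                      negative_yields = "keep"))
  sel <- select_error_structure(co)
  expect_identical(sel$chosen, "combined")
  expect_true(all(sel$candidates$converged))
})

test_that("homogeneous truth is recognized at large n in most replicates", {
  truth <- yield_model(intercept = 1.63, slope = 0.12, sigma = 2,
                       error = "homogeneous")
  wins <- 0
  for (i in 1:100) {
    co <- simulate_cohort(cohort_config(n = 1000, truth = truth,
                                        seed = 900 + i,
                                        negative_yields = "keep"))
    s <- tryCatch(suppressWarnings(select_error_structure(co))$chosen,
                  error = function(e) NA_character_)
    wins <- wins + identical(s, "homogeneous")
  }
  expect_gte(wins, 90)
})

test_that("AIC ties break deterministically to fewer parameters, then order", {
  pick <- cd34yield:::.select_min
  expect_identical(pick(c(10, 10 + 1e-12), c(4, 3)), 2L)
  expect_identical(pick(c(10, 10 + 1e-12), c(3, 4)), 1L)
  expect_identical(pick(c(10, 10), c(3, 3)), 1L)
  expect_identical(pick(c(10, 8), c(3, 4)), 2L)
})

test_that("tumor type beats age on AIC in most replicates under the confounded truth", {
  wins <- 0
  for (i in 1:100) {
    co <- simulate_cohort(cohort_config(n = 45, seed = 100 + i))
    s <- tryCatch(suppressWarnings(select_covariates(co,
                                                     error = "combined")),
                  error = function(e) NULL)
    if (!is.null(s) && isTRUE(s$tumor_vs_age$tumor_preferred))
      wins <- wins + 1
  }
  expect_gt(wins, 50)
})

test_that("with no covariate effects the empty model is the plurality choice", {
  truth <- yield_model(intercept = 1.63, slope = 0.12, sigma = 0.49,
                       kappa = 1.76, error = "combined")
  picks <- character(100)
  for (i in 1:100) {
    co <- simulate_cohort(cohort_config(n = 45, truth = truth,
                                        seed = 300 + i))
    s <- tryCatch(suppressWarnings(select_covariates(co,
                                                     error = "combined")),
                  error = function(e) NULL)
    picks[i] <- if (is.null(s)) NA_character_
                else if (!length(s$chosen)) "(none)" else s$chosen
  }
  tab <- sort(table(picks), decreasing = TRUE)
  expect_identical(names(tab)[1], "(none)")
})

test_that("constant candidates are excluded; all-constant errors", {
  co <- simulate_cohort(cohort_config(n = 45, seed = 57))
  co$arm <- factor("plerixafor+G-CSF",
                   levels = c("plerixafor+G-CSF", "G-CSF alone"))
  expect_warning(s <- select_covariates(co, error = "combined",
                                        candidates = c("arm", "sex")),
                 "constant")
  expect_false("arm" %in% s$candidates$covariate)
  expect_error(suppressWarnings(
    select_covariates(co, error = "combined", candidates = "arm")),
    "constant")
})

test_that("selection is invariant to row order", {
  co <- simulate_cohort(cohort_config(n = 45, seed = 63))
  perm <- co[sample(nrow(co)), ]
  s1 <- select_error_structure(co)
  s2 <- select_error_structure(perm)
  expect_identical(s1$chosen, s2$chosen)
  expect_equal(s1$candidates$aic, s2$candidates$aic, tolerance = 1e-6)
})

test_that("linear truth wins the linear-vs-log comparison and vice versa", {
  co <- simulate_cohort(cohort_config(n = 500, seed = 71))
  cmp <- compare_linear_log(co)
  expect_identical(cmp$chosen, "linear")
  expect_lt(cmp$candidates$sum_abs_error[cmp$candidates$scale == "linear"],
            cmp$candidates$sum_abs_error[cmp$candidates$scale == "log"])

  set.seed(73)
  pb <- rlnorm(300, log(40), 0.8)
  ap <- exp(-1.2 + 0.9 * log(pb) + rnorm(300, 0, 0.05))
  cmp2 <- compare_linear_log(tiny_cohort(pb, ap))
  expect_identical(cmp2$chosen, "log")
})

test_that("identical predictions tie-break to the linear scale", {
  # constant response: both scales predict the constant exactly
  d <- tiny_cohort(pb = c(10, 20, 40, 80, 160), ap = rep(5, 5))
  cmp <- compare_linear_log(d)
  expect_identical(cmp$chosen, "linear")
  expect_equal(diff(cmp$candidates$sum_abs_error), 0, tolerance = 1e-6)
})

test_that("rows unusable by the log model are excluded from both fits", {
  co <- simulate_cohort(cohort_config(n = 100, seed = 79))
  co$ap_cd34[3] <- 0
  expect_message(cmp <- compare_linear_log(co), "excluding 1")
  expect_identical(cmp$n_excluded, 1L)
})
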