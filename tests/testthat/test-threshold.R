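test_that("exceedance probability matches the published worked points", {
  bm <- base_model()
  # prediction equal to the threshold gives probability one half
  pb_mid <- (2 - 1.63) / 0.12
  expect_equal(unname(threshold_probability(bm, pb_mid, 2)), 0.5,
               tolerance = 1e-12)
  expect_equal(unname(threshold_probability(bm, 57.01, 2)), 0.90,
               tolerance = 0.01 / 0.90)
  fm <- final_model()
  expect_equal(unname(threshold_probability(
    fm, data.frame(pb_cd34 = 103.20, tumor_binary = "neuroblastoma"), 5)),
    0.90, tolerance = 0.01 / 0.90)
})

test_that("exceedance probability is monotone in pb for positive slopes", {
  # monotonicity holds where predictions are nonnegative (the clinical
  # regime); with a negative intercept the |f| in the SD breaks it below
  # the zero crossing
  set.seed(91)
  for (i in 1:20) {
    m <- yield_model(intercept = runif(1, 0, 4), slope = runif(1, 0.02, 0.3),
                     sigma = runif(1, 0.1, 0.7), kappa = runif(1, 0, 3),
                     error = "combined")
    pb <- seq(0, 400, length.out = 60)
    p <- threshold_probability(m, pb, threshold = sample(c(2, 5), 1))
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("closed-form inversion agrees with the bisection root", {
  set.seed(97)
  for (i in 1:20) {
    err <- sample(c("homogeneous", "proportional", "combined"), 1)
    m <- yield_model(intercept = runif(1, -1, 4), slope = runif(1, 0.05, 0.3),
                     sigma = runif(1, 0.1, 0.6),
                     kappa = if (err == "combined") runif(1, 0, 3),
                     error = err)
    gam <- runif(1, 0.55, 0.95)
    tv <- sample(c(2, 5), 1)
    cf <- invert_threshold(m, tv, gam)
    nm <- invert_threshold(m, tv, gam, method = "numeric")
    if (!attr(cf, "clamped"))
      expect_lt(abs(as.numeric(cf) - as.numeric(nm)),
                1e-8 * max(1, as.numeric(cf)))
  }
})

test_that("median inversion is independent of the variance parameters", {
  for (sg in c(0.1, 0.3, 0.6)) {
    m <- yield_model(intercept = 1.63, slope = 0.12, sigma = sg,
                     kappa = 1.76, error = "combined")
    pb <- invert_threshold(m, 2, 0.5)
    expect_equal(unname(predict_mean(m, as.numeric(pb))), 2,
                 tolerance = 1e-10)
  }
})

test_that("a higher harvest target never needs fewer circulating cells", {
  set.seed(103)
  for (i in 1:15) {
    m <- yield_model(intercept = runif(1, -1, 3), slope = runif(1, 0.05, 0.3),
                     sigma = runif(1, 0.1, 0.6), kappa = runif(1, 0, 2),
                     error = "combined")
    expect_gte(as.numeric(invert_threshold(m, 5, 0.9)),
               as.numeric(invert_threshold(m, 2, 0.9)))
  }
})

test_that("no finite inversion exists when z*sigma >= 1", {
  m <- yield_model(intercept = 1, slope = 0.1, sigma = 0.9, kappa = 0.5,
                   error = "combined")
  expect_error(invert_threshold(m, 2, 0.9), "no finite")
  m2 <- yield_model(intercept = 5, slope = -0.1, sigma = 0.3, kappa = 0.5,
                    error = "combined")
  expect_error(invert_threshold(m2, 2, 0.9), "positive slope")
})

test_that("intercepts low enough to guarantee the dose clamp pb* at zero", {
  m <- yield_model(intercept = 30, slope = 0.1, sigma = 0.2, kappa = 0,
                   error = "combined")
  pb <- invert_threshold(m, 2, 0.9)
  expect_identical(as.numeric(pb), 0)
  expect_true(attr(pb, "clamped"))
})

test_that("bootstrap CIs are deterministic given the seed and degenerate at n_boot = 1", {
  co <- simulate_cohort(cohort_config(n = 45, seed = 107))
  nd <- data.frame(tumor_binary = "neuroblastoma")
  b1 <- bootstrap_inversion_ci(co, covariates = "tumor_binary",
                               threshold = 2, newdata = nd,
                               n_boot = 60, seed = 5)
  b2 <- bootstrap_inversion_ci(co, covariates = "tumor_binary",
                               threshold = 2, newdata = nd,
                               n_boot = 60, seed = 5)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_identical(b1$boot_values, b2$boot_values)

  b3 <- suppressWarnings(bootstrap_inversion_ci(
    co, covariates = "tumor_binary", threshold = 2, newdata = nd,
    n_boot = 1, seed = 6))
  expect_identical(b3$ci_low, b3$ci_high)
  expect_identical(b3$ci_low, b3$boot_values[1])
})

test_that("the two final-model tumor groups differ by a fixed pb* offset", {
  fm <- final_model()
  off <- (3.01 - 0.01) / 0.13
  for (tv in c(2, 5)) for (gam in c(0.6, 0.75, 0.9)) {
    p_nb <- invert_threshold(fm, tv, gam,
                             data.frame(tumor_binary = "neuroblastoma"))
    p_ot <- invert_threshold(fm, tv, gam,
                             data.frame(tumor_binary = "other"))
    expect_equal(attr(p_ot, "pb_raw") - attr(p_nb, "pb_raw"), off,
                 tolerance = 1e-9)
  }
  # reported values floor at zero: a low enough target probability needs
  # no circulating minimum for the neuroblastoma group
  p0 <- invert_threshold(fm, 2, 0.6,
                         data.frame(tumor_binary = "neuroblastoma"))
  expect_identical(as.numeric(p0), 0)
  expect_true(attr(p0, "clamped"))
  expect_lt(attr(p0, "pb_raw"), 0)
})

test_that("probability_curve tabulates both thresholds over the grid", {
  fm <- final_model()
  pc <- probability_curve(fm, seq(0, 200, 25),
                          newdata = data.frame(tumor_binary = "other"))
  expect_identical(nrow(pc), 18L)
  expect_true(all(pc$probability >= 0 & pc$probability <= 1))
  sub5 <- pc[pc$threshold == 5, ]
  expect_true(all(diff(sub5$probability) >= 0))
})
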