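test_that("direct extrapolation matches the analytic normal interval", {
  e0 <- direct_extrapolation(1000, 0.5, 0, seed = 1)
  expect_equal(c(e0$ci_lower, e0$point, e0$ci_upper), c(500, 500, 500))
  e <- direct_extrapolation(1000, 0.5, 0.1, n_sims = 1e6, seed = 2)
  expect_equal(e$point, 500)
  lo <- 1000 * (0.5 - qnorm(0.975) * 0.1)
  hi <- 1000 * (0.5 + qnorm(0.975) * 0.1)
  expect_lt(abs(e$ci_lower - lo) / lo, 0.01)
  expect_lt(abs(e$ci_upper - hi) / hi, 0.01)
  expect_true(e$ci_lower <= e$point && e$point <= e$ci_upper)
  # negative simulated densities floor the lower bound at zero
  ef <- direct_extrapolation(1000, 0.1, 0.5, seed = 3)
  expect_equal(ef$ci_lower, 0)
  expect_true(ef$lower_floored)
  expect_error(direct_extrapolation(1000, 0.5, -0.1), "sd_density")
  expect_error(direct_extrapolation(1000, 0.5, 0.1, n_sims = 10), "n_sims")
})

test_that("the SE-of-mean variant narrows the simulation interval", {
  e_sd <- direct_extrapolation(1000, 0.5, 0.1, n_sims = 1e5, seed = 4)
  e_se <- direct_extrapolation(1000, 0.5, 0.1, n_sims = 1e5, seed = 4,
                               use_se_of_mean = TRUE, n_polygons = 25L)
  expect_lt(e_se$ci_upper - e_se$ci_lower,
            (e_sd$ci_upper - e_sd$ci_lower) / 4)
})

test_that("linear fit solves the normal equations", {
  a <- c(10, 20, 30, 40)
  f <- fit_linear(0.8 * a, a)
  expect_equal(f$slope, 0.8, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$sigma2, 0, tolerance = 1e-20)
  f2 <- fit_linear(c(1, 3, 5), c(1, 2, 3))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, -1, tolerance = 1e-12)
  # permutation invariance
  f3 <- fit_linear(c(5, 1, 3), c(3, 1, 2))
  expect_equal(f3$slope, f2$slope)
  expect_equal(f3$intercept, f2$intercept)
  expect_error(fit_linear(c(1, 2), c(1, 2)), "3 polygons")
  expect_error(fit_linear(c(1, 2, 3), c(2, 2, 2)), "equal")
})

test_that("linear prediction uses the SE of the mean response", {
  a <- c(10, 20, 30, 40, 50)
  set.seed(8)
  c_ <- 0.7 * a + rnorm(5, 0, 2)
  f <- fit_linear(c_, a)
  # at the training mean the prediction SE reduces to sqrt(sigma2/n)
  e <- predict_linear(f, mean(a), z = 1.96)
  half <- (e$ci_upper - e$ci_lower) / 2
  expect_equal(half, 1.96 * sqrt(f$sigma2 / 5), tolerance = 1e-9)
  # an exact-line fit has zero interval width
  fe <- fit_linear(0.8 * a, a)
  ee <- predict_linear(fe, 30)
  expect_equal(ee$ci_upper - ee$ci_lower, 0, tolerance = 1e-9)
  # predicting far beyond the polygon areas signals extrapolation
  expect_warning(predict_linear(f, 5000), class = "hauloutr_extrapolation")
})

test_that("NB GLM reproduces offset algebra and degenerate fits", {
  fx <- make_nb_fixture(n = 400, seed = 3)
  f1 <- fit_nb_glm(fx$count, fx$area, fx$terrain)
  f2 <- fit_nb_glm(fx$count, fx$area * 2, fx$terrain)
  expect_equal(f2$intercept, f1$intercept - log(2), tolerance = 1e-6)
  expect_equal(f2$sandy, f1$sandy, tolerance = 1e-6)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-4)
  # all counts equal on one terrain: intercept = log(count/area)
  f3 <- suppressWarnings(
    fit_nb_glm(rep(50, 20), rep(100, 20), rep("rocky_type", 20)))
  expect_equal(f3$intercept, log(50 / 100), tolerance = 1e-6)
  expect_equal(deviance_explained(f3), 0, tolerance = 1e-6)
  expect_true(is.na(f3$sandy))
  expect_warning(fit_nb_glm(rep(c(49, 51), 10), rep(100, 20),
                            rep("rocky_type", 20)), "single terrain")
  expect_error(fit_nb_glm(c(1, 2), c(1, 1), c("rocky_type", "gravel")),
               "terrain")
})

test_that("NB GLM agrees with a direct joint-ML refit", {
  fx <- make_nb_fixture(n = 1000, seed = 11)
  fit <- fit_nb_glm(fx$count, fx$area, fx$terrain)
  oracle <- nb_joint_ml(fx$count, fx$area, fx$terrain)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-5)
  expect_equal(fit$sandy, oracle$sandy, tolerance = 1e-5)
  expect_equal(fit$theta, oracle$theta, tolerance = 1e-3)
  expect_equal(fit$residual_deviance, oracle$residual_deviance,
               tolerance = 1e-6)
  expect_equal(fit$null_deviance, oracle$null_deviance, tolerance = 1e-6)
  expect_equal(deviance_explained(fit), oracle$deviance_explained,
               tolerance = 1e-6)
  expect_gt(deviance_explained(fit), 0)
})

test_that("NB fit on Poisson-generated counts drives theta large", {
  set.seed(13)
  terrain <- rep(c("rocky_type", "sandy_type"), each = 300)
  mu <- exp(-0.434 + 0.305 * (terrain == "sandy_type")) * 387.3
  counts <- rpois(600, mu)
  fit <- suppressWarnings(fit_nb_glm(counts, rep(387.3, 600), terrain))
  expect_gt(fit$theta, 50)
})

test_that("NB prediction applies the delta method on the log scale", {
  fit <- nb_count_fit(-0.434, 0.305, theta = 8.979)
  expect_equal(predict_nb(fit, 1, "rocky_type")$point, exp(-0.434))
  expect_equal(predict_nb(fit, 1, "sandy_type")$point, exp(-0.434 + 0.305))
  # zero coefficient covariance collapses the interval
  e <- predict_nb(fit, 5000, "rocky_type")
  expect_equal(e$ci_lower, e$point)
  expect_equal(e$ci_upper, e$point)
  # with a real covariance the interval is asymmetric and positive
  V <- matrix(c(4e-4, -2e-4, -2e-4, 4e-4), 2)
  fit2 <- nb_count_fit(-0.434, 0.305, vcov = V, theta = 8.979)
  e2 <- predict_nb(fit2, 5000, "sandy_type", k = 2)
  var_eta <- drop(t(c(1, 1)) %*% V %*% c(1, 1))
  sd_log <- sqrt(log(1 + var_eta))
  expect_equal(e2$ci_lower, e2$point * exp(-2 * sd_log))
  expect_equal(e2$ci_upper, e2$point * exp(+2 * sd_log))
  expect_gt(e2$ci_upper - e2$point, e2$point - e2$ci_lower)
  expect_gt(e2$ci_lower, 0)
  # monotone in area; sandy above rocky at equal area for positive sandy
  a_seq <- c(100, 1000, 10000)
  pts <- vapply(a_seq, function(a) predict_nb(fit, a, "rocky_type")$point, 0)
  expect_true(all(diff(pts) > 0))
  expect_gt(predict_nb(fit, 1000, "sandy_type")$point,
            predict_nb(fit, 1000, "rocky_type")$point)
  expect_error(predict_nb(suppressWarnings(
    fit_nb_glm(rep(c(49, 51), 10), rep(100, 20), rep("rocky_type", 20))),
    100, "sandy_type"), "not in the fitted model")
})

test_that("deviance explained handles its boundary cases", {
  f <- nb_count_fit(-0.4, 0.3, theta = 9,
                    null_deviance = 100, residual_deviance = 100)
  expect_equal(deviance_explained(f), 0)
  f2 <- nb_count_fit(-0.4, 0.3, theta = 9,
                     null_deviance = 100, residual_deviance = 0)
  expect_equal(deviance_explained(f2), 100)
  f3 <- nb_count_fit(-0.4, 0.3, theta = 9, null_deviance = 0,
                     residual_deviance = 0)
  expect_error(deviance_explained(f3), "null deviance")
})
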