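test_that("beta fit holds the mean and recovers the reported interval", {
  fit <- fit_beta_from_mean_ci(0.70, 0.372, 0.938)
  expect_equal(fit[["shape1"]] / (fit[["shape1"]] + fit[["shape2"]]), 0.70,
               tolerance = 1e-9)
  ## independent numeric-CDF oracle: bisect pbeta, never qbeta
  q025 <- cdf_quantile(function(x) stats::pbeta(x, fit[1], fit[2]),
                       0.025, 0, 1)
  q975 <- cdf_quantile(function(x) stats::pbeta(x, fit[1], fit[2]),
                       0.975, 0, 1)
  expect_lt(abs(q025 - 0.372), 0.02)
  expect_lt(abs(q975 - 0.938), 0.02)
})

test_that("symmetric beta input yields equal shapes", {
  fit <- fit_beta_from_mean_ci(0.5, 0.2, 0.8)
  expect_equal(unname(fit[1]), unname(fit[2]), tolerance = 1e-6)
})

test_that("gamma fit holds the mean and recovers the interval within 5%", {
  for (case in list(c(106, 29, 232), c(5, 1.3, 11))) {
    fit <- fit_gamma_from_mean_ci(case[1], case[2], case[3])
    expect_equal(unname(fit[["shape"]] * fit[["scale"]]), case[1],
                 tolerance = 1e-9)
    cdf <- function(x) stats::pgamma(x, shape = fit[1], scale = fit[2])
    q025 <- cdf_quantile(cdf, 0.025, 1e-9, case[1] * 50)
    q975 <- cdf_quantile(cdf, 0.975, 1e-9, case[1] * 50)
    expect_lt(abs(q025 - case[2]) / case[2], 0.05)
    expect_lt(abs(q975 - case[3]) / case[3], 0.05)
  }
})

test_that("infeasible inputs are rejected with the parameter named", {
  expect_error(fit_beta_from_mean_ci(0.3, 0.4, 0.9, name = "p_eligible"),
               "p_eligible")
  expect_error(fit_gamma_from_mean_ci(5, -1, 11, name = "ha_life"),
               "ha_life")
  expect_error(parameter_spec("p", 0.5, 0.6, 0.9, family = "beta"),
               "outside its CI")
})

test_that("every reported parameter's fitted prior reproduces its mean", {
  ps <- fit_parameter_set(default_parameter_set())
  for (i in seq_len(nrow(ps))) {
    fitted_mean <- switch(ps$family[i],
      beta = ps$par1[i] / (ps$par1[i] + ps$par2[i]),
      gamma = ps$par1[i] * ps$par2[i],
      fixed = ps$mean[i])
    expect_equal(fitted_mean, ps$mean[i], tolerance = 1e-6,
                 label = paste("fitted mean of", ps$name[i]))
  }
})

test_that("fixed parameters are constant and draws are deterministic", {
  ps <- test_model()$params
  d1 <- sample_draw(ps, draw_id = 7L, seed = 123L)
  d2 <- sample_draw(ps, draw_id = 7L, seed = 123L)
  expect_identical(unclass(d1), unclass(d2))
  expect_identical(d1$average_age, 52.8)
  expect_identical(d1$discount_rate, 0.035)
  d3 <- sample_draw(ps, draw_id = 8L, seed = 123L)
  expect_false(identical(d1$prop_eligible, d3$prop_eligible))
  ## draw k does not depend on whether earlier draws were generated
  for (k in 1:6) invisible(sample_draw(ps, k, seed = 123L))
  expect_identical(unclass(sample_draw(ps, 7L, seed = 123L)), unclass(d1))
})

test_that("draws respect their supports and converge to the fitted means", {
  ps <- test_model()$params
  n <- 10000L
  elig <- numeric(n)
  ok_bounds <- TRUE
  for (k in seq_len(n)) {
    d <- sample_draw(ps, k, seed = 5L)
    elig[k] <- d$prop_eligible
    vals <- unlist(d, use.names = TRUE)
    beta_vals <- vals[ps$name[ps$family == "beta"]]
    gamma_vals <- vals[ps$name[ps$family == "gamma"]]
    if (any(beta_vals < 0 | beta_vals > 1) || any(gamma_vals <= 0))
      ok_bounds <- FALSE
  }
  expect_true(ok_bounds)
  ## eligibility beta: MC mean within 3 standard errors of 0.70
  se <- stats::sd(elig) / sqrt(n)
  expect_lt(abs(mean(elig) - 0.70), 3 * se)
})

test_that("unfitted sets refuse to sample and parameter CSV round-trips", {
  ps <- default_parameter_set()
  expect_error(sample_draw(ps, 1L, 1L), "unfitted")
  path <- withr::local_tempfile(fileext = ".csv")
  write_parameter_set(ps, path)
  ps2 <- read_parameter_set(path)
  expect_identical(as.data.frame(ps)[c("name", "mean", "ci_low", "ci_high",
                                       "family", "units")],
                   as.data.frame(ps2)[c("name", "mean", "ci_low", "ci_high",
                                        "family", "units")])
})
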