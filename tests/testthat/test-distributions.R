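test_that("distribution specs validate their parameters", {
  expect_error(dist_spec("pareto", rate = 1), class = "vaxflow_config_error")
  expect_error(
    dist_spec("exponential", rate = 0),
    class = "vaxflow_config_error"
  )
  expect_error(
    dist_spec("exponential", rate = -2),
    class = "vaxflow_config_error"
  )
  expect_error(
    dist_spec("normal", mean = 5, sd = -1),
    class = "vaxflow_config_error"
  )
  expect_error(dist_spec("gamma", shape = 2), class = "vaxflow_config_error")
  expect_error(
    dist_spec("exponential", shift = -1, rate = 1),
    class = "vaxflow_config_error"
  )
  expect_error(
    dist_spec("exponential", rate = 1, scale = 2),
    class = "vaxflow_config_error"
  )
})

test_that("shifted-exponential quantiles reproduce the published percentile rows", {
  # preparation: 1 + exp(rate 3) -> 1.0 1.1 1.2 1.5 2.0
  prep <- dist_spec("exponential", shift = 1, rate = 3)
  expect_equal(
    round(quantile(prep, table1_percentiles), 1),
    c(1.0, 1.1, 1.2, 1.5, 2.0)
  )
  # registration: 3 + exp(rate 0.7) -> 3.1 3.4 4.0 5.0 7.3
  reg <- dist_spec("exponential", shift = 3, rate = 0.7)
  expect_equal(
    round(quantile(reg, table1_percentiles), 1),
    c(3.1, 3.4, 4.0, 5.0, 7.3)
  )
  # the rate parameterisation: median of 3 + exp(0.7) is 3 + ln2/0.7
  expect_equal(quantile(reg, 0.5), 3 + log(2) / 0.7, tolerance = 1e-12)
  # 95th percentile of 1 + exp(3) is 1.9986
  expect_equal(quantile(prep, 0.95), 1 + log(20) / 3, tolerance = 1e-12)
})

test_that("quantiles are non-decreasing, respect the shift, and reject bad p", {
  specs <- list(
    dist_spec("exponential", shift = 2, rate = 1),
    dist_spec("normal", mean = 20, sd = 0.5),
    dist_spec("lognormal", shift = 1, meanlog = 0.5, sdlog = 0.4),
    dist_spec("gamma", shift = 0.5, shape = 2, rate = 1),
    dist_spec("weibull", shift = 3, shape = 1.5, scale = 2),
    dist_spec("uniform", min = 0.5, max = 2)
  )
  p <- seq(0.01, 0.99, by = 0.01)
  for (spec in specs) {
    q <- quantile(spec, p)
    expect_true(all(diff(q) >= 0), info = format(spec))
    expect_true(all(q >= spec$shift), info = format(spec))
    # p -> 0+ approaches the shift for shifted families with base >= 0
    if (spec$family %in% c("exponential", "lognormal", "gamma", "weibull")) {
      expect_lt(quantile(spec, 1e-300) - spec$shift, 1e-6)
    }
  }
  expect_error(quantile(specs[[1]], 0), class = "vaxflow_domain_error")
  expect_error(quantile(specs[[1]], 1), class = "vaxflow_domain_error")
  expect_error(quantile(specs[[1]], -0.2), class = "vaxflow_domain_error")
})

test_that("gamma quantile matches numeric inversion of the CDF", {
  spec <- dist_spec("gamma", shape = 2, rate = 1)
  # independent oracle: bisection on the regularised incomplete gamma CDF
  invert <- function(p) {
    lo <- 0
    hi <- 100
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (stats::pgamma(mid, shape = 2, rate = 1) < p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (p in c(0.05, 0.5, 0.95)) {
    expect_equal(quantile(spec, p), invert(p), tolerance = 1e-6)
  }
})

test_that("sampling matches the stated moments and honours the shift", {
  set.seed(401)
  n <- 2e5
  # median of 3 + exp(0.7) ~ 3.99 (printed 4.0)
  x <- sample_service_times(dist_spec("exponential", shift = 3, rate = 0.7), n)
  expect_equal(median(x), 3.99, tolerance = 0.01)
  # mean of 2 + exp(1) = 3 within 3 standard errors (sd = 1)
  y <- sample_service_times(dist_spec("exponential", shift = 2, rate = 1), n)
  expect_lt(abs(mean(y) - 3), 3 / sqrt(n))
  expect_true(all(y >= 2))
  # normal family: negative draws are rejected, never returned
  z <- sample_service_times(dist_spec("normal", mean = 1, sd = 2), 1e4)
  expect_true(all(z >= 0))
  # empty input
  expect_identical(
    length(sample_service_times(dist_spec("exponential", rate = 1), 0)), 0L
  )
})

test_that("empirical CDFs of all five service families agree with quantile()", {
  specs <- list(
    dist_spec("exponential", shift = 3, rate = 0.7),
    dist_spec("normal", mean = 20, sd = 0.5),
    dist_spec("lognormal", shift = 2, meanlog = 1, sdlog = 0.5),
    dist_spec("gamma", shift = 1, shape = 2, rate = 1.5),
    dist_spec("weibull", shift = 0.5, shape = 1.3, scale = 3)
  )
  set.seed(402)
  n <- 1e5
  for (spec in specs) {
    draws <- sample_service_times(spec, n)
    for (p in table1_percentiles) {
      # Kolmogorov-Smirnov-scale tolerance at n = 1e5
      expect_lt(
        abs(mean(draws <= quantile(spec, p)) - p), 0.015
      )
    }
  }
})

test_that("identical seeds give identical draw sequences", {
  spec <- dist_spec("weibull", shift = 1, shape = 2, scale = 3)
  set.seed(77)
  a <- sample_service_times(spec, 1000)
  set.seed(77)
  b <- sample_service_times(spec, 1000)
  expect_identical(a, b)
  mix <- obs_mixture()
  set.seed(78)
  m1 <- sample_observation(mix, 1000)
  set.seed(78)
  m2 <- sample_observation(mix, 1000)
  expect_identical(m1, m2)
})

test_that("observation mixture pairs durations with adverse flags", {
  expect_error(obs_mixture(adverse_prob = 1.5), class = "vaxflow_config_error")

  # degenerate mixture: no adverse reactions
  set.seed(403)
  none <- sample_observation(obs_mixture(adverse_prob = 0), 5000)
  expect_false(any(none$adverse))
  expect_equal(mean(none$duration), 20, tolerance = 0.05)
  expect_true(all(abs(none$duration - 20) < 5 * 0.5))

  # defaults: 2% adverse, mixture mean 0.98*20 + 0.02*30 = 20.2
  set.seed(404)
  n <- 2e5
  obs <- sample_observation(obs_mixture(), n)
  expect_lt(
    abs(sum(obs$adverse) - n * 0.02), 3 * sqrt(n * 0.02 * 0.98)
  )
  expect_equal(mean(obs$duration), 20.2, tolerance = 0.02)
  # durations come from the component matching the flag
  expect_true(all(obs$duration[obs$adverse] >= 20))
  expect_true(all(abs(obs$duration[!obs$adverse] - 20) < 5 * 0.5))
})
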