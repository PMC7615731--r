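test_that("moment matching reproduces elicited integer-rounded priors", {
  cases <- list(
    list(mean = 0.18, sd = 0.02, alpha = 66, beta = 302),
    list(mean = 0.28, sd = 0.02, alpha = 141, beta = 362)
  )
  for (cs in cases) {
    p <- beta_from_moments(cs$mean, cs$sd, round_params = TRUE)
    expect_equal(p$alpha, cs$alpha)
    expect_equal(p$beta, cs$beta)
  }
  # uniform's own moments round-trip without rounding
  u <- beta_from_moments(0.5, sqrt(1 / 12))
  expect_equal(u$alpha, 1, tolerance = 1e-10)
  expect_equal(u$beta, 1, tolerance = 1e-10)
})

test_that("moment matching round-trips for arbitrary valid priors", {
  shapes <- list(c(66, 302), c(141, 362), c(11, 48), c(1, 1), c(0.5, 7),
                 c(6600, 30200))
  for (s in shapes) {
    m <- beta_moments(beta_params(s[1], s[2]))
    back <- beta_from_moments(m[["mean"]], m[["sd"]])
    expect_equal(back$alpha, s[1], tolerance = 1e-8)
    expect_equal(back$beta, s[2], tolerance = 1e-8)
  }
})

test_that("infeasible moments are rejected", {
  expect_error(beta_from_moments(0.18, 0.5),
               class = "bayesnid_error_invalid_moments")
  expect_error(beta_from_moments(0.18, 0.4),
               class = "bayesnid_error_invalid_moments")
  expect_error(beta_params(0, 1), class = "bayesnid_error_domain")
})

test_that("moments and effective sample size match closed forms", {
  m <- beta_moments(beta_params(66, 302))
  expect_equal(m[["mean"]], 66 / 368, tolerance = 1e-12)
  expect_equal(m[["sd"]], sqrt(oracle_beta_var(66, 302)), tolerance = 1e-12)
  expect_equal(round(m[["mean"]], 2), 0.18)
  expect_equal(round(m[["sd"]], 2), 0.02)
  m2 <- beta_moments(beta_params(11, 48))
  expect_equal(round(m2[["mean"]], 2), 0.19)
  expect_equal(round(m2[["sd"]], 2), 0.05)
  expect_equal(effective_sample_size(beta_params(66, 302)), 368)
  expect_equal(effective_sample_size(beta_params(141, 362)), 503)
  expect_equal(effective_sample_size(beta_params(1, 1)), 2)
})

test_that("conjugate updating adds data to the prior; ESS is additive", {
  post <- posterior_update(beta_params(1, 1), events = 56, size = 310)
  expect_equal(post$alpha, 57)
  expect_equal(post$beta, 255)
  post2 <- posterior_update(beta_params(66, 302), events = 56, size = 310)
  expect_equal(post2$alpha, 122)
  expect_equal(post2$beta, 556)
  # identity with no data
  expect_equal(posterior_update(beta_params(1, 1), 0, 0), beta_params(1, 1))
  for (s in list(c(1, 1), c(66, 302), c(11, 48))) {
    p <- beta_params(s[1], s[2])
    expect_identical(
      effective_sample_size(posterior_update(p, 13, 100)),
      effective_sample_size(p) + 100
    )
  }
  expect_error(posterior_update(beta_params(1, 1), 5, 3),
               class = "bayesnid_error_domain")
  expect_error(posterior_update(beta_params(1, 1), -1, 3),
               class = "bayesnid_error_domain")
})

test_that("central intervals use exact Beta quantiles", {
  ci <- central_interval(beta_params(66, 302))
  # strong design prior spans roughly 14% to 22%
  expect_equal(round(ci[["lower"]], 2), 0.14)
  expect_equal(round(ci[["upper"]], 2), 0.22)
  expect_equal(central_interval(beta_params(1, 1)),
               c(lower = 0.025, upper = 0.975))
  # MC quantile oracle agrees
  p <- beta_params(11, 48)
  ci2 <- central_interval(p)
  mc <- withr::with_seed(5, quantile(rbeta(1e6, 11, 48), c(0.025, 0.975)))
  expect_equal(unname(ci2), unname(mc), tolerance = 2e-3)
  # endpoints bracket the mean and widen with level
  m <- beta_moments(p)[["mean"]]
  expect_true(ci2[["lower"]] < m && m < ci2[["upper"]])
  levels <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  widths <- vapply(levels, function(l) diff(central_interval(p, l)), 0)
  expect_true(all(diff(widths) > 0))
})
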