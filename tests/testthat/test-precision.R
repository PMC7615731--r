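skeptical_inputs <- function() {
  precision_inputs(beta_params(141, 362), beta_params(66, 302),
                   p1_assumed = 141 / 503, p0_assumed = 66 / 368)
}

flat_inputs <- function(p = 0.18) {
  precision_inputs(beta_params(1, 1), beta_params(1, 1), p, p)
}

test_that("closed-form widths match hand-evaluated reference cases", {
  sk <- skeptical_inputs()
  expect_equal(round(ci_width(sk, 0), 2), 0.11)
  expect_equal(round(ci_width(sk, 350), 2), 0.08)
  expect_equal(round(ci_width(flat_inputs(), 450), 2), 0.10)
  # closed form written out once, independently of the implementation
  n <- 350
  v1 <- (141 + n * 141 / 503) * (362 + n * (1 - 141 / 503)) /
    ((503 + n)^2 * (503 + n + 1))
  v0 <- (66 + n * 66 / 368) * (302 + n * (1 - 66 / 368)) /
    ((368 + n)^2 * (368 + n + 1))
  expect_equal(ci_width(sk, n), 2 * qnorm(0.975) * sqrt(v1 + v0),
               tolerance = 1e-12)
})

test_that("width decreases in n, scales as 1/sqrt(n), and vanishes with
           level and with n", {
  curve <- width_curve(flat_inputs(), seq(100, 1000, by = 100))
  expect_true(all(diff(curve$width) < 0))
  expect_equal(ci_width(flat_inputs(), 4e5) / ci_width(flat_inputs(), 1e5),
               0.5, tolerance = 5e-3)
  expect_lt(ci_width(flat_inputs(), 1e8), 1e-3)
  tiny_level <- precision_inputs(beta_params(1, 1), beta_params(1, 1),
                                 0.18, 0.18, level = 1e-8)
  expect_lt(ci_width(tiny_level, 100), 1e-8)
  # informative priors shrink the width at every n
  sk_at_flat_p <- precision_inputs(beta_params(141, 362), beta_params(66, 302),
                                   0.18, 0.18)
  expect_true(all(ci_width(sk_at_flat_p, curve$n_per_group) < curve$width))
})

test_that("closed-form width agrees with the Monte Carlo quantile oracle", {
  cases <- list(
    list(a1 = 141, b1 = 362, a0 = 66, b0 = 302,
         p1 = 141 / 503, p0 = 66 / 368, n = 350),
    list(a1 = 141, b1 = 362, a0 = 66, b0 = 302,
         p1 = 141 / 503, p0 = 66 / 368, n = 0),
    list(a1 = 11, b1 = 48, a0 = 11, b0 = 48, p1 = 0.18, p0 = 0.18, n = 400)
  )
  for (cs in cases) {
    closed <- ci_width(
      precision_inputs(beta_params(cs$a1, cs$b1), beta_params(cs$a0, cs$b0),
                       cs$p1, cs$p0),
      cs$n
    )
    mc <- oracle_mc_width(cs$a1, cs$b1, cs$a0, cs$b0, cs$p1, cs$p0, cs$n,
                          reps = 2e5, seed = 31)
    expect_equal(closed, mc, tolerance = 0.02)
  }
})

test_that("n_for_width returns the smallest grid point under the target", {
  hit <- n_for_width(flat_inputs(), target_width = 0.10)
  expect_identical(hit$n_per_group, 460L)
  expect_lte(hit$width, 0.10)
  expect_gt(ci_width(flat_inputs(), hit$n_per_group - 10), 0.10)
  hit_sk <- n_for_width(skeptical_inputs(), target_width = 0.10)
  expect_identical(hit_sk$n_per_group, 100L)
  # already satisfied at the grid minimum
  easy <- n_for_width(skeptical_inputs(), target_width = 0.5)
  expect_identical(easy$n_per_group, 0L)
  expect_error(n_for_width(flat_inputs(), 0.001, n_max = 500),
               class = "bayesnid_error_not_found")
})

test_that("ACCEPT curves are monotone, anchored at 0.5, and sharpen with n", {
  inputs <- flat_inputs()
  ns <- c(138, 199, 310, 551, 1241)
  curves <- accept_curve(inputs, ns, thresholds = seq(0.05, 0.15, by = 0.005))
  for (n in ns) {
    pr <- curves$probability[curves$n_per_group == n]
    expect_true(all(diff(pr) <= 0))
    expect_true(all(pr >= 0 & pr <= 1))
  }
  # steepness (max |slope|, taken across a band containing the posterior
  # mean) increases with sample size
  steep <- vapply(ns, function(n) {
    pr <- accept_prob(inputs, n, seq(-0.05, 0.15, by = 0.005))
    max(abs(diff(pr)))
  }, 0)
  expect_true(all(diff(steep) > 0))
  # exactly 1/2 at the posterior mean (flat equal arms: mean 0)
  expect_equal(accept_prob(inputs, 310, 0), 0.5, tolerance = 1e-12)
  # limits at extreme thresholds
  expect_equal(accept_prob(inputs, 310, -10), 1)
  expect_equal(accept_prob(inputs, 310, 10), 0)
})

test_that("large trials pin the posterior down near the assumed difference", {
  inputs <- flat_inputs()
  expect_lt(accept_prob(inputs, 1241, 0.02), 0.1)
  expect_lt(accept_prob(inputs, 138, 0.06), 0.1)
})

test_that("precision inputs can be sourced from any part of a scenario", {
  sc <- odyssey_scenario("skeptical")
  from_analysis <- precision_inputs_from_scenario(sc, p_from = "analysis")
  expect_equal(from_analysis$p1_assumed, 141 / 503, tolerance = 1e-12)
  from_design <- precision_inputs_from_scenario(sc, p_from = "design")
  expect_equal(from_design$p1_assumed, 66 / 368, tolerance = 1e-12)
  explicit <- precision_inputs_from_scenario(sc, p_from = "value",
                                             p1 = 0.28, p0 = 0.18)
  expect_equal(explicit$p1_assumed, 0.28)
  expect_error(precision_inputs_from_scenario(sc, p_from = "value"),
               class = "bayesnid_error_domain")
})
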