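# Property-level checks run at modest replicate counts; the published
# headline values are exercised at full precision in the acceptance tests.

test_that("joint, wrong-sign and unconditional probabilities are coherent", {
  for (name in c("base", "skeptical", "margin-u0515")) {
    res <- predictive_power(odyssey_scenario(name), 150, reps = 2e4,
                            seed = 101)
    expect_identical(res$joint_power + res$prob_sig_and_inferior,
                     res$unconditional_power)
    expect_gte(res$joint_power, 0)
    expect_lte(res$joint_power, res$unconditional_power)
    expect_lte(res$unconditional_power, 1)
  }
})

test_that("with a supportive design prior the wrong-sign slice is bounded by
           the prior probability of inferiority", {
  sc <- odyssey_scenario("base")
  res <- predictive_power(sc, 310, reps = 5e4, seed = 11)
  prior_inf <- 1 - prior_prob_ni(sc$experimental$design, sc$control$design,
                                 0.10)
  expect_lte(res$prob_sig_and_inferior, prior_inf + 0.005)
})

test_that("predictive power is monotone in n under common random numbers", {
  curve <- power_curve(odyssey_scenario("base"), seq(50, 650, by = 100),
                       reps = 2e4, seed = 7)
  expect_true(all(diff(curve$joint_power) >= -0.01))
  expect_identical(curve$n_per_group, sort(curve$n_per_group))
})

test_that("a one-point curve duplicates a direct call at the same seed", {
  sc <- odyssey_scenario("base")
  one <- power_curve(sc, 310, reps = 1e4, seed = 33)
  direct <- predictive_power(sc, 310, reps = 1e4, seed = 33)
  expect_identical(one$joint_power, direct$joint_power)
  expect_identical(one$unconditional_power, direct$unconditional_power)
})

test_that("a degenerate uniform margin reproduces the fixed-margin run", {
  sc_fixed <- odyssey_scenario("base")
  eps <- 1e-12
  sc_u <- scenario_with_margin(0.10 - eps, 0.10 + eps)
  a <- predictive_power(sc_fixed, 310, reps = 2e4, seed = 5)
  b <- predictive_power(sc_u, 310, reps = 2e4, seed = 5)
  expect_equal(a$joint_power, b$joint_power)
  expect_equal(a$unconditional_power, b$unconditional_power)
})

test_that("the search returns the smallest grid point meeting the target", {
  sc <- odyssey_scenario("base")
  fit <- find_n_for_power(sc, target = 0.80, step = 20, reps = 2e4, seed = 13)
  expect_gte(fit$estimate, 0.80)
  # the preceding grid point must fall short under the same random numbers
  below <- predictive_power(sc, fit$n_per_group - fit$step,
                            reps = fit$reps_at_decision, seed = 13)
  expect_lt(below$joint_power, 0.80)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(glance(fit)$seed, 13L)
})

test_that("an unreachable power target reports the best attempt", {
  err <- expect_error(
    find_n_for_power(odyssey_scenario("skeptical"), target = 0.999,
                     step = 200, n_max = 600, reps = 5e3, seed = 2),
    class = "bayesnid_error_not_found"
  )
  expect_true(is.finite(err$best_estimate))
  expect_true(err$best_n <= 600)
})

test_that("results carry their seed and replicate provenance", {
  res <- predictive_power(odyssey_scenario("base"), 100, reps = 1e4,
                          seed = 99)
  expect_identical(res$seed, 99L)
  expect_identical(res$reps, 10000L)
  # omitted seed is drawn and reported, and reruns differ
  r1 <- predictive_power(odyssey_scenario("base"), 100, reps = 1e3)
  expect_true(is.integer(r1$seed))
  expect_identical(
    predictive_power(odyssey_scenario("base"), 100, reps = 1e4,
                     seed = r1$seed)$joint_power,
    predictive_power(odyssey_scenario("base"), 100, reps = 1e4,
                     seed = r1$seed)$joint_power
  )
})
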