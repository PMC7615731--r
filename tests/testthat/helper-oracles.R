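# Independent oracles used across tests: straight transcriptions of the
# closed forms, kept free of the package's own code paths.

# Beta variance, closed form
oracle_beta_var <- function(a, b) a * b / ((a + b)^2 * (a + b + 1))

# Monte Carlo quantile oracle for the credible-interval width of the risk
# difference: sample each arm's posterior at assumed counts and take the
# central quantiles of the difference. Checks the normal-approximation
# closed form from the outside.
oracle_mc_width <- function(a1, b1, a0, b0, p1, p0, n, level = 0.95,
                            reps = 2e5, seed = 1) {
  withr::with_seed(seed, {
    d <- rbeta(reps, a1 + n * p1, b1 + n * (1 - p1)) -
      rbeta(reps, a0 + n * p0, b0 + n * (1 - p0))
    q <- quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    q[2] - q[1]
  })
}

scenario_with_margin <- function(lower, upper) {
  trial_scenario(
    experimental = arm_priors(design = beta_params(66, 302),
                              analysis = beta_params(1, 1)),
    control = arm_priors(design = beta_params(66, 302),
                         analysis = beta_params(1, 1)),
    margin = margin_uniform(lower, upper)
  )
}
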