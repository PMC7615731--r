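#' Normal approximation to the risk-difference posterior
#'
#' With independent Beta distributions for the two arms' failure
#' probabilities, the risk difference delta = pi1 - pi0 (experimental minus
#' control) is treated as approximately normal with mean equal to the
#' difference of the Beta means and variance equal to the sum of the Beta
#' variances. This is the computational workhorse for every probability
#' statement the package makes about delta.
#'
#' @param experimental,control [beta_params] for the experimental and control
#'   arm (priors or posteriors).
#' @return An object of class `normal_summary` with fields `mean` and
#'   `variance`.
#' @examples
#' diff_posterior_normal(beta_params(57, 255), beta_params(60, 252))
#' @export
diff_posterior_normal <- function(experimental, control) {
  experimental <- as_beta_params(experimental, "experimental")
  control <- as_beta_params(control, "control")
  m1 <- beta_moments(experimental)
  m0 <- beta_moments(control)
  structure(
    list(mean = unname(m1[["mean"]] - m0[["mean"]]),
         variance = unname(m1[["sd"]]^2 + m0[["sd"]]^2)),
    class = "normal_summary"
  )
}

#' @export
print.normal_summary <- function(x, ...) {
  cat(sprintf("Risk difference ~ N(mean = %.4f, sd = %.4f)\n",
              x$mean, sqrt(x$variance)))
  invisible(x)
}

#' Probability that the risk difference falls below a threshold
#'
#' Evaluates P(delta < threshold) under a [diff_posterior_normal()] summary:
#' the posterior probability of non-inferiority when `threshold` is the
#' margin. Its complement is the exceedance probability plotted by ACCEPT
#' curves.
#'
#' @param summary A `normal_summary`.
#' @param threshold Threshold on the risk-difference scale (vectorised).
#' @return Probabilities in \[0, 1\].
#' @export
prob_diff_below <- function(summary, threshold) {
  if (!inherits(summary, "normal_summary")) {
    abort("`summary` must come from diff_posterior_normal().",
          class = "bayesnid_error_domain")
  }
  pnorm((threshold - summary$mean) / sqrt(summary$variance))
}

#' Prior probability of non-inferiority
#'
#' The probability, before any trial data, that pi1 - pi0 falls below the
#' margin when the two arms' failure probabilities follow the given Beta
#' distributions. `method = "normal"` uses the normal approximation to the
#' difference; `method = "mc"` samples the two Betas directly and serves as
#' the exact-model check on the approximation.
#'
#' @param experimental,control [beta_params] for the two arms.
#' @param margin Non-inferiority margin in (0, 1).
#' @param method `"normal"` (default) or `"mc"`.
#' @param reps Monte Carlo draws when `method = "mc"`.
#' @param seed Seed for the MC draw; drawn (and reported) when `NULL`.
#' @return A single probability. For `method = "mc"` it carries attributes
#'   `mc_se`, `reps` and `seed`.
#' @examples
#' prior_prob_ni(beta_params(11, 48), beta_params(11, 48), margin = 0.10)
#' @export
prior_prob_ni <- function(experimental, control, margin,
                          method = c("normal", "mc"),
                          reps = 1e6, seed = NULL) {
  experimental <- as_beta_params(experimental, "experimental")
  control <- as_beta_params(control, "control")
  check_number(margin, "margin", 0, 1, open_lower = TRUE, open_upper = TRUE)
  method <- match.arg(method)
  if (method == "normal") {
    return(prob_diff_below(diff_posterior_normal(experimental, control),
                           margin))
  }
  check_number(reps, "reps", lower = 1, integer = TRUE)
  seed <- resolve_seed(seed)
  est <- withr::with_seed(seed, {
    d <- rbeta(reps, experimental$alpha, experimental$beta) -
      rbeta(reps, control$alpha, control$beta)
    mean(d < margin)
  })
  structure(est, mc_se = sqrt(est * (1 - est) / reps),
            reps = as.integer(reps), seed = seed)
}
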