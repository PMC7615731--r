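#' Inputs for precision-based sample size assessment
#'
#' The precision approach works entirely from the analysis priors and an
#' assumed observed outcome: with `n` patients per arm and assumed observed
#' failure proportions `p1_assumed`, `p0_assumed`, each arm's posterior is
#' the analysis prior updated with `n * p` assumed events, and the
#' risk-difference posterior is summarised by the usual normal
#' approximation. Design priors play no role here.
#'
#' The assumed proportions are deliberately a required argument. Common
#' practice sets them to the analysis-prior means when the priors are
#' informative, but to the anticipated event rate (not 50%) when the
#' analysis priors are flat; no default can serve both.
#' [precision_inputs_from_scenario()] builds inputs from a scenario, taking
#' the proportions from the analysis priors, the design priors, or explicit
#' values.
#'
#' @param analysis_experimental,analysis_control Analysis-prior
#'   [beta_params] for the two arms.
#' @param p1_assumed,p0_assumed Assumed observed failure proportions, in
#'   (0, 1).
#' @param level Credibility level for interval widths (default 0.95).
#' @return An object of class `precision_inputs`.
#' @examples
#' precision_inputs(beta_params(1, 1), beta_params(1, 1), 0.18, 0.18)
#' @export
precision_inputs <- function(analysis_experimental, analysis_control,
                             p1_assumed, p0_assumed, level = 0.95) {
  check_number(p1_assumed, "p1_assumed", 0, 1, TRUE, TRUE)
  check_number(p0_assumed, "p0_assumed", 0, 1, TRUE, TRUE)
  check_number(level, "level", 0, 1, open_lower = TRUE, open_upper = TRUE)
  structure(
    list(
      analysis_experimental = as_beta_params(analysis_experimental,
                                             "analysis_experimental"),
      analysis_control = as_beta_params(analysis_control, "analysis_control"),
      p1_assumed = as.numeric(p1_assumed),
      p0_assumed = as.numeric(p0_assumed),
      level = as.numeric(level)
    ),
    class = "precision_inputs"
  )
}

#' @param scenario A [trial_scenario].
#' @param p_from Where to take the assumed proportions from: the analysis
#'   priors' means, the design priors' means, or explicit `p1`/`p0` values.
#' @param p1,p0 Explicit assumed proportions when `p_from = "value"`.
#' @rdname precision_inputs
#' @export
precision_inputs_from_scenario <- function(scenario,
                                           p_from = c("analysis", "design",
                                                      "value"),
                                           p1 = NULL, p0 = NULL,
                                           level = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  p_from <- match.arg(p_from)
  if (p_from == "value") {
    if (is.null(p1) || is.null(p0)) {
      abort("`p_from = \"value\"` needs explicit `p1` and `p0`.",
            class = "bayesnid_error_domain")
    }
  } else {
    role <- if (p_from == "analysis") "analysis" else "design"
    p1 <- beta_moments(scenario$experimental[[role]])[["mean"]]
    p0 <- beta_moments(scenario$control[[role]])[["mean"]]
  }
  precision_inputs(scenario$experimental$analysis, scenario$control$analysis,
                   p1, p0, level = level %||% (1 - scenario$alpha))
}

# posterior normal summary for assumed (non-integer) counts n*p per arm
assumed_posterior_normal <- function(inputs, n_per_group) {
  a1 <- inputs$analysis_experimental
  a0 <- inputs$analysis_control
  n <- n_per_group
  A1 <- a1$alpha + n * inputs$p1_assumed
  B1 <- a1$beta + n * (1 - inputs$p1_assumed)
  A0 <- a0$alpha + n * inputs$p0_assumed
  B0 <- a0$beta + n * (1 - inputs$p0_assumed)
  list(mean = A1 / (A1 + B1) - A0 / (A0 + B0),
       sd = sqrt(beta_var(A1, B1) + beta_var(A0, B0)))
}

#' Credible-interval width for the risk difference at a given sample size
#'
#' Closed-form width of the central credible interval for delta = pi1 - pi0
#' under the normal approximation:
#' `2 Z_{(1-level)/2} * sqrt(Var(pi1 | data) + Var(pi0 | data))`, with each
#' arm's posterior formed from its analysis prior plus `n * p` assumed
#' events in `n` patients. Deterministic; no simulation involved.
#'
#' @param inputs A [precision_inputs] object.
#' @param n_per_group Patients per arm; 0 gives the width from the priors
#'   alone. Vectorised.
#' @return Interval width(s) on the risk-difference scale.
#' @examples
#' flat <- precision_inputs(beta_params(1, 1), beta_params(1, 1), 0.18, 0.18)
#' ci_width(flat, 450) # about 0.10
#' @export
ci_width <- function(inputs, n_per_group) {
  stopifnot(inherits(inputs, "precision_inputs"))
  if (any(n_per_group < 0)) {
    abort("`n_per_group` must be non-negative.",
          class = "bayesnid_error_domain")
  }
  post <- assumed_posterior_normal(inputs, n_per_group)
  2 * qnorm(1 - (1 - inputs$level) / 2) * post$sd
}

#' Width of the credible interval across a grid of sample sizes
#'
#' @inheritParams ci_width
#' @param n_grid Vector of per-group sample sizes.
#' @return A tibble (class `width_curve`) with columns `n_per_group` and
#'   `width`, ordered by `n_per_group`; widths are strictly decreasing.
#' @export
width_curve <- function(inputs, n_grid) {
  if (length(n_grid) < 1) {
    abort("`n_grid` must be non-empty.", class = "bayesnid_error_domain")
  }
  n <- sort(unique(as.numeric(n_grid)))
  out <- tibble(n_per_group = n, width = ci_width(inputs, n),
                level = inputs$level)
  class(out) <- c("width_curve", class(out))
  out
}

#' Smallest sample size achieving a target interval width
#'
#' Deterministic scan of the closed-form width; the returned `n*` satisfies
#' `ci_width(n*) <= target_width < ci_width(n* - step)`. The comparison uses
#' the unrounded width; published tables often quote widths rounded to the
#' whole percent, which can make their sample size one step smaller.
#'
#' @inheritParams ci_width
#' @param target_width Required interval width (> 0).
#' @param step Grid step (default 10).
#' @param n_min,n_max Grid range (defaults 0 and 10000).
#' @return A one-row tibble with `n_per_group` and `width`.
#' @examples
#' flat <- precision_inputs(beta_params(1, 1), beta_params(1, 1), 0.18, 0.18)
#' n_for_width(flat, target_width = 0.10)
#' @export
n_for_width <- function(inputs, target_width, step = 10, n_min = 0,
                        n_max = 10000) {
  check_number(target_width, "target_width", lower = 0, open_lower = TRUE)
  check_number(step, "step", lower = 1, integer = TRUE)
  grid <- seq(n_min, n_max, by = step)
  widths <- ci_width(inputs, grid)
  hit <- which(widths <= target_width)
  if (length(hit) == 0) {
    abort(sprintf(
      "Width %.4f not reachable by n = %d (best %.4f).",
      target_width, n_max, min(widths)
    ), class = "bayesnid_error_not_found",
    best_n = grid[which.min(widths)], best_width = min(widths))
  }
  tibble(n_per_group = as.integer(grid[hit[1]]), width = widths[hit[1]])
}

#' Posterior probability that the risk difference exceeds a threshold
#'
#' The quantity plotted by ACCEPT (ACceptability Curve Estimation using
#' Probability above Threshold): `P(delta > threshold | data) =
#' 1 - Phi((threshold - mu) / sigma)`, with `mu`, `sigma` from the assumed
#' posterior of [precision_inputs]. Complementary to [prob_diff_below()] at
#' the same threshold.
#'
#' @inheritParams ci_width
#' @param threshold Risk-difference threshold(s); vectorised.
#' @return Exceedance probabilities in \[0, 1\].
#' @export
accept_prob <- function(inputs, n_per_group, threshold) {
  stopifnot(inherits(inputs, "precision_inputs"))
  check_number(n_per_group, "n_per_group", lower = 0)
  post <- assumed_posterior_normal(inputs, n_per_group)
  1 - pnorm((threshold - post$mean) / post$sd)
}

#' ACCEPT curves over a range of non-inferiority thresholds
#'
#' Tabulates the exceedance probability over thresholds for one or more
#' sample sizes (long format, one row per n-threshold pair). Curves are
#' monotone non-increasing in the threshold and become steeper as `n`
#' grows; the probability is exactly 0.5 at the posterior mean.
#'
#' @inheritParams ci_width
#' @param n_per_group One or more per-group sample sizes.
#' @param thresholds Ascending vector of risk-difference thresholds
#'   (default the 5%-15% band conventionally examined).
#' @return A tibble (class `accept_curve`) with columns `n_per_group`,
#'   `threshold`, `probability`.
#' @examples
#' flat <- precision_inputs(beta_params(1, 1), beta_params(1, 1), 0.18, 0.18)
#' accept_curve(flat, c(138, 310, 1241))
#' @export
accept_curve <- function(inputs, n_per_group,
                         thresholds = seq(0.05, 0.15, by = 0.005)) {
  if (length(thresholds) < 1 || is.unsorted(thresholds)) {
    abort("`thresholds` must be a non-empty ascending vector.",
          class = "bayesnid_error_domain")
  }
  rows <- purrr::map(sort(unique(as.numeric(n_per_group))), function(n) {
    tibble(n_per_group = n, threshold = as.numeric(thresholds),
           probability = accept_prob(inputs, n, thresholds))
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("accept_curve", class(out))
  out
}
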