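#' Run all four sample-size approaches on a scenario
#'
#' Convenience wrapper that dispatches to the frequentist formula, the
#' predictive-power search, the expected-posterior-probability search and
#' the precision width curve, and collects the results in one structured,
#' JSON-serialisable record. Every stochastic component carries its `reps`
#' and `seed`, and the record includes a hash of the scenario, so identical
#' (scenario, seed, reps) inputs give identical output.
#'
#' The frequentist comparator needs point values: it uses the design-prior
#' means as expected proportions and, under a margin prior, the midpoint of
#' its support.
#'
#' @inheritParams predictive_power
#' @param target Target power / expected posterior probability for the
#'   searches (default 0.90).
#' @param step Grid step for the searches (default 10).
#' @param n_per_group Sample size at which predictive power is reported;
#'   defaults to the frequentist answer.
#' @param width_grid Sample sizes for the precision width curve.
#' @param p_from Source of the assumed observed proportions for the
#'   precision approach (see [precision_inputs_from_scenario()]); default
#'   `"design"`, the anticipated event rates.
#' @return A list of class `ni_report`; use [report_json()] to serialise.
#' @examples
#' \donttest{
#' rep <- run_report(odyssey_scenario("base"), reps = 20000, seed = 1)
#' }
#' @export
run_report <- function(scenario, target = 0.90, step = 10, n_per_group = NULL,
                       width_grid = seq(0, 1000, by = 50),
                       p_from = "design", reps = 1e5, seed = NULL) {
  stopifnot(inherits(scenario, "trial_scenario"))
  seed <- resolve_seed(seed)
  p1 <- beta_moments(scenario$experimental$design)[["mean"]]
  p0 <- beta_moments(scenario$control$design)[["mean"]]
  margin_pt <- if (scenario$margin$kind == "fixed") {
    scenario$margin$value
  } else {
    (scenario$margin$lower + scenario$margin$upper) / 2
  }

  freq_n <- freq_required_n(p1, p0, margin_pt, alpha = scenario$alpha,
                            power = target)
  n_report <- as.integer(n_per_group %||% freq_n)
  power <- predictive_power(scenario, n_report, reps = reps, seed = seed)
  power_search <- find_n_for_power(scenario, target = target, step = step,
                                   reps = reps, seed = seed)
  epp_search <- find_n_for_epp(scenario, target = target, step = step,
                               reps = reps, seed = seed)
  prec <- precision_inputs_from_scenario(scenario, p_from = p_from)
  widths <- width_curve(prec, width_grid)

  structure(
    list(
      scenario_hash = rlang::hash(scenario),
      settings = list(target = target, step = step, reps = as.integer(reps),
                      seed = seed, p_from = p_from),
      frequentist = list(n_per_group = freq_n, p1_expected = p1,
                         p0_expected = p0, margin = margin_pt,
                         power = target),
      predictive_power = as.list(tidy(power)),
      predictive_power_search = as.list(tidy(power_search)),
      expected_posterior_search = as.list(tidy(epp_search)),
      width_curve = as.data.frame(widths)
    ),
    class = "ni_report"
  )
}

#' @export
print.ni_report <- function(x, ...) {
  cat("Non-inferiority sample-size report\n")
  cat(sprintf("  frequentist:          %d per group (%.0f%% power)\n",
              x$frequentist$n_per_group, 100 * x$frequentist$power))
  cat(sprintf("  predictive power:     %.3f at n = %d\n",
              x$predictive_power$joint_power,
              x$predictive_power$n_per_group))
  cat(sprintf("  power search:         %d per group for %.0f%%\n",
              x$predictive_power_search$n_per_group,
              100 * x$settings$target))
  cat(sprintf("  expected posterior:   %d per group for %.0f%%\n",
              x$expected_posterior_search$n_per_group,
              100 * x$settings$target))
  cat(sprintf("  width at n = %g:      %.3f\n",
              max(x$width_curve$n_per_group),
              min(x$width_curve$width)))
  invisible(x)
}

#' Serialise a report to JSON
#'
#' @param report An `ni_report` from [run_report()].
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ni_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
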