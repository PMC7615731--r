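#' Expected posterior probability of non-inferiority
#'
#' Estimates `e_n`, the mean over the predictive distribution of the data of
#' the posterior probability P(delta < delta* | data). Whereas the
#' predictive-power approach asks how often the posterior probability will
#' clear a high bar, this approach controls only its expectation, and so
#' leads to smaller sample sizes; it suits trials whose focus is estimating
#' the probability of non-inferiority rather than testing it.
#'
#' At `n_per_group = 0` the data step vanishes: with a fixed margin the
#' result is the analysis-prior probability of non-inferiority, computed
#' deterministically (no Monte Carlo error); informative analysis priors can
#' therefore meet a target with no patients at all. With a margin prior the
#' n = 0 value still averages over margin draws.
#'
#' @inheritParams predictive_power
#' @param n_per_group Patients per arm; 0 is allowed.
#' @return An `epp_result` with fields `e_n`, `mc_se`, `reps`, `seed`,
#'   `n_per_group`.
#' @examples
#' expected_posterior_prob(odyssey_scenario("base"), n_per_group = 110,
#'                         reps = 10000, seed = 1)
#' @export
expected_posterior_prob <- function(scenario, n_per_group, reps = 1e5,
                                    seed = NULL) {
  check_number(n_per_group, "n_per_group", lower = 0, integer = TRUE)
  if (n_per_group == 0 && scenario$margin$kind == "fixed") {
    e <- prior_prob_ni(scenario$experimental$analysis,
                       scenario$control$analysis,
                       margin = scenario$margin$value, method = "normal")
    return(structure(
      list(e_n = e, mc_se = 0, reps = 0L, seed = NA_integer_,
           n_per_group = 0L),
      class = "epp_result"
    ))
  }
  seed <- resolve_seed(seed)
  sim <- ni_replicates(scenario, n_per_group, reps, seed)
  structure(
    list(
      e_n = mean(sim$post_prob),
      mc_se = sd(sim$post_prob) / sqrt(reps),
      reps = as.integer(reps), seed = seed,
      n_per_group = as.integer(n_per_group)
    ),
    class = "epp_result"
  )
}

#' @export
print.epp_result <- function(x, ...) {
  cat(sprintf(
    "Expected posterior probability of non-inferiority at n = %d per group\n",
    x$n_per_group
  ))
  cat(sprintf("  e_n = %.4f (MC se %.2g)\n", x$e_n, x$mc_se))
  if (x$reps > 0) {
    cat(sprintf("  reps %s, seed %d\n", format(x$reps, big.mark = ","),
                x$seed))
  } else {
    cat("  deterministic (analysis prior alone)\n")
  }
  invisible(x)
}

#' @export
tidy.epp_result <- function(x, ...) {
  tibble(n_per_group = x$n_per_group, e_n = x$e_n, mc_se = x$mc_se)
}

#' @export
glance.epp_result <- function(x, ...) {
  tibble(reps = x$reps, seed = x$seed, n_per_group = x$n_per_group)
}

#' Expected posterior probability across a grid of sample sizes
#'
#' One [expected_posterior_prob()] row per sample size, with common random
#' numbers across the grid.
#'
#' @inheritParams expected_posterior_prob
#' @param n_values Vector of per-group sample sizes (0 allowed).
#' @return A tibble (class `epp_curve`) with columns `n_per_group`, `e_n`,
#'   `mc_se`, `reps`, `seed`, ordered by `n_per_group`.
#' @examples
#' epp_curve(odyssey_scenario("base"), c(0, 110), reps = 5000, seed = 1)
#' @export
epp_curve <- function(scenario, n_values, reps = 1e5, seed = NULL) {
  if (length(n_values) < 1) {
    abort("`n_values` must be non-empty.", class = "bayesnid_error_domain")
  }
  seed <- resolve_seed(seed)
  rows <- purrr::map(sort(unique(as.integer(n_values))), function(n) {
    tidy(expected_posterior_prob(scenario, n, reps = reps, seed = seed))
  })
  out <- purrr::list_rbind(rows)
  out$reps <- as.integer(reps)
  out$seed <- seed
  class(out) <- c("epp_curve", class(out))
  out
}

#' Smallest sample size reaching a target expected posterior probability
#'
#' Grid search with the same conventions as [find_n_for_power()] (common
#' random numbers, one-off tenfold replicate escalation at a boundary
#' decision). `n_min = 0` is allowed: an informative analysis prior may meet
#' the target with no data.
#'
#' @inheritParams find_n_for_power
#' @param target Required expected posterior probability of non-inferiority.
#' @param n_min Smallest sample size considered (default 0).
#' @return An `ni_search` object; `$n_per_group` holds the answer.
#' @examples
#' \donttest{
#' find_n_for_epp(odyssey_scenario("base"), target = 0.9, seed = 1)
#' }
#' @export
find_n_for_epp <- function(scenario, target = 0.90, step = 10,
                           n_min = 0, n_max = 2000, reps = 1e5, seed = NULL) {
  seed <- resolve_seed(seed)
  estimate_fun <- function(n, r) {
    res <- expected_posterior_prob(scenario, n, reps = r, seed = seed)
    list(estimate = res$e_n, mc_se = res$mc_se, reps = r)
  }
  search_grid_mc(estimate_fun, target, step, n_min, n_max, reps, seed,
                 label = "expected posterior probability")
}
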