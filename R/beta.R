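#' Beta prior/posterior for an arm's failure probability
#'
#' A `beta_params` object stores the two shape parameters of a Beta
#' distribution used as prior (or posterior) for a single arm's failure
#' probability. `alpha` counts pseudo-events and `beta` pseudo-non-events, so
#' the prior is "worth" `alpha + beta` observations (its effective sample
#' size).
#'
#' @param alpha Positive shape parameter (pseudo-events).
#' @param beta Positive shape parameter (pseudo-non-events).
#'
#' @return An object of class `beta_params`.
#' @examples
#' beta_params(66, 302)
#' @export
beta_params <- function(alpha, beta) {
  check_number(alpha, "alpha", lower = 0, open_lower = TRUE)
  check_number(beta, "beta", lower = 0, open_lower = TRUE)
  structure(
    list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
    class = "beta_params"
  )
}

#' @export
print.beta_params <- function(x, ...) {
  m <- beta_moments(x)
  cat(sprintf("Beta(%g, %g)  mean %.3f, sd %.3f, ESS %g\n",
              x$alpha, x$beta, m[["mean"]], m[["sd"]],
              effective_sample_size(x)))
  invisible(x)
}

is_beta_params <- function(x) inherits(x, "beta_params")

as_beta_params <- function(x, name = "prior") {
  if (is_beta_params(x)) return(x)
  if (is.numeric(x) && length(x) == 2L) return(beta_params(x[[1]], x[[2]]))
  abort(sprintf("`%s` must be a beta_params object or a length-2 numeric.",
                name), class = "bayesnid_error_domain")
}

#' Moment matching for Beta priors
#'
#' `beta_from_moments()` converts a (mean, sd) pair into the Beta distribution
#' with those moments; `beta_moments()` is its inverse. Matching solves
#' `alpha = mean * K`, `beta = (1 - mean) * K` with
#' `K = mean (1 - mean) / sd^2 - 1`. A Beta distribution with the requested
#' moments exists only when `sd^2 < mean (1 - mean)`.
#'
#' Elicited priors are usually reported with integer-rounded parameters (for
#' example a mean of 18% and SD of 2% is quoted as Beta(66, 302));
#' `round_params = TRUE` reproduces that convention by rounding each shape
#' parameter independently to the nearest integer. The default keeps the
#' exact real-valued solution.
#'
#' @param mean Prior mean, strictly inside (0, 1).
#' @param sd Prior standard deviation, positive.
#' @param round_params Round the matched shape parameters to integers?
#'
#' @return `beta_from_moments()`: a [beta_params] object. `beta_moments()`:
#'   a named numeric vector with elements `mean` and `sd`.
#' @examples
#' beta_from_moments(0.18, 0.02, round_params = TRUE) # Beta(66, 302)
#' beta_moments(beta_params(66, 302))
#' @export
beta_from_moments <- function(mean, sd, round_params = FALSE) {
  check_number(mean, "mean", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(sd, "sd", lower = 0, open_lower = TRUE)
  if (sd^2 >= mean * (1 - mean)) {
    abort(sprintf(
      "No Beta distribution has mean %g and sd %g: need sd^2 < mean*(1-mean) = %g.",
      mean, sd, mean * (1 - mean)
    ), class = "bayesnid_error_invalid_moments")
  }
  K <- mean * (1 - mean) / sd^2 - 1
  a <- mean * K
  b <- (1 - mean) * K
  if (round_params) {
    a <- round(a)
    b <- round(b)
  }
  beta_params(a, b)
}

#' @param p A [beta_params] object.
#' @rdname beta_from_moments
#' @export
beta_moments <- function(p) {
  p <- as_beta_params(p)
  s <- p$alpha + p$beta
  c(mean = p$alpha / s, sd = sqrt(p$alpha * p$beta / (s^2 * (s + 1))))
}

#' Effective sample size of a Beta prior
#'
#' The number of observations a Beta prior is worth: `alpha + beta`.
#'
#' @param p A [beta_params] object.
#' @return A single number.
#' @examples
#' effective_sample_size(beta_params(66, 302)) # 368
#' @export
effective_sample_size <- function(p) {
  p <- as_beta_params(p)
  p$alpha + p$beta
}

#' Central credible interval of a Beta distribution
#'
#' Equal-tailed interval from the exact Beta quantile function.
#'
#' @param p A [beta_params] object.
#' @param level Credibility level in (0, 1); default 0.95.
#' @return Named numeric vector with elements `lower` and `upper`.
#' @examples
#' central_interval(beta_params(66, 302)) # roughly 14% to 22%
#' @export
central_interval <- function(p, level = 0.95) {
  p <- as_beta_params(p)
  check_number(level, "level", 0, 1, open_lower = TRUE, open_upper = TRUE)
  tail <- (1 - level) / 2
  q <- qbeta(c(tail, 1 - tail), p$alpha, p$beta)
  c(lower = q[[1]], upper = q[[2]])
}

#' Conjugate Beta-binomial update
#'
#' A Beta(a, b) prior observing `events` failures out of `size` patients
#' yields the Beta(a + events, b + size - events) posterior.
#'
#' @param p A [beta_params] prior.
#' @param events Observed number of events (failures), `0 <= events <= size`.
#' @param size Number of patients observed.
#' @return The posterior [beta_params].
#' @examples
#' posterior_update(beta_params(1, 1), events = 56, size = 310) # Beta(57, 255)
#' @export
posterior_update <- function(p, events, size) {
  p <- as_beta_params(p)
  check_number(size, "size", lower = 0, integer = TRUE)
  check_number(events, "events", lower = 0, upper = size, integer = TRUE)
  beta_params(p$alpha + events, p$beta + size - events)
}

# vectorised Beta variance on raw shape parameters (used by the MC engines)
beta_var <- function(a, b) {
  s <- a + b
  a * b / (s^2 * (s + 1))
}
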