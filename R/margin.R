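#' Non-inferiority margin specification
#'
#' The non-inferiority margin delta* is the largest clinically acceptable
#' excess failure risk of the experimental arm over control. It can be fixed,
#' as in conventional designs, or given a uniform prior to represent
#' variability of opinion among experts; with a margin prior each Monte Carlo
#' replicate draws its own delta* and the predictive power becomes the
#' expected proportion of experts convinced by the final analysis.
#'
#' @param value Fixed margin, strictly inside (0, 1), on the risk-difference
#'   scale (0.10 means 10 percentage points).
#' @param lower,upper Bounds of a uniform margin prior,
#'   `0 < lower < upper < 1`.
#'
#' @return An object of class `margin_spec`.
#' @examples
#' margin_fixed(0.10)
#' margin_uniform(0.08, 0.12)
#' @export
margin_fixed <- function(value) {
  check_number(value, "value", 0, 1, open_lower = TRUE, open_upper = TRUE)
  structure(list(kind = "fixed", value = as.numeric(value)),
            class = "margin_spec")
}

#' @rdname margin_fixed
#' @export
margin_uniform <- function(lower, upper) {
  check_number(lower, "lower", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(upper, "upper", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (lower >= upper) {
    abort("`lower` must be strictly below `upper`.",
          class = "bayesnid_error_domain")
  }
  structure(list(kind = "uniform", lower = as.numeric(lower),
                 upper = as.numeric(upper)),
            class = "margin_spec")
}

#' @export
print.margin_spec <- function(x, ...) {
  if (x$kind == "fixed") {
    cat(sprintf("Fixed non-inferiority margin: %g\n", x$value))
  } else {
    cat(sprintf("Uniform(%g, %g) prior on the non-inferiority margin\n",
                x$lower, x$upper))
  }
  invisible(x)
}

as_margin_spec <- function(x, name = "margin") {
  if (inherits(x, "margin_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(margin_fixed(x))
  if (is.numeric(x) && length(x) == 2L) return(margin_uniform(x[[1]], x[[2]]))
  abort(sprintf(
    "`%s` must be a margin_spec, a single fixed value, or uniform bounds.",
    name
  ), class = "bayesnid_error_domain")
}

#' Draw non-inferiority margins from a margin specification
#'
#' Fixed margins are returned deterministically (repeated `n` times); uniform
#' margin priors are sampled from the current random stream, so callers
#' control reproducibility by seeding.
#'
#' @param margin A [margin_fixed()] / [margin_uniform()] specification.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_margin <- function(margin, n = 1) {
  margin <- as_margin_spec(margin)
  check_number(n, "n", lower = 1, integer = TRUE)
  if (margin$kind == "fixed") {
    rep(margin$value, n)
  } else {
    runif(n, margin$lower, margin$upper)
  }
}
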