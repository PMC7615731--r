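#' Frequentist sample size for a non-inferiority trial with binary outcome
#'
#' The standard normal-approximation formula: with expected event proportions
#' `p1_expected`, `p0_expected`, margin `delta*`, two-sided level `alpha` and
#' power `1 - beta`, the per-group size is
#' `n = (Z_{alpha/2} + Z_beta)^2 [p1(1-p1) + p0(1-p0)] / (p1 - p0 - delta*)^2`,
#' rounded to the nearest integer (half away from zero). Nearest-integer
#' rounding, rather than the more common ceiling, reproduces the published
#' reference values for this design (for example 310 per group at an 18%
#' failure proportion and 10% margin).
#'
#' @param p1_expected,p0_expected Expected failure proportions in the
#'   experimental and control arm, in (0, 1).
#' @param margin Non-inferiority margin on the risk-difference scale; must
#'   exceed `p1_expected - p0_expected` or the design is infeasible.
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.90).
#' @return Per-group sample size (positive integer).
#' @examples
#' freq_required_n(0.18, 0.18, margin = 0.10) # 310
#' @export
freq_required_n <- function(p1_expected, p0_expected, margin,
                            alpha = 0.05, power = 0.90) {
  f <- freq_f(p1_expected, p0_expected, margin, alpha, power)
  n <- (qnorm(1 - alpha / 2) + qnorm(power))^2 / f
  max(1L, as.integer(floor(n + 0.5)))
}

freq_f <- function(p1_expected, p0_expected, margin, alpha, power) {
  check_number(p1_expected, "p1_expected", 0, 1, TRUE, TRUE)
  check_number(p0_expected, "p0_expected", 0, 1, TRUE, TRUE)
  check_number(margin, "margin", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  check_number(power, "power", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (margin <= p1_expected - p0_expected) {
    abort(sprintf(
      "Infeasible design: margin (%g) must exceed the expected risk difference (%g).",
      margin, p1_expected - p0_expected
    ), class = "bayesnid_error_infeasible")
  }
  (p1_expected - p0_expected - margin)^2 /
    (p1_expected * (1 - p1_expected) + p0_expected * (1 - p0_expected))
}

#' Frequentist power at a given per-group sample size
#'
#' Algebraic inversion of the sample-size formula:
#' `power = Phi(sqrt(n f) - Z_{alpha/2})`.
#'
#' @inheritParams freq_required_n
#' @param n Per-group sample size.
#' @return Power in (0, 1); monotone increasing in `n`.
#' @examples
#' freq_power(0.18, 0.18, margin = 0.10, n = 310) # about 0.90
#' @export
freq_power <- function(p1_expected, p0_expected, margin, n, alpha = 0.05) {
  check_number(n, "n", lower = 1, integer = TRUE)
  f <- freq_f(p1_expected, p0_expected, margin, alpha, power = 0.5)
  pnorm(sqrt(n * f) - qnorm(1 - alpha / 2))
}

#' Inflate a per-group sample size for expected attrition
#'
#' Divides by the expected retention fraction and takes the ceiling, so the
#' retained patients still meet the design size.
#'
#' @param n_per_group Per-group sample size before inflation.
#' @param loss_fraction Anticipated loss to follow-up, in \[0, 1).
#' @return Inflated per-group size (integer).
#' @examples
#' adjust_for_attrition(310, 0.10) # 345
#' @export
adjust_for_attrition <- function(n_per_group, loss_fraction) {
  check_number(n_per_group, "n_per_group", lower = 1, integer = TRUE)
  check_number(loss_fraction, "loss_fraction", 0, 1, open_upper = TRUE)
  as.integer(ceiling(n_per_group / (1 - loss_fraction)))
}
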