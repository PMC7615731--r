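#' Plot methods for curve objects
#'
#' `autoplot()` methods turn the curve tibbles returned by [power_curve()],
#' [epp_curve()], [width_curve()] and [accept_curve()] into ggplot2 figures;
#' `plot()` on the same objects prints the autoplot. Monte Carlo curves show
#' a 95% band of the simulation error around the estimate.
#'
#' @param object A curve object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name autoplot-bayesnid
NULL

#' @rdname autoplot-bayesnid
#' @importFrom ggplot2 autoplot
#' @export
autoplot.power_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_per_group,
                                       y = .data$joint_power)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$joint_power - 1.96 * .data$mc_se,
                   ymax = .data$joint_power + 1.96 * .data$mc_se),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Patients per group",
                  y = "Predictive power (significant & correct)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-bayesnid
#' @export
autoplot.epp_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_per_group, y = .data$e_n)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$e_n - 1.96 * .data$mc_se,
                   ymax = .data$e_n + 1.96 * .data$mc_se),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Patients per group",
                  y = "Expected posterior probability of non-inferiority") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-bayesnid
#' @export
autoplot.width_curve <- function(object, ...) {
  lev <- if ("level" %in% names(object)) object$level[1] else 0.95
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_per_group,
                                       y = .data$width)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Patients per group",
                  y = sprintf("%g%% credible-interval width (risk difference)",
                              100 * lev)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-bayesnid
#' @export
autoplot.accept_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$probability,
                                       colour = factor(.data$n_per_group))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Non-inferiority threshold (risk difference)",
                  y = "P(risk difference > threshold | data)",
                  colour = "n per group") +
    ggplot2::theme_minimal()
}

#' @param x A curve object.
#' @param y Ignored.
#' @rdname autoplot-bayesnid
#' @export
plot.power_curve <- function(x, y, ...) print(autoplot(x, ...))

#' @rdname autoplot-bayesnid
#' @export
plot.epp_curve <- function(x, y, ...) print(autoplot(x, ...))

#' @rdname autoplot-bayesnid
#' @export
plot.width_curve <- function(x, y, ...) print(autoplot(x, ...))

#' @rdname autoplot-bayesnid
#' @export
plot.accept_curve <- function(x, y, ...) print(autoplot(x, ...))
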