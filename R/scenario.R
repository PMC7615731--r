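#' Design and analysis priors for one trial arm
#'
#' Each arm carries two Beta priors that play different roles. The design
#' prior encodes uncertainty about the arm's true failure probability at the
#' planning stage and is averaged over when computing operating
#' characteristics. The analysis prior is the one the trial's Bayesian
#' analysis will actually use (often flat). They need not agree: a team may
#' borrow external information for planning while keeping the analysis vague.
#'
#' @param design [beta_params] design prior.
#' @param analysis [beta_params] analysis prior; defaults to the design prior.
#' @return An object of class `arm_priors`.
#' @export
arm_priors <- function(design, analysis = design) {
  structure(
    list(design = as_beta_params(design, "design"),
         analysis = as_beta_params(analysis, "analysis")),
    class = "arm_priors"
  )
}

#' Trial scenario for a two-arm non-inferiority design
#'
#' Bundles everything the sample-size methods need: design and analysis
#' priors for both arms, the margin specification, and the two-sided
#' significance level used by the Bayesian decision rule (a "significant"
#' result is posterior P(delta < delta*) > 1 - alpha/2). The outcome is a
#' failure, so higher probabilities are worse and delta = pi1 - pi0 with pi1
#' the experimental arm.
#'
#' @param experimental,control [arm_priors] for the two arms.
#' @param margin A [margin_fixed()] / [margin_uniform()] specification (a
#'   bare number is taken as a fixed margin).
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @return An object of class `trial_scenario`.
#' @examples
#' sc <- trial_scenario(
#'   experimental = arm_priors(design = beta_params(66, 302),
#'                             analysis = beta_params(1, 1)),
#'   control = arm_priors(design = beta_params(66, 302),
#'                        analysis = beta_params(1, 1)),
#'   margin = margin_fixed(0.10)
#' )
#' sc
#' @export
trial_scenario <- function(experimental, control, margin, alpha = 0.05) {
  if (!inherits(experimental, "arm_priors") || !inherits(control, "arm_priors")) {
    abort("`experimental` and `control` must be arm_priors objects.",
          class = "bayesnid_error_domain")
  }
  check_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  structure(
    list(experimental = experimental, control = control,
         margin = as_margin_spec(margin), alpha = as.numeric(alpha)),
    class = "trial_scenario"
  )
}

#' @export
print.trial_scenario <- function(x, ...) {
  fmt <- function(p) sprintf("Beta(%g, %g)", p$alpha, p$beta)
  cat("Non-inferiority trial scenario (binary outcome, risk difference)\n")
  cat(sprintf("  experimental: design %s, analysis %s\n",
              fmt(x$experimental$design), fmt(x$experimental$analysis)))
  cat(sprintf("  control:      design %s, analysis %s\n",
              fmt(x$control$design), fmt(x$control$analysis)))
  if (x$margin$kind == "fixed") {
    cat(sprintf("  margin:       fixed at %g\n", x$margin$value))
  } else {
    cat(sprintf("  margin:       Uniform(%g, %g) prior\n",
                x$margin$lower, x$margin$upper))
  }
  cat(sprintf("  alpha:        %g (two-sided)\n", x$alpha))
  invisible(x)
}

#' Bundled ODYSSEY-style scenarios
#'
#' Ready-made scenarios for the worked example running through the package: a
#' paediatric antiretroviral-therapy trial (ODYSSEY) whose primary outcome is
#' treatment failure by 96 weeks, anticipated at 18% in both arms, with a 10%
#' non-inferiority margin on the risk-difference scale.
#'
#' * `"base"` — Beta(66, 302) design priors on both arms (mean 18%, SD 2%,
#'   effective sample size 368), flat Beta(1, 1) analysis priors, fixed
#'   margin 10%.
#' * `"degenerate-design"` — as base but with near-point-mass Beta(6600,
#'   30200) design priors; reproduces the frequentist operating
#'   characteristics.
#' * `"enthusiastic"` — as base but with Beta(11, 48) analysis priors on both
#'   arms (mean 18%, SD 5%), strongly favouring non-inferiority.
#' * `"skeptical"` — as base but with informative analysis priors favouring
#'   inferiority: control Beta(66, 302) (mean 18%), experimental
#'   Beta(141, 362) (mean 28%).
#' * `"margin-u0812"`, `"margin-u0515"` — as base but with Uniform(8%, 12%)
#'   or Uniform(5%, 15%) priors on the margin.
#'
#' @param name Scenario name; see Details.
#' @return A [trial_scenario].
#' @examples
#' odyssey_scenario("base")
#' @export
odyssey_scenario <- function(name = c("base", "degenerate-design",
                                      "enthusiastic", "skeptical",
                                      "margin-u0812", "margin-u0515")) {
  name <- match.arg(name)
  strong <- beta_params(66, 302)
  flat <- beta_params(1, 1)
  base_margin <- margin_fixed(0.10)
  switch(name,
    "base" = trial_scenario(
      experimental = arm_priors(design = strong, analysis = flat),
      control = arm_priors(design = strong, analysis = flat),
      margin = base_margin
    ),
    "degenerate-design" = trial_scenario(
      experimental = arm_priors(design = beta_params(6600, 30200),
                                analysis = flat),
      control = arm_priors(design = beta_params(6600, 30200),
                           analysis = flat),
      margin = base_margin
    ),
    "enthusiastic" = trial_scenario(
      experimental = arm_priors(design = strong,
                                analysis = beta_params(11, 48)),
      control = arm_priors(design = strong, analysis = beta_params(11, 48)),
      margin = base_margin
    ),
    "skeptical" = trial_scenario(
      experimental = arm_priors(design = strong,
                                analysis = beta_params(141, 362)),
      control = arm_priors(design = strong, analysis = strong),
      margin = base_margin
    ),
    "margin-u0812" = trial_scenario(
      experimental = arm_priors(design = strong, analysis = flat),
      control = arm_priors(design = strong, analysis = flat),
      margin = margin_uniform(0.08, 0.12)
    ),
    "margin-u0515" = trial_scenario(
      experimental = arm_priors(design = strong, analysis = flat),
      control = arm_priors(design = strong, analysis = flat),
      margin = margin_uniform(0.05, 0.15)
    )
  )
}

parse_prior <- function(x, path) {
  bad <- function(msg) {
    abort(sprintf("%s: %s", path, msg), class = "bayesnid_error_config")
  }
  if (!is.list(x)) bad("prior must be a mapping")
  if (!is.null(x$alpha) || !is.null(x$beta)) {
    if (is.null(x$alpha) || is.null(x$beta)) {
      bad("give both `alpha` and `beta`")
    }
    return(beta_params(x$alpha, x$beta))
  }
  if (!is.null(x$mean) || !is.null(x$sd)) {
    if (is.null(x$mean) || is.null(x$sd)) bad("give both `mean` and `sd`")
    round_params <- isTRUE(x$round_params) || isTRUE(x$round)
    out <- tryCatch(
      beta_from_moments(x$mean, x$sd, round_params = round_params),
      error = function(e) bad(conditionMessage(e))
    )
    return(out)
  }
  bad("prior needs either {alpha, beta} or {mean, sd}")
}

parse_arm <- function(x, path) {
  if (!is.list(x) || is.null(x$design)) {
    abort(sprintf("%s: arm needs at least a `design` prior", path),
          class = "bayesnid_error_config")
  }
  design <- parse_prior(x$design, paste0(path, "$design"))
  analysis <- if (is.null(x$analysis)) design else {
    parse_prior(x$analysis, paste0(path, "$analysis"))
  }
  arm_priors(design = design, analysis = analysis)
}

parse_margin <- function(x, path) {
  bad <- function(msg) {
    abort(sprintf("%s: %s", path, msg), class = "bayesnid_error_config")
  }
  if (is.numeric(x) && length(x) == 1L) return(margin_fixed(x))
  if (!is.list(x)) bad("margin must be a number or a mapping")
  if (!is.null(x$fixed)) return(margin_fixed(x$fixed))
  if (!is.null(x$uniform)) {
    u <- unlist(x$uniform)
    if (length(u) != 2L) bad("`uniform` needs two bounds")
    return(margin_uniform(u[[1]], u[[2]]))
  }
  if (!is.null(x$lower) && !is.null(x$upper)) {
    return(margin_uniform(x$lower, x$upper))
  }
  bad("margin needs `fixed`, `uniform: [lo, hi]`, or `lower`/`upper`")
}

#' Load a trial scenario from a configuration file or fixture name
#'
#' Reads a YAML or JSON scenario description. Priors can be given either as
#' `{alpha, beta}` shape parameters or as `{mean, sd}` pairs (moment-matched
#' on load; add `round_params: true` to round the matched parameters to
#' integers). The margin is a single fixed value or `{uniform: [lo, hi]}`.
#' Probabilities in files are always decimals (write `0.10`, not `10%`).
#' Alternatively, pass one of the bundled fixture names accepted by
#' [odyssey_scenario()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or a fixture name.
#' @return A [trial_scenario].
#' @examples
#' load_scenario("odyssey-base")
#' @export
load_scenario <- function(path) {
  fixtures <- c("base", "degenerate-design", "enthusiastic", "skeptical",
                "margin-u0812", "margin-u0515")
  if (is.character(path) && length(path) == 1L && !file.exists(path)) {
    name <- sub("^odyssey-", "", path)
    if (name %in% fixtures) return(odyssey_scenario(name))
    if (!grepl("[./\\\\]", path)) {
      abort(sprintf(
        "Unknown scenario fixture '%s'. Available: %s.",
        path, paste0("odyssey-", fixtures, collapse = ", ")
      ), class = "bayesnid_error_config")
    }
    abort(sprintf("Scenario file '%s' does not exist.", path),
          class = "bayesnid_error_config")
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("experimental", "control", "margin")) {
    if (is.null(cfg[[field]])) {
      abort(sprintf("scenario$%s is missing", field),
            class = "bayesnid_error_config")
    }
  }
  trial_scenario(
    experimental = parse_arm(cfg$experimental, "scenario$experimental"),
    control = parse_arm(cfg$control, "scenario$control"),
    margin = parse_margin(cfg$margin, "scenario$margin"),
    alpha = cfg$alpha %||% 0.05
  )
}
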