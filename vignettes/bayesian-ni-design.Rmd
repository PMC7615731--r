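---
title: "Bayesian sample size determination for non-inferiority trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian sample size determination for non-inferiority trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesnid)
```

## The design problem

A non-inferiority trial asks whether a new treatment is *not unacceptably
worse* than the standard of care on efficacy, usually because it offers
other benefits (safety, cost, convenience). With a binary failure outcome,
the effect is the risk difference $\delta = \pi_1 - \pi_0$ between the
experimental and control failure probabilities, and the null hypothesis is
$\delta \ge \delta^*$ for a positive margin $\delta^*$. When the planned
primary analysis is Bayesian, a *significant result* means the posterior
probability of non-inferiority exceeds a threshold,
$P(\delta < \delta^* \mid \text{data}) > 1 - \alpha/2$, and the sample size
should be chosen under the same model.

`bayesnid` implements three Bayesian routes to a sample size and the
standard frequentist comparator. All of them build on one conjugate model:
each arm's failure probability carries a Beta distribution, data are
binomial with $n$ patients per arm (equal allocation), and each arm's
posterior is again Beta.

Two distinct prior roles are kept separate throughout. The **analysis
prior** is the one the trial's Bayesian analysis will actually use — often
flat $\mathrm{Beta}(1,1)$, sometimes informative. The **design prior**
encodes planning-stage uncertainty about the true event rates and is only
ever averaged over; it never touches the analysis. A team may happily
borrow external information for planning while keeping the analysis vague,
so `arm_priors()` holds both per arm.

## The normal approximation

Every probability statement about $\delta$ goes through a normal
approximation: given Beta distributions for the two arms,

$$\delta \sim N\!\big(E(\pi_1) - E(\pi_0),\; \mathrm{Var}(\pi_1) +
\mathrm{Var}(\pi_0)\big),$$

with exact Beta moments. This is the package's default computational path
everywhere — the significance indicator of the power engine, the expected
posterior probability, the credible-interval width and the ACCEPT curves —
because it makes the precision quantities fully analytic and keeps all four
approaches mutually consistent. The exact-model alternative (sampling the
two Betas directly) is retained as a verification method:
`prior_prob_ni(..., method = "mc")` and the Monte Carlo quantile oracle in
the test suite check the approximation from outside. For flat priors and no
data — the least favourable case, where the Beta distributions are as
non-normal as they get here — the approximation error of
$P(\delta < 0.10)$ is below 0.002; with effective sample sizes of 50 or
more per arm the two routes agree to within Monte Carlo error.

## The three Bayesian approaches

**Predictive power** (`predictive_power()`, `find_n_for_power()`). Each
Monte Carlo replicate draws true rates $\pi_1, \pi_0$ from the design
priors, a margin $\delta^*$ from its specification, binomial data, and then
judges the resulting analysis-prior posterior: did it declare
non-inferiority, and was that declaration true ($\pi_1 - \pi_0 <
\delta^*$)? The joint frequency of *significant and correct* is the
predictive power. We report the unconditional significance probability and
the significant-but-inferior slice as well; the three satisfy an exact
accounting identity on every run, and with a design prior supportive of
non-inferiority the wrong-sign slice is negligible. With a margin prior,
the same $\delta^*$ draw feeds both indicators, so the result reads as the
expected proportion of experts convinced by the final analysis.

**Expected posterior probability** (`expected_posterior_prob()`,
`find_n_for_epp()`). The same simulation layout, but each replicate records
the posterior probability of non-inferiority itself, and the criterion is
its mean $e_n$. Controlling a mean rather than a tail makes this criterion
much cheaper in patients; at $n = 0$ the data step vanishes and, with a
fixed margin, the value collapses deterministically to the analysis-prior
probability of non-inferiority — an informative prior can meet the target
with no patients at all, which is reported honestly as $n = 0$.

**Precision** (`ci_width()`, `n_for_width()`, `accept_prob()`,
`accept_curve()`). Deterministic: the credible-interval width for $\delta$
follows in closed form from the analysis priors updated with *assumed*
counts $np$ per arm. Design priors play no role here, which is why the
`precision_inputs()` constructor takes the assumed observed proportions
`p1_assumed`, `p0_assumed` as **required** arguments rather than defaulting
to any prior mean: with informative analysis priors the prior means are the
natural choice, but with flat priors (mean 50%) the only sensible choice is
the anticipated event rate, and a silent default would quietly do the wrong
thing for one of the two. `precision_inputs_from_scenario()` makes the
choice explicit (`p_from = "analysis"`, `"design"` or `"value"`). ACCEPT
curves plot $P(\delta > t \mid \text{data})$ over thresholds $t$: monotone
non-increasing, exactly $0.5$ at the posterior mean, and steeper — hence
more informative — as $n$ grows.

**Frequentist comparator** (`freq_required_n()`, `freq_power()`). The
standard formula
$n = (z_{\alpha/2} + z_\beta)^2\,[\pi_1(1-\pi_1) + \pi_0(1-\pi_0)] /
(\pi_1 - \pi_0 - \delta^*)^2$. Rounding is to the *nearest* integer, not
the ceiling: across the reference margins 5–15% this reproduces the
published per-group set $\{1241, 551, 310, 199, 138\}$ exactly, which
ceiling (311, 552) or floor (198) would not.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `alpha` | 0.05 | two-sided level; the Bayesian bar is $1-\alpha/2$ |
| `margin` | — | risk-difference scale; fixed value or uniform bounds |
| `reps` | $10^5$ | MC standard error $\approx 0.0012$ on a probability near 0.85 |
| `step` | 10 | search grid; published reference sizes are multiples of 10 |
| `n_min`, `n_max` | 10 (power) / 0 (expectation), 2000 | search range |
| `level` | 0.95 | credibility level for widths |
| `seed` | drawn & recorded | every stochastic result carries `(reps, seed)` |

## Numerical and design choices

**Common random numbers and the boundary rule.** Within a grid search the
same seed is reused at every $n$, so the truth draws $(\pi_1, \pi_0,
\delta^*)$ are identical across grid points and the estimated curve is
monotone in $n$ up to the binomial layer. The draw order is fixed
(rates, margin, data), and the margin draw consumes the random stream even
when the margin is fixed, so a degenerate $\mathrm{Uniform}(d, d)$ margin
prior reproduces a fixed-margin run bit for bit. The reference designs sit
essentially *on* their targets (joint power within one MC standard error of
0.90 at the selected $n$), where a naive scan at $10^5$ replicates would
flip between adjacent grid points from seed to seed; when a decision is
that close, the two bracketing grid points are re-estimated once with
tenfold replicates before committing. This keeps the returned $n$ stable to
within one grid step.

**Moment matching.** `beta_from_moments()` keeps real-valued shape
parameters by default and rounds them to integers only on request, because
elicited priors are conventionally quoted with integer parameters (mean
18%, SD 2% is quoted as $\mathrm{Beta}(66, 302)$) while internal
computation has no reason to round. One wrinkle worth knowing: the
conventional "mean 18%, SD 5%" enthusiasm prior is quoted as
$\mathrm{Beta}(11, 48)$, whose actual mean is 18.6%; exact matching gives
$\mathrm{Beta}(10.45, 47.59)$. The bundled enthusiastic scenario uses the
quoted $\mathrm{Beta}(11, 48)$.

**Width search.** `n_for_width()` compares the *unrounded* width against
the target. Published tables often quote widths rounded to the whole
percent, which can make a quoted sample size one grid step smaller than
the strict criterion returns (width 0.1004 at $n = 450$ "is" 10%); the
package does not emulate that rounding, and its tests pin widths at given
$n$ rather than the searched $n$ where the conventions differ.

**Degenerate and extreme inputs.** Zero-data updates are identities;
infeasible designs (margin not exceeding the expected risk difference) and
impossible moment pairs ($sd^2 \ge m(1-m)$) raise classed errors rather
than returning nonsense; searches that exhaust their grid raise a
`not_found` error carrying the best attempt.

## What the bundled scenarios emulate

The `odyssey_scenario()` fixtures describe a realistic paediatric HIV
treatment trial: 18% anticipated failure in both arms, a 10% margin,
strong design priors worth 368 patients per arm (mean 18%, SD 2%), and
analysis priors ranging from flat through enthusiastic
($\mathrm{Beta}(11,48)$, prior probability of non-inferiority 92%) to
skeptical (experimental $\mathrm{Beta}(141, 362)$, mean 28%). These are
*design-stage* constructs: simulated trials draw their truths from the
stated design priors and their data from exact binomial sampling. Real
trials add what this model omits — loss to follow-up (only the
`adjust_for_attrition()` inflation helper addresses it), non-adherence,
clustered or time-varying event risks, interim looks, and unequal
allocation. Passing tests therefore certify the operating characteristics
*of the stated model*, not robustness to those departures.

## Problem sizes

The test suite runs property checks at $10^4$–$2\times10^4$ replicates and
the headline reproductions at $10^5$ ($10^6$ for the prior-probability
check); the acceptance script uses $10^5$ replicates per grid point and
$10^6$ for the prior probability. At these sizes the whole suite runs in
well under a minute on a single core, with every Monte Carlo standard
error at or below 0.0016.

## Known limitations

* Risk difference only; no odds-ratio or rate-ratio margins.
* Conjugate Beta priors on the two arms only — priors placed directly on
  $\delta$ (or on $\delta$ and $\pi_0$) would require full simulation and
  are out of scope, as are design-prior-averaged precision curves.
* Equal allocation per arm.
* The normal approximation is used for decisions as well as summaries; for
  very small $n$ with extreme analysis priors the exact-Beta tail can
  differ by a few thousandths (the MC verification path quantifies this).
* The expected-posterior criterion controls only the mean of the posterior
  probability; two designs with equal $e_n$ can spread that probability
  very differently, so it should not be chosen merely because it yields
  smaller trials.
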