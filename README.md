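# bayesnid

Bayesian sample size determination for two-arm non-inferiority trials with
binary outcomes.

When the primary analysis of a non-inferiority trial will be Bayesian, the
sample size should be chosen under the same framework, so that uncertainty
in the assumed event rates — treated as fixed and known by the standard
frequentist formula — is properly priced into the design. `bayesnid`
implements three Bayesian approaches side by side with the frequentist
comparator, for trials comparing an experimental arm against control on the
risk-difference scale:

* **Predictive power.** The probability, averaged over *design priors* for
  the two arms' failure probabilities, that the trial will yield a
  significant Bayesian result **and** that this conclusion is correct.
* **Expected posterior probability.** The mean, over the predictive
  distribution of the data, of the posterior probability of
  non-inferiority; controls the expectation of the evidence rather than the
  chance of clearing a high bar, and so leads to smaller trials.
* **Precision.** The closed-form width of the credible interval for the
  risk difference as a function of sample size, plus ACCEPT curves
  (posterior probability that the risk difference exceeds a threshold,
  across thresholds).

It is aimed at trial statisticians designing (or reviewing) non-inferiority
trials, particularly in settings like paediatric or rare-disease research
where informative priors and honest accounting of design uncertainty
matter most.

## The model

Failure probabilities π₁ (experimental) and π₀ (control) carry conjugate
Beta priors, separately for design and analysis roles:

    π₁ ~ Beta(a₁, b₁),  π₀ ~ Beta(a₀, b₀),
    r₁ ~ Bin(n, π₁),    r₀ ~ Bin(n, π₀)   (n per arm, equal allocation)

so each arm's posterior is again Beta. The treatment effect is the risk
difference δ = π₁ − π₀ with a positive margin δ\*: non-inferiority means
δ < δ\*, and a *significant Bayesian result* is
P(δ < δ\* | data) > 1 − α/2. The posterior of δ is approximated as normal
with mean E(π₁|r₁) − E(π₀|r₀) and variance Var(π₁|r₁) + Var(π₀|r₀), which
makes the credible-interval width analytic:

    width(n) = 2 z_{α/2} √( Σ_arms (a + n p)(b + n(1−p)) / ((a+b+n)²(a+b+n+1)) )

with p the assumed observed failure proportion in each arm. The margin δ\*
may be fixed or given a uniform prior representing variability of expert
opinion; predictive power is then the expected proportion of experts
convinced by the final analysis.

## Worked example

A paediatric HIV treatment trial anticipates 18% failure in both arms and a
10% non-inferiority margin. The frequentist formula gives 310 per group for
90% power; the bundled `odyssey_scenario("base")` adds Beta(66, 302) design
priors (mean 18%, SD 2%, worth 368 patients of information) and flat
Beta(1, 1) analysis priors:

```r
library(bayesnid)

freq_required_n(0.18, 0.18, margin = 0.10)
#> [1] 310

sc <- odyssey_scenario("base")
predictive_power(sc, n_per_group = 310, reps = 1e5, seed = 2026)
#> Predictive power at n = 310 per group
#>   joint (significant & correct): 0.8305 (MC se 0.0012)
#>   unconditional significance:    0.8305
#>   significant but inferior:      0
#>   reps 100,000, seed 2026
```

Admitting 2% SD of uncertainty in the assumed failure proportions drops the
power of the 310-per-group design from 90% to about 83%. Restoring 90%
predictive power needs a bigger trial, while targeting the expected
posterior probability needs a much smaller one:

```r
find_n_for_power(sc, target = 0.90, seed = 2026)
#> Smallest n per group with predictive power >= 0.9: 440
#>   estimate 0.9038 (MC se 0.00093, 100,000 reps), grid step 10, seed 2026

find_n_for_epp(sc, target = 0.90, seed = 2026)
#> Smallest n per group with expected posterior probability >= 0.9: 110
#>   estimate 0.9013 (MC se 0.00051, 100,000 reps), grid step 10, seed 2026
```

The precision route is deterministic — with flat analysis priors and 18%
observed failure in both arms, a 0.10-wide 95% credible interval needs
about 460 per group:

```r
flat <- precision_inputs(beta_params(1, 1), beta_params(1, 1), 0.18, 0.18)
n_for_width(flat, target_width = 0.10)
#> # A tibble: 1 × 2
#>   n_per_group  width
#>         <int>  <dbl>
#> 1         460 0.0993
```

Curve functions (`power_curve()`, `epp_curve()`, `width_curve()`,
`accept_curve()`) return tibbles with `autoplot()` methods; fitted results
have broom-style `tidy()` and `glance()` methods. Scenarios can be loaded
from YAML/JSON via `load_scenario()` (see `inst/extdata/odyssey-base.yaml`),
and `inst/cli/bayesnid` is a thin command-line front end over the same
functions (`freq-n`, `power`, `power-n`, `epp`, `epp-n`, `width`,
`width-n`, `accept`, `report`).

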