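---
title: "Bayesian modelling of resource use, costs and QALYs in trial-based economic evaluations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian modelling of resource use, costs and QALYs in trial-based economic evaluations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

## The problem

Trial-based cost-utility analyses compare two arms on mean quality-adjusted
life-years (QALYs) and mean total costs. Neither quantity is observed
directly: utilities come from preference-scored questionnaires (EQ-5D-type
instruments) at a handful of visits, and costs are assembled by pricing
self-reported health care resource use (HRU) — counts of contacts with each
of `K` services — collected by lengthy inventories such as the CSRI. Those
inventories suffer *item* nonresponse (some service questions skipped) on
top of the *unit* nonresponse (whole questionnaire skipped) familiar from
HRQoL instruments. The routine work-around is to impute unanswered service
items as zero use before costing. A zero is data, not absence of data: when
the unobserved true use is positive, zero imputation drags cost estimates
down and understates uncertainty, and it does so more aggressively the more
aggregated the analysis model is (totals hide how many items were guessed).

`trialcea` implements a Bayesian alternative: model the data at the level
where the missingness actually occurs and let MCMC treat each missing
outcome as an unknown, so that missingness uncertainty propagates into the
cost-effectiveness results. Three nested strategies are provided, together
with the ad hoc zero-imputation comparators, so an analyst can see on their
own data how much the conclusions are driven by the handling of
nonresponse.

## Data model and derived quantities

The canonical container (`trial_data()`) is a long tibble: one row per
individual and visit, with `utility`, one column per catalogued service,
and explicit `NA` for every unanswered item. Baseline is `time = 0`;
follow-up visit `j` covers a fraction `delta[j]` of the time unit
(`schedule()`, default 0.5/0.5 for a 6/12-month design on one year).
Derivations are strict about missingness:

* QALY by the trapezoid rule,
  `e_i = sum_j (u_ij + u_i,j-1) delta_j / 2`, missing whenever any utility
  in the trajectory is missing;
* per-time cost `c_ij = sum_k p_k HRU_ijk`, missing as soon as one item is
  missing; total cost `tc_i = sum_{j>=1} c_ij` over the follow-up period
  (baseline costs are computed as a candidate covariate but never enter the
  total, which covers the trial's follow-up horizon).

`apply_strategy()` implements the three preprocessing attitudes. `ALL`
touches nothing. `IMP-H` zeroes missing service items at visits where at
least one item was answered — the classic "they did not mention it, so
they did not use it" — while a fully skipped inventory still produces a
missing per-time cost. `IMP-HC` additionally zeroes those remaining
missing per-time costs. Distinguishing the two levels matters: it is
exactly the difference between assuming *answers* and assuming *whole
questionnaires*, and the two comparators bracket common practice. (Under a
reading where `IMP-H` zeroed every missing item including whole-unit
nonresponse, `IMP-HC` would be indistinguishable from it; the two-level
definition is the one that keeps all three comparators meaningful.)

## The three model strategies

All models are fitted per arm by MCMC (JAGS via `rjags`), with missing
outcomes declared as stochastic nodes — the Bayesian analogue of full
information analysis under missingness-at-random (MAR). Marginal means are
recovered per draw by averaging individual predicted means over the
sample, so every downstream quantity is a deterministic transformation of
the joint posterior.

**S1 — totals.** A marginal normal model for the QALY, adjusted for
baseline utility (itself given a marginal normal model, so missing
baselines are no obstacle), and a conditional gamma model with log link
for the total cost given the QALY. This factorisation of the joint
distribution captures cost–effectiveness correlation while keeping only
two likelihoods.

**S2 — per-time costs and utilities.** For each follow-up visit, utility
given previous utility and the contemporaneous per-time cost (normal,
identity link), and per-time cost given the previous visit's utility and
cost (gamma, log link); baseline utility and cost are modelled marginally.
`mu_e` is assembled from the per-time mean utilities by the same trapezoid
rule, `mu_tc` by summing per-time mean costs.

**S3 — per-service hurdles.** Resource-use variables carry large spikes of
*structural zeros*: individuals who report zero use of a service at every
visit. Each service gets a two-part model: a Bernoulli indicator `d_ik`
of a structural-zero profile, with logistic regression on centred baseline
utility, and a normal model for usage among the remaining individuals with
conditioning on the previous visit's utility and usage. Per draw, the
marginal usage rate combines exactly as

```
mu_hru[j,k] = (1 - pi_k) * mu_pos[j,k]
```

and is priced and summed into `mu_tc`. Individuals whose observed profile
is all-zero but incomplete have a *latent* indicator: in the sampler the
point mass at zero is represented by a very-high-precision normal spike
(sd 0.001 contacts), so their observed zeros update `d_ik` while their
missing items are sampled from whichever component the current `d_ik`
selects. Individuals with a complete all-zero profile enter only the
logistic component (their continuous likelihood would be an uninformative
constant), which also keeps the graph small.

Modelling choices the data could not settle were resolved as follows.

* *Covariates.* Baseline utility is the single adjustment everywhere — the
  minimal defensible set for a randomised comparison. Baseline
  service-specific use is deliberately **not** added to the hurdle
  logistic: a positive baseline count implies `d_ik = 0` deterministically
  (structural zero is defined over all visits, baseline included), so that
  covariate quasi-separates the indicator and only destabilises mixing.
* *S3 utility conditioning.* The utility module in S3 conditions on the
  previous utility only. Conditioning on the contemporaneous use of all
  `K` services would pull every structural-zero usage node into the
  utility graph for a second-order gain; S2 retains the
  contemporaneous-cost covariate, so the alternative ordering remains
  available one level up.
* *Arms.* Fitted separately. Nothing is shared between arms, which is the
  cleanest reading of an arm-stratified estimand; it also halves each
  model graph.
* *Likelihood families.* Normal for utilities and QALYs, gamma for costs,
  normal for nonzero usage. Lognormal and normal cost alternatives are
  available in S1 (and a normal alternative in S2) so that the choice can
  be audited by WAIC (`compute_waic()` on the stored pointwise
  log-likelihoods) and posterior predictive checks; count families for
  usage (Poisson, negative binomial) are not provided because the data
  model admits non-integer usage.

## Priors, scaling and numerical conventions

Priors are weakly informative on deliberately standardised scales:
Normal(0, 10^2) on every regression coefficient (link scale),
half-Normal(0, 10) on normal-likelihood standard deviations,
Exponential(0.1) on gamma shapes. To make one prior scale serve utilities
(≈0.5), usage (≈0–10 contacts) and costs (≈10^3 currency units), costs are
rescaled to thousands internally and rescaled back in all reported draws;
lagged and contemporaneous covariates are centred at their observed means,
which markedly improves mixing of the conditional models. Observed zero
costs are offset by 0.01 currency units before a gamma or lognormal fit
(the count of offsets is reported by `glance()`); gamma support excludes
zero and the offset is far below the scale of any priced contact.
Draws of the structural-zero probability live in (0, 1) by construction
(inverse-logit); the hurdle identity above holds exactly per draw, not in
expectation.

Default MCMC is 2 chains × 20,000 iterations with 10,000 burn-in.
Convergence is summarised by split R-hat (each chain halved before the
potential-scale-reduction computation) and effective sample size per
monitored parameter (`diagnose()`); a fit is flagged converged when every
finite R-hat is below 1.05, with constant-chain parameters reported as
degenerate rather than failing the flag.

## The synthetic trial generator

Because real trial datasets of this kind are rarely shareable, the package
ships a generator (`simulate_trial()`) whose default configuration
(`default_study_config()`) emulates a 244-participant (136/108) two-arm
community trial with nine services, structural-zero probabilities of 0.15,
0.65, 0.77, 0.14, 0.19, 0.80, 0.004, 0.22 and 0.35, baseline + 6/12-month
visits, and unit plus item nonresponse at the moderate follow-up rates
typical of self-reported instruments (unit ~3–8%, item ~2.5–3%, baseline
fully observed). Nonzero usage is zero-truncated normal linked across
visits by a Gaussian AR(1) copula (autocorrelation 0.5); utilities are
AR(1) normal (0.6) clamped at the EQ-5D ceiling of 1; missingness log-odds
decrease by 1 per unit of centred baseline utility (sicker participants
respond less — a MAR mechanism, since baseline is always observed in the
generated data). Usage means (1.5–4 contacts per half-year, intervention
15% lower at follow-up) and utility trajectories (control 0.45→0.50,
intervention 0.45→0.62) were fixed once to give QALY and annual-cost
scales typical of such trials. The generator returns the complete
pre-missingness dataset and its realized sample means as ground truth; the
hurdle identity holds in that ground truth exactly as a sample identity.

What the generator does *not* emulate: integer-valued counts (usage is
continuous), MNAR mechanisms, within-visit correlation between services
beyond what baseline utility induces, and time-varying prices. Passing
recovery tests on these data therefore demonstrates correctness of the
machinery under a MAR, continuous-usage world — not robustness to
informative missingness, which is out of scope by design.

## Economic evaluation layer

`increments()` pairs the arm-level draws and forms `delta_e`, `delta_tc`
oriented *intervention minus control*, so that a positive `delta_e`
favours the intervention and the south-east quadrant of the
cost-effectiveness plane (cheaper and more effective) is the favourable
one; the orientation is recorded in the pipeline metadata. `icer()` is the
ratio of posterior mean increments. `ceac()` evaluates
`P(k * delta_e - delta_tc > 0)` on a willingness-to-pay grid (default £0
to £10,000 per QALY in steps of 100, the range conventional for these
decision problems); the net benefit must be *strictly* positive, so a draw
exactly on the threshold line never counts as cost-effective, and
`cep_table(..., k_line = 25000)` uses the same convention for its
sustainability area. Both objects have `autoplot()` methods.

## Problem sizes used in the test suite

The packaged experiments run at deliberately reduced but statistically
meaningful sizes: recovery experiments use the full 244-participant design
with 2 chains × 2,000 iterations (burn-in 1,000) over 20 seeded
replications per strategy; the end-to-end demonstration run uses 2 × 6,000
(burn-in 1,000). Production analyses should use the 2 × 20,000 default.
Coverage is assessed against the realized complete-data means, which is
the estimand the fitted sample actually carries; population-parameter
coverage at these sample sizes would differ only by the usual first-order
sampling noise.

## Known limitations

* MAR is assumed throughout; selection or pattern-mixture analyses for
  MNAR sensitivity are not implemented.
* The hurdle's continuous component is normal; strongly skewed positive
  usage within users would call for a different family, which the WAIC
  machinery can compare but the S3 fitter does not currently offer.
* Structural-zero status is a per-individual, all-visits property. A
  service used in some periods and structurally absent in others is not
  representable.
* The spike representation of the point mass is an approximation with sd
  0.001 contacts; it is exact for all practical purposes but a truly
  discrete mixture sampler would avoid the constant.
* Costs and QALYs are undiscounted (single-year horizon).
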