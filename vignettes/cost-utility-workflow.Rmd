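---
title: "Within-trial cost-utility analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Within-trial cost-utility analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

trialcea implements a within-trial cost-utility analysis over a 12-month
horizon for a two-arm randomised trial: EQ-5D-5L responses are scored to
utilities against a pluggable value set, QALYs are computed by area under
the utility curve, participant-level costs are built from resource-use
counts, study-drug exposure, category-costed medications and out-of-pocket
expenses, missing data are handled by multiple imputation with chained
equations and predictive mean matching, adjusted incremental costs and
QALYs come from seemingly unrelated regression with bias-corrected and
accelerated bootstrap intervals, and the decision layer produces ICERs with
cost-effectiveness-plane quadrant semantics, net monetary benefit and
acceptability curves. A calibrated synthetic-trial generator stands in for
patient-level trial data, which are typically not shareable.

This vignette records the model, its assumptions, and the design decisions
that were genuinely open, in the order the pipeline runs.

## Utility scoring

The EQ-5D-5L describes health on five dimensions (mobility, self-care,
usual activities, pain/discomfort, anxiety/depression), each at five
levels. A value set (tariff) maps each of the $5^5 = 3125$ profiles to a
utility anchored at 1 for full health (state 11111) and 0 for dead;
negative values are states valued worse than dead and are **not floored**.
`score_eq5d()` scores a profile only when all five dimensions are present —
there is no partial scoring; a missing dimension yields a missing utility,
which the imputation stage later handles.

Tariffs are data, not code. `load_tariff()` accepts an exhaustive
`state,utility` table or an additive `term,value` decrement table
(per-dimension level decrements plus an optional constant decrement for any
problem). The packaged default is a **synthetic** decrement tariff with the
qualitative structure of crosswalk-style value sets (anchor 1.0, floor
$-0.59$); it is a stand-in, clearly labelled, because published value sets
are licensed artefacts that the analysis treats as pluggable inputs. Tests
use a linear toy tariff ($U = 1 - 0.05\sum_d(\ell_d - 1)$) whose closed
form makes expected values trivially checkable, never the shipped
coefficients.

## QALYs

With utilities $u_0, u_6, u_{12}$ at the protocol visits (0, 0.5, 1.0
years), the trapezoid rule gives

$$\mathrm{QALY} = \tfrac12\frac{u_0+u_6}{2} + \tfrac12\frac{u_6+u_{12}}{2}
  = 0.25\,u_0 + 0.5\,u_6 + 0.25\,u_{12}.$$

Two deliberate choices: visit times are fixed at the protocol schedule
(actual questionnaire-return dates are not modelled), and baseline-utility
imbalance is handled as a **covariate in the outcome regression**, not by
subtracting the baseline from the area — covariate adjustment is the
standard correction for baseline imbalance in QALY analyses and composes
cleanly with the other adjustment covariates.

Hand pain on the numerical rating scale is treated as 0 (no pain) to 10
(worst pain); the instrument is occasionally described as 0–11, but the
eleven-*point* 0–10 convention is adopted throughout. `pain_change()` is
the 6-month-minus-baseline difference, negative meaning relief.

## Costing

Costs are UK pounds sterling at 2015 prices; with a 12-month horizon no
discounting is applied. Three rules matter:

* **Missing is not zero.** Resource counts are multiplied by unit costs
  item by item; a blank count gives a missing item cost, and any missing
  component makes the visit's healthcare subtotal missing. This mirrors
  questionnaires where free-text "other" slots are often left blank, and
  it is what makes complete economic profiles scarce (roughly 30% of
  participants under the default missingness pattern).
* **Study-drug costing** is anchored on the 200 mg / 60-tablet pack price
  (£5.15): daily cost is `(dose/200) * 5.15/60`, a 300 mg dose is costed
  as 1.5 tablets/day (alternating 200/400 days), the allocated dose is
  assumed constant, and exposure is truncated at the recorded stop day.
  Placebo tablets are a research cost: the control arm must carry zero
  drug cost, and a control row with drug exposure is a validation error.
* **Medications** recorded on investigator forms (3, 6, 9, 12 months) are
  costed by category averages, not micro-costed per product. The packaged
  category averages are placeholders flagged uncalibrated, since no
  published per-category averages exist to ship.

The NHS/PSS perspective totals healthcare + drug + medications over the two
follow-up reporting periods; the societal perspective adds participant
out-of-pocket spend (over-the-counter medication, childcare, travel).
Possible double counting between over-the-counter spend and the medication
categories under the societal perspective is a documented property of the
design, accepted rather than corrected. Baseline-visit resource costs cover
pre-trial use and enter only as the baseline-cost covariate.

## Missing data

The base case is intention-to-treat with multiple imputation by chained
equations and predictive mean matching (PMM), assuming data are missing at
random. Design decisions, all config-exposed:

* **Component-level imputation.** Utilities, per-visit healthcare costs,
  per-visit expenses and follow-up pain are imputed per timepoint, and
  QALYs/total costs are aggregated *afterwards*. Imputing components
  preserves the AUC weighting and the costing structure; whether to impute
  components or aggregates is not settled by any published description, so
  the component route was chosen and is stated here.
* **Defaults m = 20, 10 cycles, k = 5 donors** follow common practice; no
  published values exist for these in the emulated analysis.
* The imputation model uses the clinical-analysis covariates (baseline
  pain, concomitant analgesic use, grip strength, BMI, age, gender) plus
  the arm indicator; baseline cost and baseline utility participate as
  chained variables that predict each other.
* **PMM mechanics**: Bayesian parameter draw per conditional model, type-1
  matching, k nearest donors on the predicted mean, equidistant donors
  broken uniformly at random (the donor window is extended over runs of
  tied predictions so ties are never cut off). Every imputed value is an
  observed value of the same variable, which keeps semicontinuous costs
  on-support (zeros stay plausible).
* Rubin's rules pool per-imputation estimates; the Barnard–Rubin
  small-sample degrees of freedom are used when a complete-data df is
  supplied.

## Estimation

Incremental cost and incremental QALYs are the arm coefficients of a
two-equation seemingly unrelated regression (total cost; QALY), each
adjusted for baseline utility, baseline cost and the clinical covariates.
Numerically the FGLS step is solved as a whitened least-squares problem
(Cholesky of $\Sigma^{-1}$ applied to the stacked system, then QR), because
the naive normal-equations solve is ill-conditioned when the cost and QALY
residual scales differ by orders of magnitude — which they always do. With
identical regressors in both equations FGLS coincides with per-equation
least squares (the classical identity, asserted to 1e-8 in tests), but the
joint covariance still carries the cross-equation residual correlation.

Uncertainty is nonparametric bootstrap over participants, stratified by arm
so every replicate keeps the randomised arm sizes (conditioning on the
design). Three open questions were decided as follows:

* **Combining MI with the bootstrap.** Default is *boot-then-impute*:
  resample participants, then run a single stochastic imputation inside
  each replicate, so imputation uncertainty propagates into the CE-plane
  cloud and the CEAC. The alternative (*impute-then-boot*, bootstrap each
  completed dataset and pool clouds) is config-selectable.
* **BCa constants.** $z_0$ is the normal quantile of the fraction of
  replicates below the point estimate; the acceleration $a$ comes from a
  **leave-one-participant-out** jackknife (matching the resampling unit).
  For the base case the jackknife statistic uses a fixed-seed single
  imputation so it is deterministic. Interval endpoints are order
  statistics of the cloud (inverse ECDF), so percentile endpoints are
  exact ranks and BCa reduces to percentile when $z_0 = 0, a = 0$.
* **Degenerate clouds** (all replicates identical) give the degenerate
  interval $[v, v]$; a point estimate outside the cloud support clamps
  $z_0$ with a warning.

The repeated pain score uses GLS with an exchangeable (compound-symmetry)
covariance via `nlme::gls`, with a separate arm effect per visit. In
balanced panels the arm effect coincides with OLS — duplicating every
observation leaves it unchanged, which is one of the oracle tests. When the
6-month arm effect shows no pain reduction, the result carries an explicit
flag that a cost-per-unit-of-pain-reduction ratio is not meaningful rather
than reporting a cost per unit of *added* pain.

## Decision analysis

For incremental cost $\Delta C$ and effect $\Delta E$:
$\mathrm{ICER} = \Delta C / \Delta E$, with quadrant semantics — SE
(cheaper, more effective) is dominant and SW is reported as a positive
"cost saved per QALY lost". Net monetary benefit is
$\lambda \Delta E - \Delta C$; the QALY-denominated variant
$\Delta E - \Delta C/\lambda$ is exposed under a separate name. The CEAC at
$\lambda$ is the fraction of bootstrap replicates with strictly positive
net benefit. Boundary conventions are deterministic and conservative:
$\Delta E = 0$ counts as a gain and $\Delta C = 0$ as a cost increase for
quadrant assignment, and a net benefit of exactly zero is *not*
cost-effective. Under symmetric preferences for losses and gains, a
QALY-losing replicate is cost-effective iff its saving per QALY lost
exceeds $\lambda$, which coincides with positive net benefit — the package
tests this equivalence replicate by replicate. The default threshold grid
is £0–50,000 in £500 steps, covering both conventional UK anchors (£20,000
and £30,000 per QALY).

## The synthetic-trial generator

`generate_trial()` emulates the statistical structure the analysis
assumes, with defaults fixed at the emulated study conditions: 124
participants per arm, baseline utility mean 0.613 (SD 0.178) in both arms,
follow-up utility means ~0.64, right-skewed resource-use (count SDs above
means), medication-cost means of £282.16 / £300.17, study-drug dosing
200/300/400 mg in proportions 7/85/32 of 124 with 90/124 completing 365
days, and questionnaire missingness rising from ~1% at baseline to ~24% at
12 months.

Calibration is analytic, not tuned: the intervention arm's follow-up
utility means are shifted by `true_delta_qaly / 0.75` (the AUC weight of
the follow-up visits), and its follow-up resource-count means are scaled by
the single multiplier that makes the *expected* NHS/PSS cost contrast —
including the expected drug cost computed from the dosing mix and the
configured medication contrast — equal `true_delta_cost` exactly. Arm
contrasts therefore converge to the configured truths by the law of large
numbers, which is what the recovery tests assert.

Distributional choices:

* **Utilities** are drawn from a scaled beta on `[floor, 1]` through a
  Gaussian copula (within-person correlation 0.6, a negative loading on
  baseline pain), then converted to an EQ-5D-5L profile: the
  pain/discomfort level is drawn from a configured marginal (default puts
  ~99% of participants above level 1), and the other four dimensions are
  chosen as the tariff-nearest match to the target utility, ties broken at
  random. Scored utilities equal the latent targets up to profile
  discretisation (~0.01 on the mean, with no detectable effect on arm
  contrasts, since both arms discretise identically).
* **Resource counts** are negative-binomial with a mean-one lognormal
  person frailty tied to baseline pain. An earlier sketch of this design
  drew *costs* from zero-inflated gammas; integer counts priced through
  the unit-cost table match the actual costing contract, so counts are
  generated and the gamma form is kept only for the continuous personal
  expenses (zero-inflated gamma). Overdispersion (SD > mean) is preserved
  either way.
* **Missingness** is applied after outcome generation (complete data are
  retained for recovery tests), at the questionnaire-block level per
  visit, with logistic dependence on always-observed baseline fields only
  (missing at random by construction — coefficients naming a maskable
  field are rejected). Intercepts are calibrated numerically so realized
  marginal rates match the configured ones despite covariate and
  carry-over terms; a log-odds boost after a missed visit makes the
  pattern weakly monotone. The joint pattern across instruments within a
  visit is not identified by published marginals, so an
  independence/coupling knob is exposed (default 0.5) rather than
  asserting one. Person-level "blank-proneness" masks the free-text
  "other" resource items, which is what drives complete economic profiles
  down to ~30% while utility completeness stays near 74%.

What the generator does **not** emulate: adverse events, a clinical
pain-trajectory model beyond a configurable mean shift, informative
(MNAR) missingness, visit-date jitter, or within-category medication
composition. Passing recovery tests therefore show the pipeline is
consistent under the stated data-generating assumptions — they cannot show
robustness to violations the generator does not produce (e.g. MNAR
dropout).

## Problem sizes and numerical tolerances

The test suite runs the full pipeline at trial scale (124/arm) and checks
parameter recovery at 2,500/arm with m = 5 imputations and 5 cycles —
large enough that three Monte-Carlo standard errors separate signal from
the generator's truth, small enough to keep the suite quick. BCa coverage
is checked on the exponential-mean toy (n = 50, 999 replicates, 1,000
simulations) against 95% ± 2%. The acceptance script simulates the default
248-participant trial and runs the base case with B = 1,000 bootstrap
replicates, m = 10 and 5 cycles; B = 5,000 (the conventional CE-plane
cloud size) remains the package default for `run_config()`. Chained
equations use a small ridge (1e-5) on the normal equations; SUR refuses
singular designs by naming the collinear columns rather than silently
dropping them.

## Known limitations

* The shipped tariff is synthetic; real analyses must supply a licensed
  value set file.
* Medication category averages are placeholders (flagged in the CSV).
* Complete-case and MI analyses share the SUR specification; no doubly
  robust or MNAR sensitivity machinery is provided.
* No extrapolation beyond the 12-month horizon, and no discounting — both
  deliberate, matching the within-trial design; longer horizons would need
  different machinery (e.g. long-term drug-monitoring costs).

## A minimal run

```{r example}
library(trialcea)

trial <- generate_trial(generator_config(seed = 2026))
res <- run_analysis(run_config(trial$data, B = 1000, m = 10,
                               iterations = 5, seed = 2026))
print(res)

# decision outputs
res$icer
res$net_benefit
head(res$ceac)
res$ce_plane$quadrant_shares
```
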