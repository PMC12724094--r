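---
title: "Methods: trial-based cost-utility analysis with trialcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-utility analysis with trialcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

trialcea implements a within-trial economic evaluation for a three-arm
randomised trial comparing two intensities of an avatar-based psychological
therapy for distressing voices against treatment as usual (TAU), from a
health and social care perspective over a 28-week horizon. This vignette
describes the statistical model, the choices behind every tunable
parameter, what the synthetic-trial generator does and does not emulate,
and the numerical decisions a reviewer would want stated.

## The estimation problem

Each randomised participant contributes a total follow-up cost $C_i$
(service use over weeks 0–28, valued at unit costs, plus the therapy
cost) and a quality-adjusted life-year accrual $Q_i$ computed from
EQ-5D-5L utilities at weeks 0, 16 and 28 by trapezoidal
(area-under-the-curve) integration, assuming linear change between
assessments:

$$Q_i = \frac{u_{0,i}+u_{16,i}}{2}\cdot\frac{16}{52} +
        \frac{u_{16,i}+u_{28,i}}{2}\cdot\frac{12}{52}.$$

QALYs are expressed in years, so a full-health trajectory accrues
$28/52 \approx 0.538$. Baseline cost (a 12-week recall window) and
baseline utility enter as covariates, not outcomes.

Adjusted incremental costs and QALYs of each therapy arm versus TAU come
from a two-equation seemingly unrelated regression (SUR):

$$C_i = \alpha_0 + \alpha_B D_{B,i} + \alpha_E D_{E,i}
        + \alpha_c C^{base}_i + \text{site}_i + \varepsilon_{C,i},$$
$$Q_i = \beta_0 + \beta_B D_{B,i} + \beta_E D_{E,i}
        + \beta_u u_{0,i} + \text{site}_i + \varepsilon_{Q,i},$$

estimated jointly by one-step feasible generalised least squares with an
unrestricted $2\times 2$ cross-equation error covariance. The arm
coefficients $(\alpha_B,\beta_B)$ and $(\alpha_E,\beta_E)$ are the
incremental estimates. When the two equations share an identical
regressor set the FGLS estimator collapses to per-equation least squares
(Kruskal's equivalence), which the test suite asserts to $10^{-8}$.
Cross-equation weighting matters only when the regressor sets differ, as
they do here (baseline cost versus baseline utility); a practical
consequence is that changing costs can move the QALY coefficients, but
only through the error-covariance weights — empirically at the
$10^{-7}$ level, which is why scenario analyses treat incremental QALYs
as invariant.

Decision rules follow the usual quadrant logic: lower costs and more
QALYs is *dominant*, the reverse *dominated*; in the trade-off quadrants
the incremental cost-effectiveness ratio $\Delta C/\Delta Q$ is
reported. A comparison with $\Delta Q = 0$ exactly admits no ICER and is
classed by the cost sign alone.

## Missing data

Follow-up costs and QALYs are missing for participants lost to
assessment; baseline covariates can also be incomplete. The package
imputes by chained equations with type-1 predictive mean matching
(PMM): each incomplete variable is regressed on all other analysis
variables plus arm and site, regression parameters are drawn from their
approximate posterior, and each missing case receives the observed value
of a donor sampled from the $k = 5$ nearest predicted means. Matching on
observed donor values preserves the zero-inflation and right skew of
cost data that parametric draws would destroy. Defaults: $m = 10$
imputed datasets for the main analysis (enough for stable pooled
variances at these missingness fractions; configurable), 10
chained-equation cycles, donor ties broken by a seeded uniform draw.
Estimates are pooled by Rubin's rules with Barnard–Rubin small-sample
degrees of freedom; with no missing data the pipeline short-circuits to
$m$ identical copies and reproduces a single direct fit exactly.

The available-case route (per-equation least squares on complete cases,
no imputation) is retained as a sensitivity method, mirroring standard
practice.

## Uncertainty

Sampling uncertainty comes from a nonparametric bootstrap with the
imputation nested inside it: each of $B$ resamples (default 1000) redraws
participants with replacement *stratified by arm* — preserving the
115/116/114 design; unstratified resampling is available by flag — then
re-imputes ($m_{boot} = 2$, since only point estimates are needed per
draw) and refits the SUR. Each draw runs on an independent seeded
substream, so results are bit-reproducible from one master seed.

From the draws the package reports cost-effectiveness planes (quadrant
fractions of $(\Delta Q_b, \Delta C_b)$, boundary draws split equally),
and cost-effectiveness acceptability curves over a willingness-to-pay
grid of £0–£100,000 in £2,000 steps. The pairwise CEAC (the default
report output) is $P(\lambda\Delta Q_b - \Delta C_b > 0) + \tfrac12
P(=0)$; a three-way variant ranks the three arms' adjusted absolute net
benefits $\lambda\bar Q_a - \bar C_a$ per draw. Both are provided because
ranking "the groups" is ambiguous between the two constructions; they
coincide in two-arm subsets, which the tests verify against brute-force
counting.

## Costing parameters

* **Unit costs** (GBP, 2021/22 prices, no discounting over the 28-week
  horizon). The shipped table contains representative NHS values and is
  fully user-replaceable; costing fails loudly for any service without a
  cost rather than pricing it at zero.
* **Therapist session cost**, default £82.37 = £54.55/hour (Band 8) ×
  1.51 uplift for non-contact time. At mean doses of 5.1 and 8.2
  sessions this prices therapist time near £420 and £674 per recipient.
* **Fixed technology cost**, default £50 per therapy recipient, charged
  once regardless of sessions attended; a switch restricts it to
  participants with at least one session.
* **In-patient per-diem**, default £341/day, chosen so that admission
  frequencies near 7% with mean stays of 28–77 days produce per-arm mean
  in-patient costs in the £600–£2,000 range typical of this population.
* **Periods**: baseline recall 12 weeks (a reporting convention — the
  instrument asks about "the period leading up to" baseline; the window
  is configurable), week-16 covering weeks (0,16], week-28 covering
  (16,28]. Therapy cost is attributed to the two follow-up periods in
  proportion to their spans (16:12), so period totals still sum to the
  participant's follow-up total.

## Utilities and the value set

EQ-5D-5L responses are valued by table lookup in a pluggable 3,125-state
value set. The shipped default is a **synthetic crosswalk-style set**
built in code, not a published tariff: each 5L level is placed on the 3L
decrement scale by linear interpolation (levels 1…5 ↦ positions 1, 1.5,
2, 2.5, 3) and combined with the additive structure of UK 3L tariffs
(0.081 constant for any dysfunction, per-domain decrements, and a 0.269
worst-level term weighted by the most severe domain). It anchors
(1,1,1,1,1) at exactly 1 and (5,5,5,5,5) at −0.594 — the range of the
published UK crosswalk — but interior values are approximations. Any
table with the same columns can be substituted, including a direct 5L
tariff; analyses intended for decision-making should use a published
value set. Monotonicity within domains holds for this synthetic set but
is not assumed or asserted for substitutes.

## The synthetic-trial generator

`generate_trial()` emulates the features of the trial data that the
analysis machinery must survive:

* arm sizes 115/116/114 across 4 sites;
* mostly-zero service use: per-service use probabilities of 0.15–0.55
  with conditional contact counts of 2–4, so most participants have zero
  cost for most services;
* rare, long psychiatric admissions — Bernoulli (≈0.06–0.08 per arm over
  follow-up) × rounded gamma stays (shape 1.2; arm means 76.7/70/27.9
  days, capped at the period spans) — giving the heavy right tail in
  which a handful of admissions dominates total cost;
* therapy doses as negative binomials matched to mean (s.d.) 5.1 (2.4)
  and 8.2 (4.4) sessions (the negative binomial reproduces the mean
  exactly, avoiding the truncation bias of clipped normals);
* utilities from a latent person-level trajectory (baseline mean 0.55,
  between-person s.d. 0.20, occasion s.d. 0.12) with small arm×time
  improvements at weeks 16 and 28, measured by mapping each latent value
  to the *nearest* five-level state under the value set (seeded uniform
  tie-break). The inversion is a modelling convenience, not a claim
  about real response behaviour;
* missing-at-random follow-up: observation indicators drawn from a
  logistic model on arm and z-scored baseline utility and cost (slopes
  −0.5 and 0.3), with intercepts calibrated by root-finding so expected
  observation rates equal the arm-specific targets (≈80–90%,
  the completion pattern of a trial of this kind).

`trial_truth()` records the generator's implied true incremental
effects by Monte-Carlo (default $2\times10^5$ per arm), including the
stay caps and five-level measurement that closed forms miss; the
`delta_cost`/`delta_qaly` calibration shortcuts invert the expected-cost
equation using the closed-form capped-gamma mean, so configured targets
and recorded truths agree to within Monte-Carlo and rounding error.

What passing tests on these data do **not** show: robustness to
non-random (MNAR) dropout, to cost–utility dependence beyond the shared
covariates, to community service-use differences between arms (the
generator makes community use exchangeable), or to value-set
misspecification. The generator is a test harness, not evidence about
any real therapy.

## Numerical choices

* The joint FGLS system is solved on unit-variance responses (costs and
  QALYs differ by several orders of magnitude; without rescaling the
  normal equations are numerically singular), and coefficients are
  rescaled afterwards.
* Singular designs — e.g. a resample in which site is confounded —
  drop aliased columns in pivot order with a warning, keeping intercept
  and arm indicators; if an arm effect itself is unidentifiable the fit
  errors.
* Exact net-benefit ties in CEACs and boundary draws on the plane are
  split equally; with continuous costs these occur with probability
  near zero but the rule is deterministic and tested.
* All randomness descends from one master seed through named substreams
  (roster, service use, therapy, EQ-5D, missingness, one per bootstrap
  draw), so any module can be regenerated independently and full runs
  are bit-reproducible.
* Sensitivity scenarios share the master imputation seed, making MI
  noise common across scenarios and isolating the cost-assumption
  effect. Fixed-cost changes are constant within arm and therefore shift
  the adjusted incremental cost *exactly*; per-session multiplier
  changes are heterogeneous and match the mean therapist-cost change
  only up to in-sample covariate balance (order
  $\text{sd(sessions)}/\sqrt{n_a}$).

## Problem sizes in the test suite

The suite exercises the machinery at sizes chosen to keep oracle
comparisons sharp while completing quickly: donor-property and
determinism checks at $n\approx180$–$345$; MCAR calibration at
$n\approx1000$ over 50 replications with $m=5$; parameter recovery over
100 generated trials at the design size $n=345$ with $m=10$ and analytic
CIs; bootstrap-versus-analytic interval agreement at $B=600$ on complete
data; end-to-end bit-reproducibility at $B=200$, $m_{boot}=2$.

## Known limitations

* One-step FGLS (no iteration); with strongly non-normal errors the
  analytic CIs lean on large-sample arguments — the bootstrap is the
  primary uncertainty statement.
* The imputation model is linear in covariates; PMM protects the
  marginal distributions but not arbitrary non-linear structure.
* No mortality over the 28-week horizon, no discounting, no societal
  perspective, and no direct comparison between the two therapy arms —
  all deliberate scope restrictions matching the trial design the
  package serves.
* The shipped value set is synthetic (see above); published tariffs
  should replace it for real analyses.
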