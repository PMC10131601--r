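---
title: "Matched pre/post evaluation of health-care spending: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched pre/post evaluation of health-care spending: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupmatch)
library(dplyr)
```

## The problem

Health-plan-sponsored digital health programs are opt-in: members who
enlist differ systematically from members who do not (they tend to be
younger, more often female, with fewer chronic conditions and lower
baseline spending). A naive comparison of spending between enlistees and
non-enlistees therefore mostly measures who chooses to enlist, not what the
program does. `pupmatch` implements the standard observational remedy for
claims data: a retrospective, propensity-score-matched, two-group,
pre/post design with a difference-in-differences (DiD) estimand on
per-user-per-month (PUPM) spending.

The estimand, on the savings sign convention, is

$$
\widehat{\Delta\Delta} \;=\;
\big(\overline{\text{post}} - \overline{\text{pre}}\big)_{\text{comparison}}
\;-\;
\big(\overline{\text{post}} - \overline{\text{pre}}\big)_{\text{treated}},
$$

where each member's pre mean is taken over the 12 months before their
anchor month and the post mean over the 7–12 fully observed months after
it. A positive value means the treated group's spending fell relative to
its matched comparison.

## Pipeline stages

1. **Eligibility** (`filter_eligible()`): adults (>= 18), continuously
   eligible over the study period, with 12 observable pre months and >= 7
   observable post months around the anchor. All bounds are inclusive.
2. **Anchored features** (`build_features()`): covariates summarizing the
   12 whole months strictly before the anchor. The anchor (enlistment)
   month belongs to neither period — spending in it mixes pre- and
   post-exposure behavior, so it is excluded from both windows.
3. **Propensity** (`fit_propensity()`): an ensemble of two heterogeneous
   learners — linear-logistic regression and gradient-boosted trees — whose
   probabilities are averaged. Two families is the minimal honest
   "ensemble": the linear learner is well calibrated, the boosted learner
   captures interactions; averaging inherits most of both.
4. **Rolling matching** (`iterative_match()`): enlistment months are
   processed in ascending order. Each month, the still-unmatched comparison
   pool is re-featurized at that anchor, scored, and greedily matched 1:1
   to that month's enlistees by absolute logit-score distance within exact
   segments of (sex, pharmacy-data availability, plan type). Matched
   controls are consumed permanently — no replacement across months.
5. **Balance** (`compute_balance()`): standardized mean differences and
   Welch tests per feature; the conventional pass rule is all |SMD| <= 0.1.
6. **Spend** (`filter_claims()`, `cap_spending()`, `summarize_spend()`):
   non-impactable and pregnancy-related claims are removed; per-member
   period totals are capped at the pooled nearest-rank 99th percentile,
   separately for the pre and post periods; PUPM divides by the number of
   window months, counting zero-spend months in the denominator.
7. **Effects** (`within_group_change()`, `difference_in_differences()`,
   `category_breakdown()`, `classify_ed()`, `subgroup_effect()`): paired t
   tests within groups, an unpaired unequal-variance (Welch) t test for the
   between-group DiD, per-category DiD rows, and a probabilistic
   emergent/non-emergent split of ED spending by diagnosis code.

`run_pipeline()` composes all stages deterministically given a seed and
emits a manifest with stage counts, estimates, the balance report, and the
matched pairs.

## Key design choices

**Distance on the logit scale.** Nearest-neighbor distance is
$|\mathrm{logit}(\hat e_t) - \mathrm{logit}(\hat e_c)|$; the logit spreads
scores near 0 and 1 where raw-probability differences understate
dissimilarity. Scores are clipped to $[10^{-6}, 1-10^{-6}]$ so logits stay
finite.

**Greedy order and ties.** Treated members are matched in descending score
order — extreme-score members have the thinnest candidate sets, so they
pick first. All ties (treated order, equidistant controls) break by
ascending member id, making the result a function of the score multisets
only; tests verify invariance to input row order and agreement with a
brute-force implementation of the same policy.

**No caliper by default.** The design targets full 1:1 matching of the
treated group; a `caliper` argument exists for stricter use. Unmatched
treated members are reported, never silently dropped, and are excluded
from effect estimation.

**Unpaired DiD test.** Although matching is 1:1, the between-group test is
an unpaired Welch t test on member-level change scores, not a paired test
on pair differences — matching is a design device here, not a claim that
pairs are exchangeable units.

**Pooled capping.** The 99th-percentile cap is the nearest-rank
(`ceiling(0.99 n)`-th order statistic) of the *pooled* treated-plus-
comparison period totals, so both groups face a single cap and the
estimand stays symmetric; it is applied separately to pre and post totals
and spread proportionally across cost categories so category PUPMs still
sum to the total.

**Anchor inheritance.** A comparison member has no enlistment date; the
matched control inherits its partner's anchor month, and the pair shares
one post-window length (truncated at 12 months and at the earlier of the
two eligibility ends) so the two members are always evaluated over
identical calendars.

**Degenerate inputs.** All-zero change scores give estimate 0 and p = 1 by
convention; zero-variance balance features with equal means give SMD 0,
with unequal means they are flagged degenerate; unknown ED diagnosis codes
go to the "other" bucket with a warning by default.

## The synthetic claims generator

Real claims of this kind are proprietary and cannot ship with an analysis
package, so `pupmatch` includes a generator whose defaults *are* the study
conditions the pipeline is tested under. It is a stand-in: the true spend
distribution and the true selection mechanism of any real program are
unknown, and the generator's parametric forms are chosen for shape, not
fit to any proprietary data.

* **Spend**: per member-month-category, spend is zero with probability
  $p_0^{(c)}$, else $\exp\{N(\mu_c + \log s_i, \sigma_c)\}$ USD, where
  $s_i$ is the member's spend multiplier. This zero-inflated lognormal
  reproduces the right-skewed, zero-heavy shape of monthly claims;
  defaults give a typical total near $450–600 PUPM with ED and inpatient
  rates of 0.18 and 0.16 visits per member-year (utilization intensity for
  those two categories scales with chronic count).
* **Members**: ages ~ N(42, 13) truncated at 18; chronic counts Poisson
  with P(>= 1 condition) = 0.36; $s_i = \exp(z_i + 0.25\,\mathrm{cc}_i)$
  with $z_i \sim N(0, 0.6)$. The member's `risk_score` is defined as
  $s_i$ itself — a stylized "predicted use" score.
* **Selection**: enlistment is Bernoulli with logit linear in age, sex,
  chronic count, log risk score, and communication receptivity; defaults
  make enlistees younger, more female, healthier, and lower-spend, with an
  overall enlistment rate near 13%. Because the spend-level driver
  (`risk_score`) is itself a matching feature, selection is on
  observables: the matched DiD is recoverable while the naive post-period
  contrast stays badly biased — the contrast `run_pipeline()` exposes via
  `naive_post_difference()`.
* **Treatment effect**: `treatment_effect_pupm` scales each enrolled
  member's impactable post-enlistment claim amounts by
  $1 + \Delta / E_i$, where $E_i$ is the member's expected impactable
  observed monthly spend in closed form (`expected_monthly_spend()`), so
  the expected PUPM change equals $\Delta$ exactly; the calibration is
  unit-tested against the empirical mean, including linearity in
  $\Delta$.
* **Flags and codes**: claims are flagged non-impactable (8%) or, for
  female members aged 18–45, pregnancy-related (2%); ED lines carry a
  diagnosis code drawn from the shipped **synthetic** ED probability table
  (`ed_probability_table()`), which mimics the format of published
  probabilistic ED classification schemes. Users may supply a real table
  in the same CSV format.

What the generator does *not* emulate: calendar seasonality and secular
trends, serial correlation of a member's spend beyond the static
multiplier, multiple claims per category-month, benefit-design changes,
and pandemic-era utilization shifts. Passing tests therefore demonstrate
that the estimator machinery is correct under a plausible data-generating
process — not that any particular real-world program saves money.

## Simulation evidence the test suite computes

The acceptance suite runs two simulation studies (sizes chosen to exercise
the design at realistic scale while keeping a laptop run practical):

* **Recovery**: 50 replicates of 60,000 members (~7,800 enlistees,
  ~52,000 pool) with an injected effect of −$10 PUPM. The pipeline's 95%
  CI must cover 10 in at least 90% of replicates, and the naive unmatched
  post-period contrast must show at least 3 times the absolute bias of the
  matched DiD (in these conditions the naive contrast is biased upward by
  roughly $100 PUPM while the matched DiD is unbiased to within
  Monte-Carlo error).
* **Null calibration**: 500 replicates of 1,200 members with a zero
  injected effect; the DiD p-value must fall below .05 in 5% ± 2% of
  replicates.

Smaller unit simulations check the closed-form enlistment rate against the
selection logit, the injected-effect calibration and its linearity, the
shrinkage of selection-feature SMDs from pre- to post-matching, and the
type-I error of the within-group paired test.

## Numerical conventions

Months are 0-based integer indices from study start; no calendar dates.
Claim amounts are stored as integer cents; all statistics are computed in
double-precision USD. Percentiles are nearest-rank. The significance level
is fixed at $\alpha = .05$ with 95% CIs throughout. Every source of
randomness (generation, model fitting, pseudo-anchor draws) is governed by
explicit integer seeds; fixed seeds give bitwise-identical outputs.

## Limitations

Matching removes only observed confounding; with selection on unobservables
the DiD still absorbs any differential *trend* between groups. The
generator has no differential trends by construction, so the simulations
cannot detect estimator sensitivity to them. Pharmacy spend is observable
only for members with data-sharing agreements, which is why pharmacy data
availability is both an exact-matching segment and an explicit
missing-data indicator in the propensity model rather than being imputed.
The shipped ED table is synthetic; substantive emergent/non-emergent
conclusions require a real probability table supplied by the user.
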