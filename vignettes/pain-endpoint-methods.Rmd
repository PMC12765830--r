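---
title: "Methods: time-weighted pain endpoints, imputation and gatekept analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-weighted pain endpoints, imputation and gatekept analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paintrial)
```

## The scoring model

Acute-pain trials assess pain intensity (PI, numerical rating scale 0–10)
and pain relief (PR, Likert 0–4) on a fixed post-dose grid. `paintrial`
anchors the grid at Time 0 (start of the loading infusion), places the
end-of-infusion assessment at 10 min, and ends at exactly 24 h
(`protocol_schedule()`). The composite endpoints are time-weighted sums,

$$\mathrm{SPID}_t = \sum_{t_k \in (0, t]} (PI_{t_k} - PI_0)\,(t_k - t_{k-1}),
\qquad
\mathrm{TOTPAR}_t = \sum_{t_k \in (0, t]} PR_{t_k}\,(t_k - t_{k-1}),$$

where $t_{k-1}$ is the preceding grid point. Time 0 carries no weight (no
interval ends there) and the baseline pain difference is identically 0.
Because the grid weights sum to exactly 24 h, $\mathrm{SPID}_{24}$ is
bounded by $\pm 240$ and $\mathrm{TOTPAR}_{24}$ by $[0, 96]$, and both
bounds are attained by extreme integer trajectories. All windows in the
package are half-open $(\mathrm{start}, \mathrm{end}]$.

### Exact interval arithmetic

Assessment times are quantized to whole minutes, so every interval weight
is an integer number of minutes and each endpoint is accumulated as an
exact integer in score-minutes; the single division by 60 happens at
reporting. Consequences worth knowing:

* the decomposition $\mathrm{SPID}_{24} = \mathrm{SPID}_{12} +
  \mathrm{SPID}_{12\text{–}24}$ is exact on the minute scale
  (`compute_spid(..., units = "minutes")` returns the integer); on the
  hour scale the three reported doubles can disagree in the last bit,
  because $a/60 + b/60$ and $(a+b)/60$ round differently in binary
  floating point;
* window bounds must be grid points; an off-grid bound is a contract
  error, not an interpolation — trapezoidal or interpolated variants of
  the endpoint are deliberately out of scope.

## Imputation rules

`imputation_policy()` encodes three regimes with a fixed precedence:

1. **Rescue windows.** Points inside $(r, r + w]$ after a rescue dose
   ($w = 6$ h for parecoxib, $2$ h for sufentanil) take the last score
   recorded before the rescue, so rescue analgesia is not credited to
   the study drug. When windows overlap, the later rescue's pre-rescue
   score governs from its own event time.
2. **Night sleep.** Outside rescue windows, a missing night-flagged PI
   becomes NRS 3; a missing night PR takes the previous PR.
3. **LOCF** for all other gaps.

Two genuinely open readings of the rescue rule exist: the imputation text
speaks of *missing* data in the windows, while the existence of a
sensitivity analysis "without imputation for scores after rescue" implies
the primary analysis also overwrote observed post-rescue scores. The
package makes both selectable: the default fills only missing points;
`strict_rescue = TRUE` overwrites observed in-window scores as well;
`mode = "sensitivity_no_rescue_imputation"` disables the rescue rule.
The default is the literal (missing-only) reading because it is the
conservative interpretation of the written rule; the strict variant is
one flag away and the pipeline logs provenance tallies so the modes can
be audited against each other.

Degenerate inputs are errors, not silent fixes: a participant without a
baseline PI is unevaluable, and a missing PR with no preceding PR
observation (e.g. a night gap at the first post-baseline point) raises an
error naming the time point — there is no defensible value to invent
there, and the simulator never produces this case because the
end-of-infusion assessment is investigator-administered in person.
Imputation is idempotent at value level; provenance columns are
recomputed on re-imputation.

## The synthetic-trial generator

`simulate_trial()` emulates the statistical structure the analysis
assumes, not any pharmacological mechanism:

* **Baseline**: integer NRS from a discretized normal (mean 5.0, SD 1.2)
  truncated to 4–10, matching moderate-to-severe inclusion.
* **Trajectory**: $PI(t) = \mathrm{clamp}_{[0,10]}\,
  \mathrm{round}(B - E_i(1 - e^{-t/\tau}) + \varepsilon_t)$ with
  participant-level response $E_i \sim N(E_{\mathrm{arm}}, 1.3)$
  truncated to $[0, 10]$ and assessment noise
  $\varepsilon_t \sim N(0, 0.8)$. The between-participant response SD is
  the dominant source of endpoint spread: with 24 h of weight, an SD of
  1.3 NRS units produces SPID_24 SDs near 30 NRS-hours, the magnitude
  typical of this design. Default arm effects/onsets are
  placebo 2.2/2.0 h, low dose 2.7/0.8 h, high dose 3.0/0.8 h, comparator
  3.1/1.2 h — ordered placebo < low < high ≈ comparator with a slower
  comparator onset.
* **Pain relief**: $PR = \mathrm{clamp}_{[0,4]}(B - PI)$, a monotone map
  of the achieved drop.
* **Rescue**: at any assessment with $PI \ge 5$, a rescue dose is
  requested with per-assessment probability 0.30 (parecoxib 40 mg for
  the first two, sufentanil 5 µg after), reducing PI by 2 during the
  drug's window. Under these rates roughly 60% of placebo and 40% of
  active-arm participants rescue, the qualitative pattern of this trial
  class.
* **PCA demands**: a Poisson press process with intensity 0.4 presses/h
  per NRS point, thinned by `apply_pca_rules()` — dosing window
  (0.5 h, 24 h], 10-min lockout, at most 6 accepted demands in any
  trailing 60-min sliding window (the conservative reading of a
  0.3-units-per-hour cap at 0.05 units per demand; clock-hour accounting
  would allow short bursts of more than 6 in 60 min). The window is
  half-open, so a press at exactly 30 min is rejected. An optional
  coupling of accepted demands to PI exists (`pca_pi_coupling`) and is
  off by default, since demand dosing in both arms largely cancels in
  between-arm contrasts.
* **Missingness**: night window (10 h, 16 h] post dose (surgery assumed
  in the afternoon; the night window is configurable because "night" is
  not defined by the schedule itself), where assessments are missing
  with probability 0.25 and flagged `night_sleep`; 2% background
  missingness elsewhere; 1.5% dropout flags.
* **Determinism**: one master seed; each participant draws from a
  private substream indexed by (arm, counter), so per-arm output is
  reproducible independently of simulation order.

What the generator does **not** emulate: pharmacokinetic
concentration–effect relationships, adverse events, site effects,
informative (outcome-dependent) missingness beyond the night window, and
serial correlation in assessment noise. Passing tests therefore
demonstrate that the pipeline is correct and well-calibrated under a
plausible data-generating process, not that any specific drug effect in
real data would be recovered.

## Inference

* **Group t test** is read as the pooled-variance two-sample t
  (`variance_mode = "pooled"`), the classical usage consistent with a
  single reported SE per contrast; Welch is available by flag since the
  original computation is not documented either way. Confidence
  intervals use the t quantile at the corresponding df. If both samples
  are constant with equal means, p is defined as 1.
* **Gatekeeping** (`gatekept_primary_analysis()`): hypotheses in fixed
  order (high dose vs placebo, then low dose vs placebo), each at full
  α = 0.05; later hypotheses are *confirmatory* only while all earlier
  ones rejected, otherwise *exploratory*. The p values are never
  adjusted — the ordering is what bounds the familywise error, which the
  test suite verifies by null simulation. All other comparisons are
  labelled *nominal*.
* **Rescue outcomes**: Clopper–Pearson intervals from beta quantiles
  with the conventions $lo = 0$ at $k = 0$ and $hi = 1$ at $k = n$;
  Fisher's exact two-sided p as the sum of table probabilities no larger
  than the observed table's; Kaplan–Meier and log-rank via the
  `survival` package (hypergeometric tie variance, no continuity
  correction); non-rescuers censored at 24 h, and a rescue recorded
  after 24 h kept as an event at its recorded time. The no-rescue
  denominator is the full analysis-set arm size. Consumption summaries
  zero-fill non-users so means are over all treated participants. When
  a Fisher margin is zero (nobody rescued in either arm) the comparison
  carries no information and p is reported as 1.
* **Wilcoxon rank-sum**: exact enumeration when the combined sample is
  at most 20 without ties, otherwise the tie-corrected normal
  approximation without continuity correction.

## Design calculations

`sample_size_two_groups()` uses the two-group z approximation
$n = \lceil (z_{1-\alpha/2} + z_{1-\beta})^2 (\sigma_1^2 + \sigma_0^2) /
\delta^2 \rceil$. Under the default assumptions (means 88 vs 70, SDs
45/40, α 0.05, power 0.90) this gives 117.56 → 118 evaluable per group;
an iterative noncentral-t calculation gives 119, and the z form is the
default precisely because it reproduces the published plan. Dropout
inflation is division and ceiling: 118/0.9 → 132; over four equal arms,
528. `power_at_n()` is the inverse and is validated against a
Monte-Carlo t-test simulation in the test suite.

## Problem sizes in the test suite

The property suites run at sizes chosen to make Monte-Carlo margins
small while keeping the default test run fast: 1,000 random series for
additivity and oracle equivalence, exhaustive Clopper–Pearson coverage
for all $n \le 30$ over a 0.005-step grid of true proportions, 10,000
null replicates for the familywise-error bound, and 200 simulated trials
at the planned 132/arm for parameter recovery (replicate-level 95%
intervals covering the long-run contrast in at least 90% of replicates).

## Known limitations

* The rescue-trigger and PCA-press models are behavioural
  simplifications; real rescue decisions involve investigators and are
  not a per-assessment Bernoulli draw.
* Satisfaction scores are generated but only summarized descriptively;
  the rank-sum machinery applies to them unchanged.
* The package models a single 24-h treatment period; repeated-dose or
  follow-up analyses are out of scope.
* No covariate adjustment or stratification: the emulated analysis is
  unadjusted, as in the design this package reproduces.
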