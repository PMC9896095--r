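---
title: "Methods: a two-state Markov cohort model for manual-therapy cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-state Markov cohort model for manual-therapy cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcea)
```

## The problem and the model

`mtcea` evaluates the cost-effectiveness of specialised manual therapy (five-year
manual-medicine training, e.g. naprapathy) against standard orthopaedic care for
working-age patients with non-surgical musculoskeletal disorders, over an 8-year
horizon. The evidence base is a small two-arm randomised trial (40 index, 38
control) with follow-ups at 3, 6, 12 and 96 months, SF-6D utilities at each
follow-up, and per-category health-care costs in SEK.

Because individual trajectories are only observed at four time points, the
long-run comparison uses a **Markov cohort model** with two live states,
*recovered* and *non-recovered*, a 3-month cycle and a 96-month horizon
(32 cycles). The cohort is closed: no death state, which is defensible for a
working-age population over eight years but is a simplification. At each cycle
boundary the non-recovered fraction moves to recovered with probability
$p_{rec}(t)$ and the recovered fraction relapses with probability $p_{rel}(t)$:

$$f_N(t+1) = f_N(t)\,(1 - p_{rec}(t)) + f_R(t)\,p_{rel}(t), \qquad f_R = 1 - f_N.$$

QALYs accrue as area under the utility–time curve,
$(f_R u_R + f_N u_N)\cdot \tfrac{1}{4}$ years per cycle; costs accrue on the
non-recovered fraction only. Both are discounted at an annual 3% (the national
guideline rate) applied at the cycle midpoint: $(1+r)^{-t}$ with $t$ in years.

## State classification: the health-care perspective

Only direct health-care costs count. A participant who consumed **no care** in
a follow-up window is therefore *recovered for costing purposes regardless of
symptoms* — they generate no costs. This creates a deliberate dual
classification, implemented in `classify_state()`:

* **cost state** — non-recovered iff any treatment was received in the window;
  drives cost denominators and transition probabilities;
* **utility state** — non-recovered iff treated *or* untreated-but-symptomatic
  (the `untreated_nonrecovered_flag`); drives utility pooling, so that
  untreated participants who still report their disorder contribute their lower
  quality-of-life weights to the non-recovered pool.

Only this split reproduces the published pooled utilities together with the
published recovery proportions from the same table: the untreated-symptomatic
column pools with the treated columns for utilities (0.672 over 104
participant-observations at 4–96 months) while counting as recovered for
costing (22/38 = 58% control recovery at the first post-protocol follow-up).

## Model inputs

**Utilities** (`model_utilities()`). The first cycle uses arm-specific
per-protocol utilities: all participants count-weighted at the 3-month
follow-up (`weighted_utility()`, $\sum u_i n_i / \sum n_i$, reported to 3
decimals as published). All later cycles use utilities pooled across both arms
at 4–96 months, split by utility state. From the rounded published cells the
recovered pool computes to 0.812 against the published 0.811; the discrepancy
of 0.001 is attributable to rounding in the source table, and the package
reports its own computed value.

**Costs** (`estimate_cost_schedule()`). Cycle 1 is the arm's mean cost per
participant (everyone counts as non-recovered during the per-protocol period).
Later reporting windows (4–6, 7–12, 13–96 months) divide the window's cost
total by the number of cost-state non-recovered participants at the window's
closing follow-up, spread uniformly over the window's 3-month cycles. When only
the published aggregate cost table is available
(`cost_schedule_from_totals()`), its two coarse windows (baseline–12, 13–96
months) are allocated the same way: uniform across cycles, with the
denominator switching from arm size (cycle 1) to the non-recovered count at
the follow-up closing each cycle's window. This allocation is the package's
choice — the original analysis had access to the finer per-window totals — and
is configurable in record-based runs, where the finer split is used directly.

**Transition probabilities** (`estimate_transitions()`). Span probabilities
between consecutive follow-ups are converted to per-cycle values by
constant-rate conversion $p_3 = 1-(1-p_{span})^{3/span}$, which keeps
probabilities in $[0,1]$ and is exactly consistent under compounding (a linear
division is not). Two estimation routes exist:

* `method = "flows"` uses retained per-participant state sequences (exact
  newly-recovered / newly-relapsed tallies divided by the at-risk pools) —
  available whenever the panel was built from records;
* `method = "net"` (the default) uses aggregate counts only, attributing the
  net change in the recovered *proportion* to the dominant direction, with the
  reverse probability set to zero for that span.

The net route has a useful exactness property: compounding the converted
per-cycle probability over a span's cycles reproduces the span-end proportion
identically, so a cohort driven by net-flow estimates passes through the
observed recovered fractions at every follow-up *exactly*. This is the
package's internal consistency check (`validate_model()` reports 0 points of
discrepancy) and the reason `"net"` is the default for validation work. The
flows route is preferred for parameter inference on individual-level data:
when both flows are active in a span, per-cycle compounding of the two
converted probabilities approximates, rather than reproduces, the endpoint.

Proportions use the enrolment at each follow-up as denominator: participants
who withdrew contribute until withdrawal and denominators shrink (no
imputation, mirroring the trial).

## Economic endpoints

`incremental_analysis()` reports $\Delta QALY$, $\Delta cost$ and either the
ICER $\Delta cost / \Delta QALY$ or a dominance verdict (dominant iff more
effective and cheaper; dominated iff the reverse), discounted and
undiscounted. The original trial's arms differed in baseline utility, and the
published QALY gain adjusts for this. The exact adjustment method and the
baseline values are not published here, so the package implements a standard
difference-in-differences: the baseline gap times the horizon in years
(times the discounted year total for the discounted endpoint) is subtracted
from the raw QALY difference. With equal baselines it is a no-op, and shifting
one arm's baseline and its whole trace by a constant leaves the adjusted gain
unchanged. Baselines are config inputs (`baseline_utilities`), defaulting to
no adjustment — which is why the package's fixture-driven QALY gain is larger
than the published baseline-adjusted figure.

Mean costs per participant use a seeded nonparametric percentile bootstrap
(10,000 resamples by default) for 95% intervals; skewed cost data make these
intervals asymmetric, matching the published ones. The published index-arm
mean of 9003 SEK is obtained with the randomised arm size 40 as denominator
(the published table's totals divided by 40), although the accompanying text
prints $n=38$; the denominator is therefore an explicit argument.

The **2-SD sensitivity analysis** (`sensitivity_two_sd()`) pools the
individual 96-month cost totals of *both* arms, computes their mean and sample
SD, removes individuals above mean + 2·SD (one-sided: the analysis targets
expensive outliers), and recomputes arm means and intervals. With no one over
the threshold the primary result is reproduced bit-for-bit; a degenerate
zero-SD distribution warns and excludes nobody. Note that in very small sets a
single point can never exceed 2 sample SDs (the maximum $z$ in a set of $n$ is
$(n-1)/\sqrt n$), so meaningful exclusion needs a reasonably large pooled set.

## The synthetic trial generator

`simulate_trial()` exists so every stage can be tested against known ground
truth — no individual-level trial data are public. Its defaults emulate the
study conditions: arm sizes 40/38; follow-ups at 3, 6, 12, 96 months; span
transition probabilities set to the values implied by the published panel
counts (index: 0.72, 0.81, then pure relapse 0.17; control: 0.58, 0.17, 0.08);
per-protocol utilities 0.737/0.695; state utility means 0.811/0.672 with SDs
0.10/0.12, drawn truncated-normal on $[0,1]$; per-category log-normal costs
(log-scale SD 0.5) at magnitudes matching the published cost table (e.g.
physiotherapy ≈ 13,000 SEK per treated window, surgery ≈ 27,000 SEK,
specialised MT ≈ 2,600 SEK); 25% untreated-but-symptomatic among the
cost-recovered; 1% dropout per follow-up. Log-normal costs were chosen
deliberately: they motivate both the asymmetric bootstrap intervals and the
2-SD outlier analysis.

Truncation of utility draws to $[0,1]$ biases means slightly toward the
interior; at the default parameters the bias is below 0.002 and is accounted
for in parameter-recovery tolerances. State transitions happen at follow-up
boundaries (the spans are the primitive), so within-window treatment timing,
crossover dynamics, SF-36 item responses and cost–utility correlation are
*not* emulated; passing tests demonstrate the estimator–engine loop and the
analysis plumbing, not robustness to those real-data features.

## Numerical and reporting choices

* Rounding follows the published precision: utilities 3 decimals, SEK whole
  crowns, recovery percentages integer; all internal computation is double
  precision, rounding happens at the reporting surface (functions accept
  `digits = NULL` for full precision).
* Half-cycle handling: occupancy is full-cycle with mid-cycle discounting by
  default — the simplest scheme consistent with area-under-the-curve QALYs;
  `half_cycle_correction = TRUE` switches to trapezoidal occupancy.
* Degenerate inputs error early with named cells/cycles: zero denominators
  with positive numerators, missing schedule cycles, conflicting duplicate
  periods, empty utility strata.
* Ties when a participant has several treatments in one window: the costliest
  category labels them (ties broken by canonical category order), matching a
  one-column-per-participant aggregate table.
* Test problem sizes: parameter recovery uses 2,000 per arm (3-SE binomial
  tolerances), the microsimulation oracle 20,000 individuals, the null
  property 8 seeds at 100 per arm, bootstrap coverage 120 replicates — sizes
  chosen to keep Monte-Carlo error well inside the asserted tolerances while
  the whole suite runs in well under a minute.

## Known limitations

* The published discounted headline endpoints depend on the unpublished
  baseline utilities and the authors' per-period probability worksheet; they
  are approximately, not exactly, reproducible from the aggregate tables. The
  package reports its own computed endpoints next to the published reference
  values rather than forcing agreement.
* The published 69% index-arm recovery during the per-protocol period is not
  reconstructible from the aggregate table, which gives 29/40 ≈ 72% at the
  6-month follow-up; both are reported.
* The two-state closed cohort ignores mortality and any state heterogeneity
  within "non-recovered".
* Aggregate-mode cost allocation across cycles inside a reporting window is
  uniform by assumption.

## A worked run

```{r, eval = FALSE}
fix <- table_fixtures()
spec <- model_spec(
  model_utilities(fix$panel),
  cost_schedule_from_totals(fix$costs, fix$panel),
  estimate_transitions(fix$panel)
)
econ <- incremental_analysis(run_cohort(spec, "index"),
                             run_cohort(spec, "control"))
econ

# or the whole pipeline, artefacts included:
res <- run_pipeline(pipeline_config("fixtures"))
res$econ
```
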