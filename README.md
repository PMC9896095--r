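# mtcea

Trial-based cost-effectiveness analysis of **specialised manual therapy**
(five-year manual-medicine training, e.g. naprapathy) versus **standard
orthopaedic care** for working-age patients with non-surgical musculoskeletal
disorders, over an 8-year horizon. The package is aimed at health economists
and methodologists who want to re-run, probe or extend this style of
trial-based Markov evaluation — swap in their own follow-up panel, their own
transition probabilities, or a synthetic cohort with known truth.

## The model

Long-run outcomes are extrapolated with a **two-state Markov cohort model**:
states *recovered* (R) and *non-recovered* (N), 3-month cycles, 96-month
horizon (32 cycles), closed cohort. With per-cycle transition probabilities
$p_{rec}$ (N→R) and $p_{rel}$ (R→N):

$$f_N(t+1) = f_N(t)\,(1-p_{rec}(t)) + f_R(t)\,p_{rel}(t)$$

QALYs accrue as area under the SF-6D utility–time curve,
$(f_R u_R + f_N u_N)\cdot\tfrac14$ years per cycle; costs accrue on the
non-recovered fraction; both are discounted at 3%/year at cycle midpoints.
The incremental result is $\Delta QALY$ (baseline-adjusted by
difference-in-differences), $\Delta cost$, and the ICER
$\Delta cost/\Delta QALY$ — or a **dominance** verdict when one arm is both
more effective and cheaper.

Model inputs are estimated from follow-up panel data the way the trial
analysis did: a *health-care perspective* state classification (untreated ⇒
recovered for costing, regardless of symptoms), count-weighted utilities,
window cost totals per non-recovered participant, and transition
probabilities from panel counts with constant-rate span→cycle conversion
$p_3 = 1-(1-p_{span})^{3/span}$. A 2-SD cost-outlier sensitivity analysis and
a validation of predicted against observed recovery are included, plus a
synthetic two-arm trial generator (`simulate_trial()`) for ground-truth
testing.

## Worked example

Run the analysis from the packaged aggregate tables (participant counts and
mean utilities per treatment category and follow-up, plus per-category cost
totals):

```r
library(mtcea)

fix <- table_fixtures()
model_utilities(fix$panel)
#> <utility_set>
#>   per-protocol: index 0.737, control 0.695
#>   post-protocol pooled: recovered 0.812, non-recovered 0.672

recovery_proportion(fix$panel, "control", 6)   # cost-state recovery, %
#> [1] 58

spec <- model_spec(
  model_utilities(fix$panel),
  cost_schedule_from_totals(fix$costs, fix$panel),
  estimate_transitions(fix$panel)
)
incremental_analysis(run_cohort(spec, "index"), run_cohort(spec, "control"))
#> <econ_result>
#>   undiscounted: dQALY +0.2317, dCost -40748 SEK -> dominant
#>   discounted:   dQALY +0.2097, dCost -36621 SEK -> dominant
```

Reading: the index arm reaches a higher per-protocol utility (0.737 vs
0.695), 58% of controls are cost-state recovered at the first post-protocol
follow-up, and over 96 months the index strategy yields more QALYs at a cost
saving of roughly 40,700 SEK per patient (36,600 discounted) — specialised
manual therapy *dominates* standard care. The QALY gain shown is
unadjusted; supplying the arms' baseline utilities via
`baseline_utilities = c(index = ..., control = ...)` applies the
difference-in-differences adjustment. Mean costs per participant:
`summarise_cost_table(fix$costs)` gives 9003 SEK (index) vs 47,784 SEK
(control arm totals over 38).

The whole pipeline — panel, schedules, traces, endpoints, validation table,
sensitivity ledger, Markdown report — runs via

```r
res <- run_pipeline(pipeline_config("fixtures"))   # or "panel" / "simulate"
```

or from a shell, `Rscript scripts/run_cea.R analyze --fixtures --out results/`
(verbs: `analyze`, `simulate`, `validate`, `report`; YAML configs via
`--config`).

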