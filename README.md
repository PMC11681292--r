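# shiftmon

Longitudinal model-shift monitoring for deployed clinical risk prediction
scores.

Machine-learning risk models (for acute kidney injury, sepsis, delirium, …)
are trained once on retrospective EHR data and then score patients for years,
while coding practices, patient mix, and documentation density keep changing
underneath them. A model whose AUROC looks stable can still drift badly in
*calibration* — predicting risks that are systematically too high — and that
drift is what inflates alert rates and erodes clinical trust. `shiftmon`
implements a four-stage monitoring pipeline over a table of scored cases
(one row per hospital stay: period, outcome label, predicted risk):

1. **Cohort profiling** — per-period case counts, incidence, and score
   ranges, flagging periods whose incidence deviates enough to suggest
   labeling changes.
2. **Discrimination stability** — per-period AUROC `A` with Hanley–McNeil
   standard errors

   `SE(A) = sqrt[ (A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²)) / (n₊ n₋) ]`,
   `Q₁ = A/(2−A)`, `Q₂ = 2A²/(1+A)`,

   and independent-samples Z-tests `Z = (A₁−A₂)/√(SE₁²+SE₂²)` between every
   pair of periods (plus AUPRC for reference).
3. **Calibration shift** — Platt scaling `p' = 1/(1+exp(A·logit(p)+B))`
   fitted on a held-out calibration split, quantile-binned reliability
   curves with Wilson 95% CIs, and expected/maximum calibration error
   (ECE/MCE); a period is flagged when its post-calibration ECE exceeds the
   calibration split's own by a margin (default 0.05).
4. **Decision impact** — alert threshold chosen to balance overdiagnosis
   (FPR) and underdiagnosis (FNR), five-category alert classification,
   decision curve analysis with net benefit
   `NB(p_t) = TP/N − (FP/N)·p_t/(1−p_t)` against treat-all/treat-none,
   incidence standardization across periods, and an unpaired bootstrap
   comparison of decision curves between periods.

A seeded synthetic cohort generator (`generate_cohort()`) with an
equal-variance binormal latent-score model provides exact analytic ground
truth for every stage: the population AUROC is `Φ((μ₊−μ₋)/(σ√2))`, the honest
posterior is exactly logistic, and injected logit-affine miscalibration is
exactly invertible by Platt scaling.

## Worked example

Simulate three years of a deployed model scoring 5000 stays/year at 15%
incidence, with the model silently starting to overestimate risk (a +1 logit
offset) in 2021, then run the full monitoring pipeline:

```r
library(shiftmon)

cfg <- cohort_config(
  periods = c("2019", "2020", "2021"), n_per_period = 5000, incidence = 0.15,
  miscal_offset = c(0, 0, 1),   # the deployed model starts overestimating in 2021
  calib_fraction = 0.2, seed = 7)
cohort <- generate_cohort(cfg)
report <- run_monitoring(monitoring_config(cohort, n_boot = 500, seed = 7),
                         quiet = TRUE)
report
#> <monitoring_report>
#>   periods: 2019, 2020, 2021
#>   selected threshold: 0.1351
#>   AUROC Z-tests significant at .05: 0 of 3
#>   calibration-shift flags: 2021
#>   decision-curve comparisons with p < .05: 0 of 18

report$calibration$flags
#> # A tibble: 3 × 3
#>   period ece_calibrated shift_flag
#>   <chr>           <dbl> <lgl>
#> 1 2019           0.0109 FALSE
#> 2 2020           0.0122 FALSE
#> 3 2021           0.0845 TRUE
```

This is the monitoring story in miniature: the drifted year's AUROC is
bit-identical to the drift-free counterfactual (a logit offset is strictly
monotone), so discrimination tests and decision-curve comparisons stay null —
only the calibration stage sees the shift (post-calibration ECE 0.084 vs
~0.011 for the stable years) and flags 2021.

Summaries of yearly metrics follow the mean (population SD) reporting
convention:

```r
tab <- yearly_auroc_tables()   # bundled published per-year AUROC percentages
format_mean_sd(tab$auroc_pct[tab$hospital == "M" & tab$use_case == "aki"])
#> [1] "90.37 (0.32)"
```

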