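---
title: "Monitoring model shift in deployed clinical risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring model shift in deployed clinical risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftmon)
```

## The monitoring problem

A clinical risk model is fitted once, on a development cohort, and then
scores patients for years. Three distinct things can degrade over time:

* **discrimination** — whether cases still score higher than controls
  (AUROC);
* **calibration** — whether a predicted risk of 0.2 still corresponds to a
  20% event rate;
* **decision value** — whether alerting at the chosen threshold still does
  more good than harm (net benefit).

These are not redundant. Any strictly increasing distortion of the scores —
for example a model that starts overestimating everyone's risk by a constant
amount on the logit scale — leaves every AUROC *bit-identical* while
arbitrarily damaging calibration and alert rates. A monitoring scheme that
watches only AUROC is therefore blind to an important class of shifts, and
`shiftmon`'s pipeline checks all three surfaces, in that order, plus the
upstream data itself (counts and incidence per period).

## The synthetic scored cohort

Real monitoring data are hospital EHR extracts that cannot ship with a
package, so `shiftmon` includes a generator whose ground truth is known in
closed form. Each case in period $y$ gets:

* a label $Y \sim \mathrm{Bernoulli}(\pi_y)$, with per-period incidence
  $\pi_y$;
* a latent score $z \sim N(\mu_+,\sigma)$ for cases and $N(\mu_-,\sigma)$
  for controls (equal-variance binormal model);
* the honest posterior
  $p = P(Y{=}1 \mid z) = \operatorname{logit}^{-1}\!\big(\tfrac{\mu_+-\mu_-}{\sigma^2}(z - \tfrac{\mu_++\mu_-}{2}) + \operatorname{logit}\pi_y\big)$,
  stored as `true_prob`;
* the deployed model's output
  $\texttt{raw\_score} = \operatorname{logit}^{-1}\!\big(a\operatorname{logit} p + b\big)$,
  with per-period miscalibration slope $a$ and offset $b$; $(a,b)=(1,0)$
  is a perfectly calibrated model.

The binormal family was chosen because it gives analytic oracles: the
population AUROC of any monotone transform of $z$ is
$\Phi\big((\mu_+-\mu_-)/(\sigma\sqrt2)\big)$ (`expected_auroc()`), the
posterior is *exactly* logistic, so "perfectly calibrated" is well defined,
and the logit-affine distortion is exactly the family Platt scaling inverts,
so injected drift is exactly recoverable — parameter recovery becomes a
sharp test, not a fuzzy one.

Defaults are chosen to resemble a good deployed inpatient risk model:
$\mu_+ - \mu_- = 2$, $\sigma = 1$ (population AUROC $\Phi(\sqrt2) = 0.9214$,
in the 0.90–0.98 range typical of the strongest published inpatient models)
and incidence 0.15, representative of a common condition such as hospital-
acquired kidney injury; rarer conditions (1–4%) are exercised through
`thin_incidence()`. Optional onset/length-of-stay fields (onset uniform on
$[0, \mathrm{los}]$, stay uniform on 1–30 days) exist solely to exercise the
five-category alert classifier; nothing else consumes them.

What the generator does **not** emulate: within-stay score trajectories
(one score per case, an end-of-stay evaluation), feature-level drift (labs,
notes, medications), non-monotone score corruption, label noise, and
case-mix changes beyond incidence. Passing tests therefore demonstrate that
the *pipeline* recovers the drift mechanisms it models — not that any
particular hospital's data are drift-free.

### The calibration reserve

All recalibration and threshold selection happens on a `calibration` split,
drawn uniformly at random from the **earliest** period only (default 10% of
it, `calib_fraction`). This mirrors deployment reality — the held-out share
of the development data predates any later drift — and it is load-bearing:
if the reserve pooled cases from all periods, drift injected into a later
period would contaminate the Platt fit itself and inflate the reference
error, weakening exactly the alarm the pipeline exists to raise. The
calibration split never contributes to any per-period test metric.

## Discrimination stage

`auroc()` is the Mann–Whitney statistic with ties half-credited, computed
from mean ranks; a property suite checks exact equality with exhaustive
pair counting. `hanley_mcneil_se()` is the closed-form SE above, and
`auroc_z_test()` compares two periods' AUROCs with an independent-samples
Z (different calendar years contain disjoint stays, so no paired/DeLong
covariance is needed — a correlated variant would differ, which is why the
choice is stated). AUPRC (`auprc()`, average precision with step
interpolation) is reported but never used for cross-period testing, because
it moves with incidence even when the model is unchanged.

**A real limitation, quantified by the test suite:** the Hanley–McNeil SE
is derived under the negative-exponential ROC model. For binormal scores at
high AUROC it overestimates the true sampling SD (at AUROC 0.92,
$n = 2000$, incidence 0.15, by roughly 30%), so the Z-test is
*conservative*: its measured null rejection rate at $\alpha = .05$ is
about 0.01, not 0.05. Absence of significant AUROC differences from this
test is therefore weaker evidence of stability than the nominal level
suggests — one more reason the pipeline never relies on discrimination
testing alone.

### Reporting yearly summaries

`summarize_yearly()` returns the mean and the **population** SD
(denominator $n$): the monitored years are the entire period under review,
not a sample from a longer hypothetical series. `format_mean_sd()` prints
the mean rounded to two decimals and the SD *truncated* at two decimals.
Truncation is deliberate: tabulated yearly metrics are themselves rounded,
and the SD computed from full-precision values can only be smaller than the
SD of their rounded versions, so truncation reproduces summaries computed
upstream of rounding and never overstates the spread.

## Calibration stage

`fit_platt()` fits $p' = 1/(1+\exp(A f + B))$, $f = \operatorname{logit}$
(raw score), by Newton–Raphson on the logistic likelihood (convergence at
gradient norm $< 10^{-8}$; $(A,B) = (-1,0)$ is the identity, matching the
original sign convention). Platt's out-of-sample target smoothing
$\big((N_++1)/(N_++2),\ 1/(N_-+2)\big)$ is available behind a flag and off
by default: the calibration reserves here are thousands of cases, not the
hundreds the smoothing was designed for. Because the fit is on the logit of
the score, the injected distortion family is inverted exactly:
$(A, B) = (-1/a,\ b/a)$.

Reliability curves use **quantile binning** — cases sorted by predicted
probability (stable sort, input order breaking ties) and split into
`n_bins` contiguous bins whose sizes differ by at most one — so no bin is
starved in the score distribution's tails. Default 10 bins: coarse enough
that per-bin event rates are stable at a few thousand cases, fine enough to
resolve the miscalibration shapes the logit-affine family can produce; it
is a config knob, not a claim. Per-bin 95% CIs are Wilson intervals, chosen
for small-count behavior (Wald collapses at observed rates near 0/1, exact
intervals overcover). ECE is the count-weighted mean absolute gap between
mean predicted and observed rates over those same bins, MCE the maximum
gap; using one binning for the plot and both errors keeps the three
mutually consistent.

`calibration_shift_report()` flags a period when its post-calibration ECE
exceeds the calibration split's own post-calibration ECE by more than
`margin` (default 0.05 absolute). The reference term matters: ECE is biased
upward by binomial noise at small $n$, so comparing a period against the
reserve's in-sample ECE, rather than against zero, makes the flag
self-calibrating across data scales. The 0.05 default is a deliberate
"clinically visible deviation" scale — the shift experiments in the test
suite show it separates injected 1-logit offset drift (period ECE ≈ 0.09 at
20000 cases/period) from downsampling to a tenth of the data and from
incidence thinning (no flags), the designed contrast between genuine
calibration drift and mere data-scale effects. Thinning deserves a remark:
removing a uniform fraction of positives shifts every posterior by a
*constant* logit amount, which the Platt family absorbs exactly — that is
why reduced incidence does not, and should not, raise the flag.

## Decision stage

`select_threshold()` scans all distinct calibrated probabilities plus
$\{0, 1\}$ — the objective $|\mathrm{FNR} - \mathrm{FPR}|$ is piecewise
constant between observed values, so the grid is lossless — and minimizes
the gap between underdiagnosis (FNR) and overdiagnosis (FPR), breaking ties
toward the smallest threshold (more alerts; for these conditions a missed
case is costlier than a nuisance alert). The comparison is done in exact
integer arithmetic ($|fn \cdot n_- - fp \cdot n_+|$), so tie-breaking never
depends on floating-point noise. Alerts fire at `prob >= threshold`.

`classify_alert()` implements the five-category scheme: TN, FP, FN, TP
(alert strictly before onset) and "arguably FN/TP" (alert at or after
onset — diagnostic rather than predictive). Discharge-code labels carry no
onset time, so when onset is unknown an alert at any time during the stay
counts as TP, and all rates collapse the fifth category into TP.

`decision_curve()` evaluates the net benefit
$NB(p_t) = TP/N - (FP/N)\,p_t/(1-p_t)$ over a threshold grid against
treat-all ($\pi - (1-\pi)p_t/(1-p_t)$, crossing zero exactly at
$p_t = \pi$) and treat-none (0). Because curves start at the prevalence,
`standardize_incidence()` first raises every lower-incidence period to the
maximum period incidence by duplicating positives sampled with replacement
(the count minimizing the absolute incidence gap, ties toward fewer
duplicates; existing cases are never touched). Duplication was chosen over
synthesizing cases so that standardized curves remain functions of
genuinely observed score–label pairs.

`compare_decision_curves()` is the nonparametric between-period test: an
unpaired case-level bootstrap (resampling within each period
independently, default 2000 replicates) of $\Delta NB$ at each threshold of
interest, with two-sided $p = 2\min(P(\Delta \le 0), P(\Delta \ge 0))$
clipped to $[0,1]$. The default thresholds of interest
$\{0.01, 0.02, 0.05, 0.10, 0.15, 0.20\}$ cover the low range where alerting
for serious inpatient conditions is plausibly net-beneficial; no
multiplicity correction is applied by default (per-threshold reporting; a
`p_adjust_method` flag exists). The bootstrap is an interpretation — the
methodology literature for comparing decision curves names no single
canonical test — and it holds its size: the suite measures per-threshold
type-I error of 0.049–0.059 over 1000 null replicates.

## Numerical and degenerate-input choices

* Single-class inputs raise classed degenerate-input errors everywhere a
  rate would be undefined; `auroc_z_test()` with two zero SEs returns
  $z = 0, p = 1$ when the AUROCs agree and errors when they differ.
* `net_benefit()` refuses $p_t = 1$ (undefined odds weight); decision grids
  live in $[0, 1)$.
* Quantile bin sizes are $\lfloor n/b \rfloor$ with the remainder spread
  over the first bins; bins are deterministic given the input order.
* Platt's Newton iterations start at the identity $(-1, 0)$ and stop at
  gradient norm $< 10^{-8}$ or error after 100 iterations; the Hessian is
  floored at $10^{-12}$ per-case weight to survive separable corners.
* All randomness (generation, splits, subsampling, augmentation, bootstrap)
  flows through explicit integer seeds; identical configuration and seed
  give byte-identical cohorts and reports.

## Problem sizes in the test suite

The suite exercises parameter recovery at 50000 cases (Platt, binormal
AUROC), shift experiments at 3 × 20000, the Z-test null at 1000 replicates
of 2 × 2000, the bootstrap null at 100 runs of 2 × 5000 with 2000
replicates plus a 1000-replicate size study at 2 × 1000 — sizes at which
the Monte-Carlo error of each checked quantity is an order of magnitude
below its assertion tolerance, while the whole suite stays desk-scale.

## Known limitations

* The binormal, logit-affine drift world is a stand-in; nothing is claimed
  about the score distribution of any particular deployed model, and
  non-monotone or feature-level drift is out of scope.
* Hanley–McNeil-based Z-tests are conservative for highly discriminating
  models (above); DeLong-type variance estimation is deliberately not
  implemented.
* The calibration-shift margin (0.05 ECE) and the thresholds of interest
  are clinical-judgment defaults, exposed in configuration, not estimated
  quantities.
* Incidence standardization assumes duplicated positives are exchangeable
  with observed ones; under strong within-period heterogeneity that is an
  approximation.
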