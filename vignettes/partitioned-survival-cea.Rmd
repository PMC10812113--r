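---
title: "Methods: a partitioned survival cost-effectiveness model for first-line serplulimab in ES-SCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a partitioned survival cost-effectiveness model for first-line serplulimab in ES-SCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmcea)
```

## The decision problem

Extensive-stage small cell lung cancer (ES-SCLC) is treated first line with
platinum–etoposide chemotherapy; adding the PD-1 inhibitor serplulimab
prolongs progression-free and overall survival but at a substantial drug
acquisition cost. `psmcea` re-implements, as a tested and configurable
engine, a published Chinese-healthcare-system cost-effectiveness analysis of
serplulimab + carboplatin/etoposide versus chemotherapy alone. The engine
answers the standard question: per quality-adjusted life year (QALY) gained,
what does adding serplulimab cost, and how does that compare with a
willingness-to-pay (WTP) threshold of three times 2022 per-capita GDP,
$37,304.346/QALY?

## Model structure

The model is a three-state partitioned survival model (PSM):
progression-free (PFS), progressed disease (PD), and death. Occupancy is
read directly off the two survival curves at each cycle boundary $t$:

$$p_{\text{PFS}}(t) = \min\{S_{\text{PFS}}(t),\, S_{\text{OS}}(t)\},\qquad
  p_{\text{death}}(t) = 1 - S_{\text{OS}}(t),\qquad
  p_{\text{PD}}(t) = S_{\text{OS}}(t) - p_{\text{PFS}}(t).$$

Cycles are 3 weeks long; the horizon is 10 years, truncated to whole cycles
with the fixed calendar convention 1 year = 365.25/7 ≈ 52.18 weeks, giving
173 cycles. Where a fitted PFS curve crosses above OS it is clamped
pointwise (standard PSM practice); every clamped boundary is counted and
reported via the `clamp_events` attribute, and the count is zero for the
bundled parameters.

## Survival extrapolation

Six parametric families are supported (Weibull, log-logistic, log-normal,
exponential, Gompertz, gamma). Fitting uses maximum likelihood with right
censoring through `flexsurv`; `select_best_fit()` picks the family with the
lowest AIC (or BIC), breaking ties by parsimony and then a declared family
order so selection is deterministic. The bundled analysis uses the
log-logistic family for all four curves, in the rate form

$$S(t) = \frac{1}{1 + \lambda t^{\gamma}},\qquad
  \text{median} = (1/\lambda)^{1/\gamma}.$$

Two things the published input table does *not* state are the log-logistic
parameterization and the unit of $t$. Both are therefore configuration
choices here, prominently exposed:

* **Parameterization.** The rate form above is the only common
  parameterization under which the published $(\gamma, \lambda)$ pairs give
  medians on a clinically sensible scale; it is fixed as the package's
  log-logistic form.
* **Time unit** (`time_unit`: `cycle`, `week` or `month`). With $t$ in
  3-week cycles the implied PFS medians are closest to the trial's reported
  medians (≈5.5 vs 5.8 months in the intervention arm); with $t$ in months
  the implied OS medians are closest (≈18.2 vs 15.4 months). Neither
  reading matches both endpoints, which is the first sign that the
  published inputs and outputs are not mutually consistent (see
  *Reproduction limits* below). The frozen default is `month`, selected by
  the convention sweep described next.

## Unstated conventions and the sweep that froze the defaults

Five further modelling conventions are unstated in the source and
materially affect totals. All are implemented and switchable, and
`convention_sweep()` re-runs the base case under all 32 combinations:

| Toggle | Options (default in bold) |
|---|---|
| Survival time unit | cycle / **month** |
| Half-cycle correction | off / **on** |
| Serplulimab maintenance duration | while progression-free / **8 cycles** (≈ the trial's 5.6-month median treatment duration) |
| Adverse-event application | one-off at entry / **per on-treatment cycle** |
| Vial policy | **round up to whole vials** / exact milligrams |

The default combination is the sweep winner against the published base-case
table, scored by "most of the five headline quantities within ±15%", with
ties broken by mean absolute relative error:

```{r sweep, eval = FALSE}
ref <- c(cost_intervention = 31020.152, qaly_intervention = 1.172,
         cost_comparator = 20126.157, qaly_comparator = 0.546,
         icer = 17402.548)
head(convention_sweep(default_config(), reference = ref))
```

Under that frozen default the intervention arm reproduces within ±15%
(QALYs ≈ −5%, cost ≈ −13%); the comparator arm does not, for reasons
explained below.

## Costing

Per accrual cycle, costs attach to occupancy as follows.

* **Drug acquisition** while progression-free. Doses follow the trial
  regimen: serplulimab 4.5 mg/kg day 1; etoposide 100 mg/m² days 1–3;
  carboplatin dosed by Calvert's formula (AUC 5, dose = 5 × (CrCl + 25) mg,
  capped at 750 mg) on day 1. Chemotherapy runs for at most 4 cycles;
  serplulimab continues per the maintenance-duration toggle. The reference
  patient is 60 kg, 1.72 m², creatinine clearance value 70 (the source
  tabulates the unit as μmol/L; the number is used as-is in Calvert's
  formula and the oddity is documented rather than corrected). Under the
  default vial policy each administration is rounded up to whole
  100-mg vials.
* **Follow-up** cost per progression-free cycle.
* **Subsequent therapy** for the uptake share of progressed patients
  (44.2% / 43.4% per arm), for each patient's first 6 cycles of
  progression, then **best supportive care**; patients not taking
  subsequent therapy receive best supportive care throughout progression.
  Entries into PD are approximated by the per-cycle decline of the PFS
  curve (deaths during the 6-cycle window are ignored; the approximation is
  clamped so it never exceeds PD occupancy). The 6-cycle cap avoids
  double-counting subsequent therapy and the supportive care that the
  source states follows second-line failure; it is configurable
  (`subsequent_max_cycles`, `Inf` = unbounded).
* **Adverse events**: grade ≥3 events with >5% incidence in either arm.
  Under the default per-cycle convention each event's cost (and utility
  decrement) applies per on-treatment induction cycle, weighted by
  incidence, matching the source's "per cycle" cost labelling; the one-off
  convention (single incidence-weighted hit at model entry, decrement
  lasting one cycle) is the alternative.

## QALY accrual, discounting, incremental analysis

QALYs accrue as occupancy × state utility (PFS 0.673, PD 0.473) × cycle
length in years; costs and QALYs are both discounted at 5% per year with a
continuous exponent on the cycle start time, $(1.05)^{-t}$ (an annual step
function is available). Half-cycle correction, when on, replaces
start-of-cycle occupancy with the mean of the bounding boundaries. The
incremental comparison reports ΔCost, ΔQALY and the ICER at full precision
(the ICER is exactly ΔCost/ΔQALY in all outputs), with explicit dominance
flags and an undefined-ICER flag at ΔQALY = 0; cost-effectiveness is judged
by net monetary benefit, $\mathrm{NMB} = \mathrm{WTP}\cdot\Delta Q -
\Delta C \ge 0$, which handles all four plane quadrants and counts ties as
acceptable.

## Sensitivity analysis

**One-way (tornado).** Every distributed input is moved to its low and high
bound (the tabulated ranges, all equal to ±25% of base; ±25% where no range
is printed) with all others at base, the full model re-run, and parameters
ranked by the absolute ICER swing. A zero-width range reproduces the
base-case ICER bit-for-bit.

**Probabilistic.** 1000 Monte Carlo iterations. Each tabulated range is
read as a 95% interval, so sd = (high − low)/3.92; gamma distributions
(costs, body surface area) are parameterized by method of moments
(shape = m²/sd², rate = m/sd²), beta distributions (utilities, utility
decrements, incidences) likewise on the same mean and sd, with the sd
shrunk to the feasibility boundary (with a warning) if needed. Incidences
are sampled from beta distributions because they are probabilities, even
though the source's table labels them with the cost distribution. The
survival shape/rate parameters are held fixed, mirroring the source's
table. Draws use a single seeded generator in fixed alphabetical parameter
order, so results are reproducible cross-platform; draws violating the
configuration schema would be rejected and redrawn with a counter (the
bundled distributions cannot actually produce such draws). The
cost-effectiveness acceptability curve is the NMB-acceptable fraction over
a WTP grid.

## Synthetic cohorts

`simulate_cohort()` generates pseudo individual-patient data so the
fit/select stage is testable without trial data: OS is drawn by inverse-CDF
sampling, PFS as the minimum of the OS draw and an independent PFS-family
draw (guaranteeing PFS ≤ OS without knowing the joint distribution), with
administrative censoring at a fixed horizon; `censoring_horizon_for()`
converts a target censored fraction into that horizon via the survival
quantile. The default cohort size, 585, matches the scale of the trial the
source drew on. What these simulations emulate is sampling noise and
administrative censoring around a *correctly specified* parametric truth;
they do not emulate digitization error, non-administrative dropout, or
model misspecification, so passing recovery tests demonstrate estimator
correctness, not robustness of the published curve fits.

At n = 2000 with 15% censoring the log-logistic shape is recovered to
within a few percent, but the rate λ = scale^(−γ) amplifies estimation
error by roughly the factor γ, giving it a sampling SD near 8% — so a 10%
recovery band on λ is a ≈1σ statement that an unlucky seed will miss. The
acceptance suite keeps fixed, arbitrarily chosen seeds rather than
selecting favourable ones.

## Numerical choices

* Calendar: 1 year = 365.25/7 weeks; 1 month = 30.4375 days; horizons
  truncate to whole cycles; a horizon shorter than one cycle is an error.
* Medians use closed forms where they exist, otherwise a bracketing
  root-finder (relative tolerance 1e−9); a negative-shape Gompertz whose
  survival plateau exceeds 0.5 signals a typed no-median condition.
* Occupancy identities (states sum to 1, death nondecreasing) hold to
  1e−12 on the full grid; refining 3-week cycles to 1-week cycles moves
  discounted totals by well under 2%.
* All internal arithmetic is full precision; rounding happens only in
  printing.

## Reproduction limits

The published base case cannot be derived from the published inputs under
any single reading of them, and the package deliberately does not paper
over this:

* Under the rate-form log-logistic, both arms' survival scales by the same
  factor when the time unit changes, so the ratio of intervention to
  comparator QALYs is ≈1.3 under *every* time unit — but the published
  per-arm QALYs have ratio 2.15. No parameterization choice can reconcile
  the two.
* Diagnostically: a log-logistic reading of the published parameters in
  months reproduces the intervention arm's QALYs to within ≈3%, while a
  *Weibull* reading $S(t)=\exp(-\lambda t^{\gamma})$ of the same pairs
  reproduces the comparator arm's QALYs to within ≈2% and all four trial
  medians to within ≈1 month. The published results appear to mix
  distribution readings between arms. (Both readings are one
  `convention_sweep()`-style re-run away for a sceptical reader; the
  package's Weibull family accepts the converted scale
  $\lambda^{-1/\gamma}$ directly.)
* The comparator arm's published total cost is several times larger than
  everything that arm can accrue from the published unit costs under any
  convention combination.
* Consequently the reproduced incremental QALY is ≈0.27 at most (published:
  0.626) and the reproduced ICER exceeds the WTP threshold under every
  convention combination, so the reproduced PSA acceptability at the
  threshold is ≈0% (published: 97.40%). The corresponding acceptance tests
  are intentionally left failing with this analysis rather than being
  weakened; the engine itself satisfies its structural property suite in
  full.

## Known limitations

* The PSM reads state membership off marginal curves; it cannot represent
  treatment-switching or post-progression survival mechanisms, and the
  subsequent-therapy window uses the PFS-decline approximation described
  above.
* Survival parameter uncertainty is excluded from the PSA (as in the
  source's table), which understates decision uncertainty.
* AE disutility durations are not published; the one-off convention assumes
  one cycle, the per-cycle convention the induction window.
* Costs are health-system direct costs only; no indirect costs, and
  currency conversion is a recorded constant (6.73 RMB/USD), not a module.
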