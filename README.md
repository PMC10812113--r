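# psmcea

Partitioned survival cost-effectiveness modelling of first-line
**serplulimab + platinum–etoposide chemotherapy versus chemotherapy alone**
in extensive-stage small cell lung cancer (ES-SCLC), from the Chinese
healthcare-system perspective.

The package is aimed at health-economics analysts who want a published
immunotherapy cost-effectiveness analysis as a *re-runnable, testable
artifact*: every input lives in a validated YAML/R configuration, every
unstated modelling convention is an explicit toggle, and the base case,
tornado, and probabilistic sensitivity analysis are reproducible functions
rather than spreadsheet states.

## The model

Three health states — progression-free (PFS), progressed disease (PD),
death — with occupancy partitioned directly from parametric survival
curves at each 3-week cycle boundary *t* over a 10-year horizon
(173 cycles):

```
p_pfs(t)   = min{ S_pfs(t), S_os(t) }
p_death(t) = 1 − S_os(t)
p_pd(t)    = S_os(t) − p_pfs(t)
```

Survival uses the rate-form log-logistic, `S(t) = 1 / (1 + λ·tᵞ)` (five
other families — Weibull, log-normal, exponential, Gompertz, gamma — are
available, with maximum-likelihood fitting under right censoring and
AIC/BIC selection). Costs (drug acquisition with Calvert-formula
carboplatin dosing and vial rounding, adverse-event management, follow-up,
subsequent therapy, best supportive care) and QALYs (state utilities
0.673 / 0.473, AE disutilities) accrue per cycle and are discounted at 5%
per year. The headline statistic is the incremental cost-effectiveness
ratio, ICER = ΔCost/ΔQALY, judged against a willingness-to-pay threshold
of $37,304.346/QALY via net monetary benefit; uncertainty is handled by a
±25% one-way tornado analysis and a 1000-draw gamma/beta probabilistic
sensitivity analysis with CEAC support.

## Worked example

```r
library(psmcea)

bc <- run_base_case(default_config())
print(bc)
#> Cost-effectiveness result
#>           arm  cost_usd  qaly
#>   serplulimab 26947.160 1.110
#>  chemotherapy  9262.055 0.843
#> incremental cost :    17685.105 USD
#> incremental QALY :        0.267
#> ICER             :    66237.501 USD/QALY
#> NMB at WTP 37304.346 : -7725.018 (not cost-effective)
```

Reading: over 10 discounted years the serplulimab arm accrues 1.110 QALYs
and $26,947 in costs versus 0.843 QALYs and $9,262 for chemotherapy alone,
i.e. 0.267 QALYs gained for an extra $17,685 — an ICER of $66,238/QALY,
*above* the $37,304/QALY threshold (negative net monetary benefit). This
differs from the published conclusion; the vignette documents why the
published table cannot be reproduced from its own inputs and how the
bundled defaults were frozen by an explicit convention sweep
(`convention_sweep()`).

The survival layer is usable on its own:

```r
os <- parametric_survival("loglogistic", c(shape = 1.937, rate = 0.00363),
                          time_unit = "month")
median_survival(os)
#> [1] 18.18562
```

and the tornado ranks parameter leverage:

```r
tor <- one_way_dsa(default_config(), default_param_specs(default_config()))
head(as.data.frame(tor)[, c("param", "icer_at_low", "icer_at_high")], 3)
#>               param icer_at_low icer_at_high
#> 1 price_serplulimab    50310.45     82164.55
#> 2       utility_pfs    85326.80     54127.99
#> 3        utility_pd    67988.42     64574.50
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "run_cea.R", package = "psmcea")` with subcommands
`base`, `dsa`, `psa`, `fit`.

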