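# Documented reproduction gaps are expected failures; keep the full suite
# running past them regardless of the reporter's failure cap.
options(testthat.progress.max_fails = 1000)

# Bundled log-logistic survival parameters, one builder per arm/endpoint.
table1_models <- function(time_unit = "month") {
  list(
    serp_os   = parametric_survival("loglogistic", c(shape = 1.937, rate = 0.00363), time_unit),
    serp_pfs  = parametric_survival("loglogistic", c(shape = 2.100, rate = 0.0129),  time_unit),
    chemo_os  = parametric_survival("loglogistic", c(shape = 1.924, rate = 0.00645), time_unit),
    chemo_pfs = parametric_survival("loglogistic", c(shape = 2.520, rate = 0.0152),  time_unit)
  )
}

# one representative valid model per family, for property loops
family_zoo <- function(time_unit = "cycle") {
  list(
    parametric_survival("weibull",     c(shape = 1.4, scale = 12),        time_unit),
    parametric_survival("loglogistic", c(shape = 2.1, rate = 0.0129),     time_unit),
    parametric_survival("lognormal",   c(meanlog = 2.2, sdlog = 0.8),     time_unit),
    parametric_survival("exponential", c(rate = 0.07),                    time_unit),
    parametric_survival("gompertz",    c(shape = 0.08, rate = 0.05),      time_unit),
    parametric_survival("gamma",       c(shape = 1.8, rate = 0.12),       time_unit)
  )
}

# published base-case values used by the reproduction checks
published_base_case <- c(cost_intervention = 31020.152,
                         qaly_intervention = 1.172,
                         cost_comparator = 20126.157,
                         qaly_comparator = 0.546,
                         icer = 17402.548)

# a short hand-built trace: fully progression-free for 4 cycles, then dead
forced_trace <- function(n_pfs = 4, n_total = 5) {
  k <- 0:n_total
  tr <- data.frame(cycle = k, t_model = k,
                   t_years = k * 3 / (365.25 / 7),
                   p_pfs = as.numeric(k < n_pfs),
                   p_pd = 0,
                   p_death = as.numeric(k >= n_pfs))
  attr(tr, "clamp_events") <- 0L
  class(tr) <- c("cycle_trace", "data.frame")
  tr
}

quiet_utilities <- function(expr) suppressWarnings(expr)
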