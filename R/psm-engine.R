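WEEKS_PER_YEAR <- 365.25 / 7      # 52.17857...
DAYS_PER_MONTH <- 30.4375         # 365.25 / 12

#' Model settings
#'
#' Global settings of the partitioned survival model: cycle length, horizon,
#' discounting and the willingness-to-pay threshold.  Defaults reflect the
#' bundled ES-SCLC analysis: 3-week cycles, a 10-year horizon, 5% annual
#' discounting of both costs and QALYs, and a threshold of three times 2022
#' Chinese per-capita GDP ($37,304.346/QALY).
#'
#' @param cycle_length_weeks Cycle length in weeks (> 0).
#' @param horizon_years Time horizon in years (> 0); truncated to whole
#'   cycles using 1 year = 365.25/7 weeks.
#' @param annual_discount_rate Annual discount rate in `[0, 1)`.
#' @param wtp_per_qaly Willingness-to-pay threshold (USD per QALY).
#' @param half_cycle_correction If `TRUE`, accrual uses mid-cycle occupancy
#'   (the mean of the two bounding cycle boundaries) instead of
#'   start-of-cycle occupancy.
#' @param discounting `"continuous"` applies `(1+r)^(-t)` at the exact cycle
#'   start time; `"annual_step"` uses `(1+r)^(-floor(t))`.
#' @return A `model_settings` object.
#' @export
model_settings <- function(cycle_length_weeks = 3,
                           horizon_years = 10,
                           annual_discount_rate = 0.05,
                           wtp_per_qaly = 37304.346,
                           half_cycle_correction = FALSE,
                           discounting = c("continuous", "annual_step")) {
  discounting <- match.arg(discounting)
  stopifnot(cycle_length_weeks > 0, horizon_years > 0,
            annual_discount_rate >= 0, annual_discount_rate < 1,
            wtp_per_qaly > 0, is.logical(half_cycle_correction))
  s <- structure(list(cycle_length_weeks = cycle_length_weeks,
                      horizon_years = horizon_years,
                      annual_discount_rate = annual_discount_rate,
                      wtp_per_qaly = wtp_per_qaly,
                      half_cycle_correction = isTRUE(half_cycle_correction),
                      discounting = discounting),
                 class = "model_settings")
  if (n_cycles(s) < 1)
    stop("horizon shorter than one cycle: no full cycle fits the horizon")
  s
}

#' Number of whole model cycles on the horizon
#'
#' The horizon is truncated to whole cycles: `floor(horizon_weeks /
#' cycle_length_weeks)` with 1 year = 365.25/7 weeks.  A horizon shorter
#' than one cycle is rejected at construction time.
#'
#' @param settings A [model_settings] object.
#' @return Integer cycle count (173 for the default configuration).
#' @export
n_cycles <- function(settings) {
  stopifnot(inherits(settings, "model_settings"))
  as.integer(floor(settings$horizon_years * WEEKS_PER_YEAR /
                   settings$cycle_length_weeks))
}

#' Cycle length in years
#' @param settings A [model_settings] object.
#' @return Length of one cycle in years.
#' @export
cycle_length_years <- function(settings) {
  settings$cycle_length_weeks / WEEKS_PER_YEAR
}

# cycle boundaries (0..n_cycles) converted into a survival model's time unit
.boundary_times <- function(settings, time_unit) {
  k <- 0:n_cycles(settings)
  w <- k * settings$cycle_length_weeks
  switch(time_unit,
         cycle = k,
         week  = w,
         month = w * 7 / DAYS_PER_MONTH)
}

#' Build the three-state occupancy trace
#'
#' Partitioned survival occupancy at every cycle boundary: membership of the
#' progression-free state is `min(S_pfs(t), S_os(t))`, death is
#' `1 - S_os(t)`, and progressive disease is the remainder.  Where the
#' fitted PFS curve crosses above OS it is clamped to OS; every clamped
#' boundary is counted and reported in the `clamp_events` attribute (0 for
#' the bundled parameters).
#'
#' @param os_model,pfs_model [parametric_survival] models for overall and
#'   progression-free survival, in the same time unit.
#' @param settings A [model_settings] object.
#' @return A data frame of class `cycle_trace` with one row per cycle
#'   boundary `k = 0..n_cycles`: `cycle`, `t_model` (boundary in the
#'   survival models' unit), `t_years`, `p_pfs`, `p_pd`, `p_death`.
#' @export
build_trace <- function(os_model, pfs_model, settings) {
  stopifnot(inherits(os_model, "parametric_survival"),
            inherits(pfs_model, "parametric_survival"),
            inherits(settings, "model_settings"))
  if (os_model$time_unit != pfs_model$time_unit)
    stop("OS and PFS models use different time units (",
         os_model$time_unit, " vs ", pfs_model$time_unit, ")")
  tt <- .boundary_times(settings, os_model$time_unit)
  s_os  <- survival_at(os_model, tt)
  s_pfs <- survival_at(pfs_model, tt)
  clamped <- s_pfs > s_os
  s_pfs <- pmin(s_pfs, s_os)
  k <- 0:n_cycles(settings)
  trace <- data.frame(cycle = k,
                      t_model = tt,
                      t_years = k * cycle_length_years(settings),
                      p_pfs = s_pfs,
                      p_pd = s_os - s_pfs,
                      p_death = 1 - s_os)
  attr(trace, "clamp_events") <- sum(clamped)
  class(trace) <- c("cycle_trace", "data.frame")
  trace
}

#' Per-cycle occupancy weights used for accrual
#'
#' Costs and QALYs accrue over the `n_cycles` intervals between boundaries.
#' Without half-cycle correction the weight of cycle `k` is the occupancy at
#' its start boundary; with correction it is the mean of the two bounding
#' boundaries.
#'
#' @param trace A `cycle_trace`.
#' @param settings A [model_settings] object.
#' @return List with numeric vectors `pfs`, `pd`, `alive` (length
#'   `n_cycles`) and `t_years` (cycle start times).
#' @export
occupancy_weights <- function(trace, settings) {
  n <- nrow(trace) - 1L
  if (settings$half_cycle_correction) {
    pfs <- (trace$p_pfs[1:n] + trace$p_pfs[2:(n + 1)]) / 2
    pd  <- (trace$p_pd[1:n]  + trace$p_pd[2:(n + 1)]) / 2
  } else {
    pfs <- trace$p_pfs[1:n]
    pd  <- trace$p_pd[1:n]
  }
  list(pfs = pfs, pd = pd, alive = pfs + pd, t_years = trace$t_years[1:n])
}
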