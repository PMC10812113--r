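#' Simulate right-censored times from one survival model
#'
#' Inverse-CDF sampling: `t = S^{-1}(U)` with `U ~ Uniform(0, 1)`, followed
#' by administrative censoring at a fixed horizon.
#'
#' @param model A [parametric_survival].
#' @param n Number of observations.
#' @param censoring_horizon Administrative censoring time in the model's
#'   time unit (`Inf` = no censoring).
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @return Data frame `time`, `event` (`TRUE` = event observed).
#' @export
simulate_survival <- function(model, n, censoring_horizon = Inf, seed = NULL) {
  stopifnot(inherits(model, "parametric_survival"), n >= 1,
            censoring_horizon >= 0)
  if (!is.null(seed)) set.seed(seed)
  t_event <- quantile_survival(model, runif(n))
  event <- t_event <= censoring_horizon
  data.frame(time = pmin(t_event, censoring_horizon), event = event)
}

#' Synthetic-cohort specification
#'
#' Defines a pseudo individual-patient cohort with coupled PFS and OS
#' endpoints drawn from parametric families, standing in for trial data
#' when exercising the fitting and selection stage.
#'
#' @param n_patients Cohort size (585 emulates the source trial).
#' @param os_model,pfs_model [parametric_survival] generating models (same
#'   time unit).
#' @param censoring_horizon Administrative censoring time (model units).
#' @param seed Integer seed.
#' @return A `sim_cohort_spec`.
#' @export
sim_cohort_spec <- function(n_patients = 585, os_model, pfs_model,
                            censoring_horizon = Inf, seed = 1) {
  stopifnot(n_patients >= 1,
            inherits(os_model, "parametric_survival"),
            inherits(pfs_model, "parametric_survival"),
            censoring_horizon >= 0)
  if (os_model$time_unit != pfs_model$time_unit)
    stop("OS and PFS generating models must share a time unit")
  structure(list(n_patients = n_patients, os_model = os_model,
                 pfs_model = pfs_model,
                 censoring_horizon = censoring_horizon, seed = seed),
            class = "sim_cohort_spec")
}

#' Simulate a coupled PFS/OS cohort
#'
#' OS is drawn first; PFS is the minimum of the OS draw and an independent
#' draw from the PFS family, which guarantees `PFS <= OS` for every patient
#' without requiring the (unreported) joint distribution.  Both endpoints
#' are administratively censored at the horizon.
#'
#' @param spec A [sim_cohort_spec].
#' @return Data frame `pfs_time`, `pfs_event`, `os_time`, `os_event`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  os <- quantile_survival(spec$os_model, runif(n))
  pfs <- pmin(os, quantile_survival(spec$pfs_model, runif(n)))
  h <- spec$censoring_horizon
  data.frame(pfs_time = pmin(pfs, h), pfs_event = pfs <= h,
             os_time = pmin(os, h), os_event = os <= h)
}

#' Censoring horizon for a target censored fraction
#'
#' With administrative censoring only, the censored fraction equals the
#' survivor function at the horizon, so the horizon achieving a target
#' fraction is the corresponding survival quantile.
#'
#' @param model Generating [parametric_survival].
#' @param censored_fraction Target fraction censored, in `(0, 1)`.
#' @return Horizon in the model's time unit.
#' @export
censoring_horizon_for <- function(model, censored_fraction) {
  stopifnot(censored_fraction > 0, censored_fraction < 1)
  quantile_survival(model, censored_fraction)
}

#' Simulate-fit-select round trip
#'
#' The module's harness for the fitting stage: simulate a censored sample
#' from a known generating model, fit all candidate families, select by
#' information criterion, and report whether the generating family won and
#' how close the recovered parameters are.
#'
#' @param model Generating [parametric_survival].
#' @param n Sample size (a `low_power` flag is set below 1000).
#' @param censoring_horizon Administrative censoring time (model units).
#' @param seed Integer seed.
#' @param families Families to screen (default: all six).
#' @param criterion `"aic"` or `"bic"`.
#' @return List: `reports` (all fits), `selected` (winning `fit_report`),
#'   `generating_family_selected`, `param_rel_error` (relative errors of
#'   the generating family's fit against truth), `low_power`.
#' @export
roundtrip_check <- function(model, n = 2000, censoring_horizon = Inf,
                            seed = 1, families = SURVIVAL_FAMILIES,
                            criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  dat <- simulate_survival(model, n, censoring_horizon, seed)
  reports <- lapply(families, function(f)
    fit_parametric(dat$time, dat$event, f, model$time_unit))
  names(reports) <- families
  best <- select_best_fit(reports, criterion)
  rel_err <- if (model$family %in% families) {
    fitted <- reports[[model$family]]$params
    abs(fitted - model$params) / abs(model$params)
  } else NULL
  list(reports = reports, selected = best,
       generating_family_selected = best$family == model$family,
       param_rel_error = rel_err,
       n = n, n_censored = sum(!dat$event),
       low_power = n < 1000)
}
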