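.settings_from_config <- function(config) {
  s <- config$settings
  model_settings(cycle_length_weeks = s$cycle_length_weeks,
                 horizon_years = s$horizon_years,
                 annual_discount_rate = s$annual_discount_rate,
                 wtp_per_qaly = s$wtp_per_qaly,
                 half_cycle_correction = isTRUE(s$half_cycle_correction),
                 discounting = s$discounting)
}

.model_from_config <- function(m, time_unit) {
  pars <- unlist(m[setdiff(names(m), "family")])
  parametric_survival(m$family, pars, time_unit)
}

.prices_from_config <- function(config) {
  lapply(stats::setNames(names(config$prices), names(config$prices)),
         function(d) drug_price(d, config$prices[[d]]$pack_mg,
                                config$prices[[d]]$price))
}

.regimen_from_config <- function(arm_cfg) {
  comps <- list(
    regimen_component("etoposide", "per_m2", 100, n_admin = 3,
                      phase = "induction"),
    regimen_component("carboplatin", "calvert", 5, n_admin = 1,
                      phase = "induction", cap_mg = 750)
  )
  if (isTRUE(arm_cfg$has_serplulimab))
    comps <- c(comps, list(
      regimen_component("serplulimab", "per_kg", 4.5, n_admin = 1,
                        phase = "maintenance")))
  regimen(comps,
          chemo_max_cycles = arm_cfg$chemo_max_cycles,
          maintenance_max_cycles = arm_cfg$maintenance_max_cycles)
}

.arm_from_config <- function(config, arm_name) {
  arm_cfg <- config$arms[[arm_name]]
  if (is.null(arm_cfg)) stop("no arm named '", arm_name, "' in configuration")
  ev <- names(config$ae_costs)
  arm_spec(
    name = arm_name,
    os_model = .model_from_config(arm_cfg$os, config$time_unit),
    pfs_model = .model_from_config(arm_cfg$pfs, config$time_unit),
    regimen = .regimen_from_config(arm_cfg),
    ae = ae_profile(ev,
                    incidence = unlist(arm_cfg$ae_incidence)[ev],
                    cost = unlist(config$ae_costs)[ev],
                    disutility = unlist(config$ae_disutilities)[ev]),
    subsequent_uptake = arm_cfg$subsequent_uptake
  )
}

#' Evaluate one treatment arm
#'
#' Builds the occupancy trace, the per-cycle cost schedule and the
#' discounted totals for one arm of a configuration.
#'
#' @param config A `study_config`.
#' @param arm_name Name of an entry of `config$arms`.
#' @return List with the `arm_spec`, `trace`, `schedule`, `total_cost` and
#'   `total_qaly`.
#' @export
evaluate_arm <- function(config, arm_name) {
  settings <- .settings_from_config(config)
  arm <- .arm_from_config(config, arm_name)
  pat <- patient(config$patient$weight_kg, config$patient$bsa_m2,
                 config$patient$crcl)
  oc <- other_costs(config$other_costs$subsequent_per_cycle,
                    config$other_costs$followup_per_cycle,
                    config$other_costs$bsc_per_cycle)
  prices <- .prices_from_config(config)
  trace <- build_trace(arm$os_model, arm$pfs_model, settings)
  sched <- cycle_cost_schedule(
    arm, trace, pat, oc, prices, settings,
    vial_policy = config$conventions$vial_policy,
    ae_application = config$conventions$ae_application,
    subsequent_max_cycles = config$conventions$subsequent_max_cycles)
  util <- utility_set(config$utilities$pfs, config$utilities$pd)
  acc <- accrue(trace, sched, util, arm$ae, settings,
                ae_application = config$conventions$ae_application,
                on_treatment_cycles = arm$regimen$chemo_max_cycles)
  list(arm = arm, trace = trace, schedule = sched,
       total_cost = acc$total_cost, total_qaly = acc$total_qaly,
       settings = settings)
}

#' Run the base-case analysis
#'
#' Evaluates every arm of the configuration and computes the incremental
#' comparison of the first arm (intervention) against the second
#' (comparator).
#'
#' @param config A `study_config` (default: the bundled configuration).
#' @param intervention,comparator Arm names; defaults are the first and
#'   second entries of `config$arms`.
#' @return List of class `base_case` with per-arm evaluations (`arms`) and
#'   the `ce_result` (`incremental`).
#' @export
run_base_case <- function(config = default_config(),
                          intervention = names(config$arms)[1],
                          comparator = names(config$arms)[2]) {
  a <- evaluate_arm(config, intervention)
  b <- evaluate_arm(config, comparator)
  res <- incremental(a, b, a$settings, labels = c(intervention, comparator))
  structure(list(arms = stats::setNames(list(a, b),
                                        c(intervention, comparator)),
                 incremental = res, config = config),
            class = "base_case")
}

#' @export
print.base_case <- function(x, ...) {
  print(x$incremental)
  invisible(x)
}

#' Sweep the unstated modelling conventions
#'
#' The source analysis leaves several conventions unstated: the time unit of
#' the survival parameters, half-cycle correction, the duration of
#' serplulimab maintenance, how adverse-event costs/disutilities are
#' applied, and whether partial vials are wasted.  This sweep re-runs the
#' base case under every combination and, when published reference values
#' are supplied, scores each combination by mean absolute relative error.
#'
#' @param config Base configuration.
#' @param reference Optional named numeric vector with elements
#'   `cost_intervention`, `qaly_intervention`, `cost_comparator`,
#'   `qaly_comparator`, `icer` to score combinations against.
#' @param maintenance_options Maintenance duration options (cycles) for the
#'   intervention arm; default unlimited-while-progression-free vs a fixed
#'   8-cycle course (about 5.6 months).
#' @param tol Relative tolerance used for the `n_within_tol` count when a
#'   reference is supplied (default 0.15).
#' @return Data frame, one row per convention combination, with the per-arm
#'   totals, incremental results and (if `reference` given) the score
#'   columns `n_within_tol` and `mean_abs_rel_err`, sorted best-first
#'   (most reference quantities within tolerance, then lowest mean error).
#' @export
convention_sweep <- function(config = default_config(), reference = NULL,
                             maintenance_options = c(Inf, 8), tol = 0.15) {
  grid <- expand.grid(time_unit = c("cycle", "month"),
                      half_cycle_correction = c(FALSE, TRUE),
                      maintenance_max_cycles = maintenance_options,
                      ae_application = c("one_off", "per_cycle"),
                      vial_policy = c("round_up_vials", "exact_mg"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg <- config
    cfg$time_unit <- g$time_unit
    cfg$settings$half_cycle_correction <- g$half_cycle_correction
    cfg$conventions$ae_application <- g$ae_application
    cfg$conventions$vial_policy <- g$vial_policy
    cfg$arms[[1]]$maintenance_max_cycles <- g$maintenance_max_cycles
    bc <- run_base_case(cfg)
    r <- bc$incremental
    out <- data.frame(g,
      cost_intervention = r$cost[1], qaly_intervention = r$qaly[1],
      cost_comparator = r$cost[2], qaly_comparator = r$qaly[2],
      incremental_cost = r$incremental_cost,
      incremental_qaly = r$incremental_qaly,
      icer = r$icer, cost_effective_at_wtp = r$cost_effective_at_wtp,
      stringsAsFactors = FALSE)
    if (!is.null(reference)) {
      got <- c(out$cost_intervention, out$qaly_intervention,
               out$cost_comparator, out$qaly_comparator, out$icer)
      ref <- reference[c("cost_intervention", "qaly_intervention",
                         "cost_comparator", "qaly_comparator", "icer")]
      err <- abs(got - ref) / abs(ref)
      out$n_within_tol <- sum(err <= tol)
      out$mean_abs_rel_err <- mean(err)
    }
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(reference))
    out <- out[order(-out$n_within_tol, out$mean_abs_rel_err), ]
  rownames(out) <- NULL
  out
}
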