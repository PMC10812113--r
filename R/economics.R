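#' Health-state utilities
#'
#' @param u_pfs Utility of the progression-free state (default 0.673).
#' @param u_pd Utility of the progressed state (default 0.473).
#' @return A `utility_set`.  `u_pfs < u_pd` is unusual and triggers a
#'   warning, not an error.
#' @export
utility_set <- function(u_pfs = 0.673, u_pd = 0.473) {
  stopifnot(u_pfs >= 0, u_pfs <= 1, u_pd >= 0, u_pd <= 1)
  if (u_pfs < u_pd)
    warning("progression-free utility below progressed-disease utility")
  structure(list(u_pfs = u_pfs, u_pd = u_pd), class = "utility_set")
}

#' Discount factor at a cycle start
#'
#' Under `"continuous"` discounting the factor is `(1+r)^(-t)` with `t` the
#' exact cycle start time in years; under `"annual_step"` it is
#' `(1+r)^(-floor(t))`.
#'
#' @param cycle_index Cycle index (0-based), possibly a vector.
#' @param settings A [model_settings].
#' @return Discount factors in `(0, 1]`.
#' @export
discount_factor <- function(cycle_index, settings) {
  stopifnot(all(cycle_index >= 0))
  t_years <- cycle_index * cycle_length_years(settings)
  r <- settings$annual_discount_rate
  expo <- if (settings$discounting == "annual_step") floor(t_years) else t_years
  (1 + r)^(-expo)
}

#' Discounted cost and QALY accrual for one arm
#'
#' Per accrual cycle, the QALY increment is
#' `(p_pfs * u_pfs + p_pd * u_pd) * cycle_length_years * discount_factor`;
#' the cost increment is the undiscounted schedule total times the same
#' discount factor.  Adverse-event disutility is applied per
#' `ae_application`: as a one-off incidence-weighted decrement lasting one
#' cycle at model entry, or as a per-cycle utility decrement on
#' progression-free occupancy during the induction window.
#'
#' @param trace A `cycle_trace`.
#' @param cost_schedule Data frame from [cycle_cost_schedule()] (or any data
#'   frame with a `total` column of length `n_cycles`).
#' @param utilities A [utility_set].
#' @param ae An [ae_profile].
#' @param settings A [model_settings].
#' @param ae_application `"one_off"` or `"per_cycle"`.
#' @param on_treatment_cycles Induction window length used by the per-cycle
#'   adverse-event convention (default 4).
#' @return List with `total_cost`, `total_qaly`, and the per-cycle
#'   discounted increment vectors.
#' @export
accrue <- function(trace, cost_schedule, utilities, ae, settings,
                   ae_application = c("one_off", "per_cycle"),
                   on_treatment_cycles = 4) {
  ae_application <- match.arg(ae_application)
  stopifnot(inherits(trace, "cycle_trace"), inherits(utilities, "utility_set"),
            inherits(settings, "model_settings"))
  w <- occupancy_weights(trace, settings)
  n <- length(w$pfs)
  if (nrow(cost_schedule) != n)
    stop("cost schedule length (", nrow(cost_schedule),
         ") does not match the number of accrual cycles (", n, ")")
  df <- discount_factor(seq_len(n) - 1L, settings)
  cyc_yr <- cycle_length_years(settings)

  ae_exp_disu <- sum(ae$incidence * ae$disutility)
  q_undisc <- (w$pfs * utilities$u_pfs + w$pd * utilities$u_pd) * cyc_yr
  if (ae_application == "one_off") {
    # one-off decrement assumed to last one model cycle
    q_undisc[1] <- q_undisc[1] - ae_exp_disu * cyc_yr
  } else {
    k <- seq_len(n) - 1L
    q_undisc <- q_undisc -
      ae_exp_disu * w$pfs * (k < on_treatment_cycles) * cyc_yr
  }
  qaly_inc <- q_undisc * df
  cost_inc <- cost_schedule$total * df
  list(total_cost = sum(cost_inc), total_qaly = sum(qaly_inc),
       cost_increments = cost_inc, qaly_increments = qaly_inc)
}

#' Incremental cost-effectiveness comparison
#'
#' @param intervention,comparator Lists (or [accrue()] results) carrying
#'   `total_cost` and `total_qaly`, computed under identical settings.
#' @param settings A [model_settings] (supplies the WTP threshold).
#' @param labels Length-2 character vector of arm labels.
#' @return A `ce_result` with per-arm totals, incremental cost, incremental
#'   QALY, the ICER (NA with a `dominance` flag where undefined), and
#'   `cost_effective_at_wtp` judged by net monetary benefit
#'   `wtp * dQALY - dCost >= 0`.
#' @export
incremental <- function(intervention, comparator, settings,
                        labels = c("intervention", "comparator")) {
  stopifnot(inherits(settings, "model_settings"))
  d_cost <- intervention$total_cost - comparator$total_cost
  d_qaly <- intervention$total_qaly - comparator$total_qaly
  dominance <- if (d_qaly > 0 && d_cost <= 0) "dominant"
               else if (d_qaly < 0 && d_cost >= 0) "dominated"
               else "none"
  icer <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  nmb <- settings$wtp_per_qaly * d_qaly - d_cost
  structure(list(
    labels = labels,
    cost = c(intervention$total_cost, comparator$total_cost),
    qaly = c(intervention$total_qaly, comparator$total_qaly),
    incremental_cost = d_cost,
    incremental_qaly = d_qaly,
    icer = icer,
    icer_defined = d_qaly != 0,
    dominance = dominance,
    nmb = nmb,
    wtp_per_qaly = settings$wtp_per_qaly,
    cost_effective_at_wtp = nmb >= 0
  ), class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness result\n")
  tab <- data.frame(arm = x$labels, cost_usd = round(x$cost, 3),
                    qaly = round(x$qaly, 3))
  print(tab, row.names = FALSE)
  cat(sprintf("incremental cost : %12.3f USD\n", x$incremental_cost))
  cat(sprintf("incremental QALY : %12.3f\n", x$incremental_qaly))
  if (x$icer_defined)
    cat(sprintf("ICER             : %12.3f USD/QALY\n", x$icer))
  else
    cat("ICER             : undefined (zero incremental QALY)\n")
  if (x$dominance != "none") cat("dominance        :", x$dominance, "\n")
  cat(sprintf("NMB at WTP %.3f : %.3f (%scost-effective)\n",
              x$wtp_per_qaly, x$nmb,
              if (x$cost_effective_at_wtp) "" else "not "))
  invisible(x)
}

#' @export
as.data.frame.ce_result <- function(x, ...) {
  data.frame(arm = x$labels, cost = x$cost, qaly = x$qaly,
             incremental_cost = c(x$incremental_cost, NA),
             incremental_qaly = c(x$incremental_qaly, NA),
             icer = c(x$icer, NA), stringsAsFactors = FALSE)
}
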