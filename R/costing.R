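#' Reference patient
#'
#' Anthropometrics used for body-weight, body-surface-area and renal dosing.
#' Defaults follow the standardized dosing model of the bundled analysis:
#' 60 kg, 1.72 m^2, creatinine clearance value 70.  The source tabulates the
#' creatinine clearance as "70 umol/L"; the number 70 is used directly in
#' Calvert's formula (as if mL/min) and the unit oddity is documented, not
#' corrected.
#'
#' @param weight_kg Body weight in kg.
#' @param bsa_m2 Body surface area in m^2.
#' @param crcl Creatinine clearance value used by Calvert's formula.
#' @return A `patient` object.
#' @export
patient <- function(weight_kg = 60, bsa_m2 = 1.72, crcl = 70) {
  stopifnot(weight_kg > 0, bsa_m2 > 0, crcl > 0)
  structure(list(weight_kg = weight_kg, bsa_m2 = bsa_m2, crcl = crcl),
            class = "patient")
}

#' Drug price
#' @param name Drug name.
#' @param pack_mg Vial/pack size in mg.
#' @param price_per_pack Price of one vial/pack in USD.
#' @return A `drug_price` object.
#' @export
drug_price <- function(name, pack_mg, price_per_pack) {
  stopifnot(pack_mg > 0, price_per_pack >= 0)
  structure(list(name = name, pack_mg = pack_mg,
                 price_per_pack = price_per_pack),
            class = "drug_price")
}

#' Carboplatin dose by Calvert's formula
#'
#' `dose (mg) = AUC x (CrCl + 25)`, capped at a maximum absolute dose.
#'
#' @param patient A [patient] object.
#' @param auc Target area under the concentration-time curve (mg/mL/min),
#'   default 5.
#' @param cap_mg Maximum dose, default 750 mg.
#' @return Dose in mg.
#' @examples
#' carboplatin_dose(patient(crcl = 70))   # 475
#' carboplatin_dose(patient(crcl = 130))  # capped at 750
#' @export
carboplatin_dose <- function(patient, auc = 5, cap_mg = 750) {
  stopifnot(inherits(patient, "patient"), auc > 0, cap_mg > 0)
  min(auc * (patient$crcl + 25), cap_mg)
}

#' Regimen component
#'
#' One drug within a regimen.  `basis` determines how the per-administration
#' dose in mg is derived from the reference patient: `"per_kg"` (dose in
#' mg/kg), `"per_m2"` (mg/m^2), `"calvert"` (`dose` is the target AUC,
#' Calvert formula with `cap_mg`) or `"flat"` (mg).  `n_admin` is the number
#' of administrations per cycle (etoposide: 3 days).  `phase` is
#' `"induction"` (given for at most `chemo_max_cycles`) or `"maintenance"`
#' (given from cycle 0 while progression-free, up to
#' `maintenance_max_cycles`).
#'
#' @param drug Drug name, matching a price list entry.
#' @param basis Dosing basis (see above).
#' @param dose Dose on that basis.
#' @param n_admin Administrations per cycle.
#' @param phase `"induction"` or `"maintenance"`.
#' @param cap_mg Dose cap for `"calvert"` components.
#' @return A `regimen_component`.
#' @export
regimen_component <- function(drug, basis = c("per_kg", "per_m2", "calvert", "flat"),
                              dose, n_admin = 1,
                              phase = c("induction", "maintenance"),
                              cap_mg = Inf) {
  basis <- match.arg(basis); phase <- match.arg(phase)
  stopifnot(dose >= 0, n_admin >= 1)
  structure(list(drug = drug, basis = basis, dose = dose,
                 n_admin = n_admin, phase = phase, cap_mg = cap_mg),
            class = "regimen_component")
}

#' Treatment regimen
#'
#' @param components List of [regimen_component] objects.
#' @param chemo_max_cycles Maximum number of cycles for induction
#'   (chemotherapy) components; 4 in the bundled analysis.
#' @param maintenance_max_cycles Maximum number of cycles for maintenance
#'   components; `Inf` means "for as long as progression-free".
#' @return A `regimen` object.
#' @export
regimen <- function(components, chemo_max_cycles = 4,
                    maintenance_max_cycles = Inf) {
  stopifnot(all(vapply(components, inherits, TRUE, "regimen_component")),
            chemo_max_cycles >= 0, maintenance_max_cycles >= 0)
  structure(list(components = components,
                 chemo_max_cycles = chemo_max_cycles,
                 maintenance_max_cycles = maintenance_max_cycles),
            class = "regimen")
}

#' Adverse-event profile
#'
#' Grade >= 3 adverse events with incidence above 5% in either arm, with
#' their management cost and utility decrement.
#'
#' @param name Character vector of event names.
#' @param incidence Incidence proportions in `[0, 1]`.
#' @param cost Management cost per event (USD, >= 0).
#' @param disutility Utility decrement per event in `[0, 1]`.
#' @return Data frame of class `ae_profile`.
#' @export
ae_profile <- function(name, incidence, cost, disutility) {
  stopifnot(all(incidence >= 0 & incidence <= 1), all(cost >= 0),
            all(disutility >= 0 & disutility <= 1))
  structure(data.frame(name = name, incidence = incidence, cost = cost,
                       disutility = disutility, stringsAsFactors = FALSE),
            class = c("ae_profile", "data.frame"))
}

#' Non-drug cost inputs
#'
#' @param subsequent_per_cycle Subsequent (second-line) therapy cost per
#'   cycle, USD.
#' @param followup_per_cycle Routine follow-up cost per progression-free
#'   cycle, USD.
#' @param bsc_per_cycle Best-supportive-care cost per progressed cycle, USD.
#' @return An `other_costs` object.
#' @export
other_costs <- function(subsequent_per_cycle = 854.050,
                        followup_per_cycle = 55.600,
                        bsc_per_cycle = 359.524) {
  stopifnot(subsequent_per_cycle >= 0, followup_per_cycle >= 0,
            bsc_per_cycle >= 0)
  structure(list(subsequent_per_cycle = subsequent_per_cycle,
                 followup_per_cycle = followup_per_cycle,
                 bsc_per_cycle = bsc_per_cycle),
            class = "other_costs")
}

#' Treatment arm specification
#'
#' @param name Arm label.
#' @param os_model,pfs_model [parametric_survival] models for the arm.
#' @param regimen A [regimen].
#' @param ae An [ae_profile].
#' @param subsequent_uptake Fraction of progressed patients receiving
#'   subsequent therapy (0.442 serplulimab arm / 0.434 chemotherapy arm).
#' @return An `arm_spec` object.
#' @export
arm_spec <- function(name, os_model, pfs_model, regimen, ae,
                     subsequent_uptake) {
  stopifnot(inherits(os_model, "parametric_survival"),
            inherits(pfs_model, "parametric_survival"),
            inherits(regimen, "regimen"), inherits(ae, "ae_profile"),
            subsequent_uptake >= 0, subsequent_uptake <= 1)
  structure(list(name = name, os_model = os_model, pfs_model = pfs_model,
                 regimen = regimen, ae = ae,
                 subsequent_uptake = subsequent_uptake),
            class = "arm_spec")
}

# per-administration dose in mg for one component
.component_dose_mg <- function(comp, patient) {
  switch(comp$basis,
    per_kg  = comp$dose * patient$weight_kg,
    per_m2  = comp$dose * patient$bsa_m2,
    calvert = min(comp$dose * (patient$crcl + 25), comp$cap_mg),
    flat    = comp$dose)
}

# cost of one administration of `dose_mg` of a priced drug
.admin_cost <- function(dose_mg, price, vial_policy) {
  packs <- dose_mg / price$pack_mg
  if (vial_policy == "round_up_vials") packs <- ceiling(packs)
  packs * price$price_per_pack
}

#' Drug acquisition cost of one on-treatment cycle
#'
#' Converts each regimen component's dose into vials and sums the cost.
#' Under `"round_up_vials"` each administration is rounded up to whole
#' vials (wastage); `"exact_mg"` prices the exact milligrams.
#'
#' @param regimen A [regimen].
#' @param prices Named list of [drug_price] objects (names = drug names).
#' @param patient A [patient].
#' @param vial_policy `"round_up_vials"` (default) or `"exact_mg"`.
#' @param phase Which components to price: `"all"` (an induction cycle, the
#'   default), `"induction"` only, or `"maintenance"` only.
#' @return Cost in USD of one such cycle.
#' @examples
#' pr <- list(serplulimab = drug_price("serplulimab", 100, 812.209))
#' rg <- regimen(list(regimen_component("serplulimab", "per_kg", 4.5,
#'                                      phase = "maintenance")))
#' drug_cost_per_cycle(rg, pr, patient())  # 3 vials -> 2436.627
#' @export
drug_cost_per_cycle <- function(regimen, prices, patient,
                                vial_policy = c("round_up_vials", "exact_mg"),
                                phase = c("all", "induction", "maintenance")) {
  vial_policy <- match.arg(vial_policy); phase <- match.arg(phase)
  stopifnot(inherits(regimen, "regimen"), inherits(patient, "patient"))
  comps <- regimen$components
  if (phase != "all")
    comps <- Filter(function(cp) cp$phase == phase, comps)
  total <- 0
  for (cp in comps) {
    if (is.null(prices[[cp$drug]]))
      stop("no price entry for drug '", cp$drug, "'")
    total <- total + cp$n_admin *
      .admin_cost(.component_dose_mg(cp, patient), prices[[cp$drug]], vial_policy)
  }
  total
}

#' Per-cycle cost schedule for one arm
#'
#' Translates state occupancy into undiscounted per-cycle costs:
#' \itemize{
#'   \item drug acquisition while progression-free (induction components for
#'     at most `chemo_max_cycles`, maintenance components up to
#'     `maintenance_max_cycles`);
#'   \item follow-up cost on progression-free occupancy;
#'   \item subsequent-therapy cost on the uptake share of progressed
#'     occupancy for each patient's first `subsequent_max_cycles` cycles of
#'     progression (entries into the progressed state are approximated by
#'     the decline of the progression-free curve);
#'   \item best-supportive-care cost on the remaining progressed occupancy;
#'   \item adverse-event management cost, either as a one-off
#'     incidence-weighted cost at model entry (`ae_application =
#'     "one_off"`) or per on-treatment cycle (`"per_cycle"`).
#' }
#'
#' @param arm An [arm_spec].
#' @param trace A `cycle_trace` built from the arm's survival models.
#' @param patient A [patient].
#' @param other An [other_costs] object.
#' @param prices Named list of [drug_price] objects.
#' @param settings A [model_settings].
#' @param vial_policy `"round_up_vials"` or `"exact_mg"`.
#' @param ae_application `"one_off"` or `"per_cycle"`.
#' @param subsequent_max_cycles Cycles of subsequent therapy per progressed
#'   patient before switching to best supportive care (default 6; `Inf`
#'   keeps the uptake share on subsequent therapy for all of progression).
#' @return Data frame with one row per accrual cycle: `cycle`, `drug`,
#'   `followup`, `subsequent`, `bsc`, `ae`, `total` (all undiscounted USD).
#' @export
cycle_cost_schedule <- function(arm, trace, patient, other, prices, settings,
                                vial_policy = c("round_up_vials", "exact_mg"),
                                ae_application = c("one_off", "per_cycle"),
                                subsequent_max_cycles = 6) {
  vial_policy <- match.arg(vial_policy)
  ae_application <- match.arg(ae_application)
  stopifnot(inherits(arm, "arm_spec"), inherits(trace, "cycle_trace"),
            inherits(other, "other_costs"), subsequent_max_cycles >= 0)
  w <- occupancy_weights(trace, settings)
  n <- length(w$pfs)
  if (any(w$pfs < -1e-12) || any(w$pd < -1e-12))
    stop("negative state occupancy in trace")
  k <- seq_len(n) - 1L

  rg <- arm$regimen
  c_ind <- drug_cost_per_cycle(rg, prices, patient, vial_policy, "induction")
  c_mnt <- drug_cost_per_cycle(rg, prices, patient, vial_policy, "maintenance")
  drug <- (c_ind * (k < rg$chemo_max_cycles) +
           c_mnt * (k < rg$maintenance_max_cycles)) * w$pfs

  followup <- other$followup_per_cycle * w$pfs

  # entries into PD per cycle ~ decline of the PFS curve (deaths during the
  # brief subsequent-therapy window are ignored; occupancy-clamped below)
  entries <- pmax(0, trace$p_pfs[1:n] - trace$p_pfs[2:(n + 1)])
  if (is.finite(subsequent_max_cycles)) {
    # a patient progressing during cycle j occupies PD from cycle j+1 on,
    # so their subsequent-therapy window is cycles j+1 .. j+m
    m <- as.integer(subsequent_max_cycles)
    recent <- vapply(seq_len(n), function(i)
      if (m > 0 && i > 1) sum(entries[max(1, i - m):(i - 1)]) else 0,
      numeric(1))
    on_subs <- pmin(w$pd, recent)
  } else {
    on_subs <- w$pd
  }
  subsequent <- other$subsequent_per_cycle * arm$subsequent_uptake * on_subs
  bsc <- other$bsc_per_cycle * (w$pd - arm$subsequent_uptake * on_subs)

  ae <- numeric(n)
  ae_exp_cost <- sum(arm$ae$incidence * arm$ae$cost)
  if (ae_application == "one_off") {
    ae[1] <- ae_exp_cost
  } else {
    ae <- ae_exp_cost * w$pfs * (k < rg$chemo_max_cycles)
  }

  out <- data.frame(cycle = k, drug = drug, followup = followup,
                    subsequent = subsequent, bsc = bsc, ae = ae)
  out$total <- out$drug + out$followup + out$subsequent + out$bsc + out$ae
  out
}
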