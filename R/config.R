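#' Bundled study configuration
#'
#' The complete input set of the bundled ES-SCLC analysis, field-for-field:
#' log-logistic OS/PFS parameters per arm, drug unit prices, adverse-event
#' incidences/costs/disutilities, state utilities, follow-up, subsequent
#' therapy and best-supportive-care costs, reference anthropometrics,
#' 3-week cycles, 10-year horizon, 5% annual discounting and the
#' $37,304.346/QALY willingness-to-pay threshold.  The `conventions` block
#' exposes every modelling toggle (survival time unit, half-cycle
#' correction, maintenance duration, adverse-event application, vial
#' policy, subsequent-therapy duration); its defaults are the combination
#' documented in the methods vignette.
#'
#' @return A nested list of class `study_config`.
#' @export
default_config <- function() {
  cfg <- list(
    settings = list(
      cycle_length_weeks = 3,
      horizon_years = 10,
      annual_discount_rate = 0.05,
      wtp_per_qaly = 37304.346,
      half_cycle_correction = TRUE,
      discounting = "continuous"
    ),
    # survival-model time unit: what one unit of t in S(t) means
    time_unit = "month",
    conventions = list(
      vial_policy = "round_up_vials",
      ae_application = "per_cycle",
      subsequent_max_cycles = 6
    ),
    patient = list(weight_kg = 60, bsa_m2 = 1.72, crcl = 70),
    prices = list(
      serplulimab = list(pack_mg = 100, price = 812.209),
      etoposide   = list(pack_mg = 100, price = 5.661),
      carboplatin = list(pack_mg = 100, price = 24.215)
    ),
    utilities = list(pfs = 0.673, pd = 0.473),
    other_costs = list(
      subsequent_per_cycle = 854.050,
      followup_per_cycle = 55.600,
      bsc_per_cycle = 359.524
    ),
    ae_costs = list(anemia = 531.723, wbc_decrease = 461.253,
                    neutropenia = 84.210, thrombocytopenia = 1054.000),
    ae_disutilities = list(anemia = 0.073, wbc_decrease = 0.200,
                           neutropenia = 0.200, thrombocytopenia = 0.190),
    arms = list(
      serplulimab = list(
        os  = list(family = "loglogistic", shape = 1.937, rate = 0.00363),
        pfs = list(family = "loglogistic", shape = 2.100, rate = 0.0129),
        ae_incidence = list(anemia = 0.054, wbc_decrease = 0.085,
                            neutropenia = 0.141, thrombocytopenia = 0.062),
        subsequent_uptake = 0.442,
        has_serplulimab = TRUE,
        chemo_max_cycles = 4,
        maintenance_max_cycles = 8
      ),
      chemotherapy = list(
        os  = list(family = "loglogistic", shape = 1.924, rate = 0.00645),
        pfs = list(family = "loglogistic", shape = 2.520, rate = 0.0152),
        ae_incidence = list(anemia = 0.056, wbc_decrease = 0.087,
                            neutropenia = 0.138, thrombocytopenia = 0.082),
        subsequent_uptake = 0.434,
        has_serplulimab = FALSE,
        chemo_max_cycles = 4,
        maintenance_max_cycles = Inf
      )
    ),
    metadata = list(
      label = "serplulimab + chemotherapy vs chemotherapy, ES-SCLC, first line",
      perspective = "Chinese healthcare system",
      currency = "USD",
      exchange_rate_rmb_per_usd = 6.73
    )
  )
  class(cfg) <- c("study_config", "list")
  cfg
}

#' Validate a study configuration
#'
#' Checks the configuration against the schema and returns every violation
#' found (an empty character vector means valid).  [load_config()] raises a
#' single error listing all violations.
#'
#' @param config A configuration list.
#' @return Character vector of violation messages.
#' @export
validate_config <- function(config) {
  v <- character(0)
  need <- function(path) {
    x <- config
    for (key in path) {
      if (!is.list(x) || is.null(x[[key]])) {
        v <<- c(v, paste0("missing field: ", paste(path, collapse = "$")))
        return(NULL)
      }
      x <- x[[key]]
    }
    x
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) v <<- c(v, msg)

  s <- need("settings")
  if (!is.null(s)) {
    chk(is.numeric(s$cycle_length_weeks) && s$cycle_length_weeks > 0,
        "settings$cycle_length_weeks must be > 0")
    chk(is.numeric(s$horizon_years) && s$horizon_years > 0,
        "settings$horizon_years must be > 0")
    chk(is.numeric(s$annual_discount_rate) && s$annual_discount_rate >= 0 &&
        s$annual_discount_rate < 1,
        "settings$annual_discount_rate must be in [0, 1)")
    chk(is.numeric(s$wtp_per_qaly) && s$wtp_per_qaly > 0,
        "settings$wtp_per_qaly must be > 0")
  }
  tu <- need("time_unit")
  if (!is.null(tu))
    chk(tu %in% c("cycle", "week", "month"),
        "time_unit must be one of cycle/week/month")
  cv <- need("conventions")
  if (!is.null(cv)) {
    chk(cv$vial_policy %in% c("round_up_vials", "exact_mg"),
        "conventions$vial_policy must be round_up_vials or exact_mg")
    chk(cv$ae_application %in% c("one_off", "per_cycle"),
        "conventions$ae_application must be one_off or per_cycle")
    chk(is.numeric(cv$subsequent_max_cycles) && cv$subsequent_max_cycles >= 0,
        "conventions$subsequent_max_cycles must be >= 0")
  }
  p <- need("patient")
  if (!is.null(p))
    for (f in c("weight_kg", "bsa_m2", "crcl"))
      chk(is.numeric(p[[f]]) && p[[f]] > 0,
          paste0("patient$", f, " must be > 0"))
  pr <- need("prices")
  if (!is.null(pr))
    for (d in names(pr)) {
      chk(is.numeric(pr[[d]]$pack_mg) && pr[[d]]$pack_mg > 0,
          paste0("prices$", d, "$pack_mg must be > 0"))
      chk(is.numeric(pr[[d]]$price) && pr[[d]]$price >= 0,
          paste0("prices$", d, "$price must be >= 0"))
    }
  u <- need("utilities")
  if (!is.null(u))
    for (f in c("pfs", "pd"))
      chk(is.numeric(u[[f]]) && u[[f]] >= 0 && u[[f]] <= 1,
          paste0("utilities$", f, " must be in [0, 1]"))
  oc <- need("other_costs")
  if (!is.null(oc))
    for (f in names(oc))
      chk(is.numeric(oc[[f]]) && oc[[f]] >= 0,
          paste0("other_costs$", f, " must be >= 0"))
  for (blk in c("ae_costs", "ae_disutilities")) {
    b <- need(blk)
    if (!is.null(b))
      for (f in names(b)) {
        ok <- is.numeric(b[[f]]) && b[[f]] >= 0 &&
          (blk == "ae_costs" || b[[f]] <= 1)
        chk(ok, paste0(blk, "$", f, if (blk == "ae_costs")
          " must be >= 0" else " must be in [0, 1]"))
      }
  }
  arms <- need("arms")
  if (!is.null(arms)) {
    if (length(arms) < 2)
      v <- c(v, "arms: at least two treatment arms are required")
    for (a in names(arms)) {
      arm <- arms[[a]]
      for (ep in c("os", "pfs")) {
        m <- arm[[ep]]
        if (is.null(m)) { v <- c(v, paste0("arms$", a, "$", ep, " missing")); next }
        chk(m$family %in% SURVIVAL_FAMILIES,
            paste0("arms$", a, "$", ep, "$family unknown: ", m$family))
        pars <- m[setdiff(names(m), "family")]
        chk(all(vapply(pars, is.numeric, TRUE)) &&
              all(is.finite(unlist(pars))),
            paste0("arms$", a, "$", ep, " parameters must be finite numbers"))
      }
      chk(is.numeric(arm$subsequent_uptake) && arm$subsequent_uptake >= 0 &&
            arm$subsequent_uptake <= 1,
          paste0("arms$", a, "$subsequent_uptake must be in [0, 1]"))
      if (!is.null(arm$ae_incidence))
        for (f in names(arm$ae_incidence))
          chk(is.numeric(arm$ae_incidence[[f]]) &&
                arm$ae_incidence[[f]] >= 0 && arm$ae_incidence[[f]] <= 1,
              paste0("arms$", a, "$ae_incidence$", f, " must be in [0, 1]"))
    }
  }
  v
}

#' Load and validate a study configuration from YAML
#'
#' @param path Path to a YAML configuration (see the bundled
#'   `system.file("extdata", "serplulimab_es_sclc.yaml", package =
#'   "psmcea")`).
#' @return A validated `study_config`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML has no Inf literal guarantee across emitters; accept the string
  for (a in names(cfg$arms)) {
    mm <- cfg$arms[[a]]$maintenance_max_cycles
    if (is.character(mm)) cfg$arms[[a]]$maintenance_max_cycles <-
        if (tolower(mm) %in% c("inf", ".inf")) Inf else as.numeric(mm)
  }
  v <- validate_config(cfg)
  if (length(v) > 0)
    stop("invalid configuration:\n  - ", paste(v, collapse = "\n  - "))
  class(cfg) <- c("study_config", "list")
  cfg
}

#' Write a study configuration to YAML
#' @param config A `study_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Path to the bundled configuration file
#' @return Path to the installed YAML copy of [default_config()].
#' @export
bundled_config_path <- function() {
  system.file("extdata", "serplulimab_es_sclc.yaml", package = "psmcea",
              mustWork = TRUE)
}
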