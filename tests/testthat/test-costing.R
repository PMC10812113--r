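default_prices <- function() list(
  serplulimab = drug_price("serplulimab", 100, 812.209),
  etoposide   = drug_price("etoposide", 100, 5.661),
  carboplatin = drug_price("carboplatin", 100, 24.215)
)

serp_regimen <- function(maintenance_max = Inf) regimen(
  list(regimen_component("etoposide", "per_m2", 100, n_admin = 3,
                         phase = "induction"),
       regimen_component("carboplatin", "calvert", 5, n_admin = 1,
                         phase = "induction", cap_mg = 750),
       regimen_component("serplulimab", "per_kg", 4.5, n_admin = 1,
                         phase = "maintenance")),
  chemo_max_cycles = 4, maintenance_max_cycles = maintenance_max)

test_that("Calvert carboplatin dose covers both branches and the cap", {
  expect_equal(carboplatin_dose(patient(crcl = 70)), 475)     # 5 x 95
  expect_equal(carboplatin_dose(patient(crcl = 130)), 750)    # 775 capped
  expect_equal(carboplatin_dose(patient(crcl = 0.00001)), 5 * 25.00001)
  expect_error(patient(crcl = -3))
})

test_that("drug cost per cycle: vial rounding and exact-mg arithmetic", {
  pr <- default_prices()
  pat <- patient()
  serp_only <- regimen(list(regimen_component("serplulimab", "per_kg", 4.5,
                                              phase = "maintenance")))
  # 4.5 x 60 = 270 mg -> 3 vials of 100 mg
  expect_equal(drug_cost_per_cycle(serp_only, pr, pat, "round_up_vials"),
               3 * 812.209)
  expect_equal(drug_cost_per_cycle(serp_only, pr, pat, "exact_mg"),
               2.7 * 812.209)
  # etoposide 172 mg/day x 3 days, exact: 5.16 vials x 5.661
  etop <- regimen(list(regimen_component("etoposide", "per_m2", 100,
                                         n_admin = 3, phase = "induction")))
  expect_equal(drug_cost_per_cycle(etop, pr, pat, "exact_mg"), 29.21076)
  # all prices zero -> zero cost
  pr0 <- lapply(pr, function(p) drug_price(p$name, p$pack_mg, 0))
  expect_equal(drug_cost_per_cycle(serp_regimen(), pr0, pat), 0)
  # missing price is a configuration error
  expect_error(drug_cost_per_cycle(serp_regimen(), pr["etoposide"], pat),
               "no price entry")
})

test_that("rounded-up vials never cost less than exact milligrams", {
  pr <- default_prices()
  for (w in c(47, 60, 63.5, 80)) for (b in c(1.5, 1.72, 2.1)) {
    pat <- patient(weight_kg = w, bsa_m2 = b)
    up <- drug_cost_per_cycle(serp_regimen(), pr, pat, "round_up_vials")
    ex <- drug_cost_per_cycle(serp_regimen(), pr, pat, "exact_mg")
    expect_gte(up, ex)
  }
})

test_that("forced 4-cycle PFS trace reproduces the hand-computed schedule", {
  tr <- forced_trace()
  s <- model_settings(half_cycle_correction = FALSE)
  arm <- arm_spec("serp", table1_models("cycle")$serp_os,
                  table1_models("cycle")$serp_pfs, serp_regimen(),
                  ae_profile(c("anemia", "wbc", "anc", "plt"),
                             c(0.054, 0.085, 0.141, 0.062),
                             c(531.723, 461.253, 84.210, 1054.000),
                             c(0.073, 0.200, 0.200, 0.190)),
                  subsequent_uptake = 0.442)
  sched <- cycle_cost_schedule(arm, tr, patient(), other_costs(),
                               default_prices(), s,
                               vial_policy = "round_up_vials",
                               ae_application = "one_off")
  # hand arithmetic: chemo cycle = 6x5.661 + 5x24.215 = 155.041;
  # serplulimab = 3x812.209 = 2436.627; follow-up 55.6 while in PFS
  expect_equal(sched$drug, c(rep(155.041 + 2436.627, 4), 0))
  expect_equal(sched$followup, c(rep(55.6, 4), 0))
  expect_equal(sched$subsequent, rep(0, 5))
  expect_equal(sched$bsc, rep(0, 5))
  expect_equal(sched$ae, c(145.141157, 0, 0, 0, 0))
  expect_equal(sum(sched$total),
               4 * (155.041 + 2436.627) + 4 * 55.6 + 145.141157)
})

test_that("cost schedule is homogeneous of degree 1 in unit costs", {
  cfg <- default_config()
  cfg2 <- cfg
  for (d in names(cfg2$prices)) cfg2$prices[[d]]$price <- 2 * cfg2$prices[[d]]$price
  for (f in names(cfg2$other_costs)) cfg2$other_costs[[f]] <- 2 * cfg2$other_costs[[f]]
  for (f in names(cfg2$ae_costs)) cfg2$ae_costs[[f]] <- 2 * cfg2$ae_costs[[f]]
  a1 <- evaluate_arm(cfg, "serplulimab")
  a2 <- evaluate_arm(cfg2, "serplulimab")
  expect_equal(a2$schedule$total, 2 * a1$schedule$total, tolerance = 1e-12)
  expect_equal(a2$total_cost, 2 * a1$total_cost, tolerance = 1e-12)
})

test_that("zero occupancy contributes zero of that state's costs", {
  # all-dead-after-cycle-0 trace: only cycle-0 PFS costs and the AE one-off
  tr <- forced_trace(n_pfs = 1, n_total = 3)
  s <- model_settings()
  m <- table1_models("cycle")
  arm <- arm_spec("chemo", m$chemo_os, m$chemo_pfs,
                  regimen(list(regimen_component("etoposide", "per_m2", 100,
                                                 n_admin = 3, phase = "induction"))),
                  ae_profile("anemia", 0.056, 531.723, 0.073),
                  subsequent_uptake = 0.434)
  sched <- cycle_cost_schedule(arm, tr, patient(), other_costs(),
                               default_prices(), s,
                               ae_application = "one_off")
  expect_equal(sched$bsc, rep(0, 3))          # no PD occupancy at cycle starts
  expect_equal(sched$subsequent, rep(0, 3))
  expect_equal(sched$drug[2:3], c(0, 0))
  expect_equal(sched$followup[2:3], c(0, 0))
})

test_that("subsequent therapy is limited to the first cycles of progression", {
  # trace that moves everyone to PD at cycle 1 and keeps them there
  k <- 0:11
  tr <- data.frame(cycle = k, t_model = k, t_years = k * 3 / (365.25 / 7),
                   p_pfs = as.numeric(k < 1), p_pd = as.numeric(k >= 1),
                   p_death = 0)
  attr(tr, "clamp_events") <- 0L
  class(tr) <- c("cycle_trace", "data.frame")
  s <- model_settings()
  m <- table1_models("cycle")
  arm <- arm_spec("serp", m$serp_os, m$serp_pfs, serp_regimen(),
                  ae_profile("anemia", 0.054, 531.723, 0.073), 0.442)
  sched <- cycle_cost_schedule(arm, tr, patient(), other_costs(),
                               default_prices(), s,
                               subsequent_max_cycles = 6)
  on_subs <- sched$subsequent / (854.050 * 0.442)
  # six cycles of subsequent therapy (cycles 1..6), BSC afterwards
  expect_equal(on_subs, c(0, rep(1, 6), rep(0, 4)))
  expect_equal(sched$bsc[8:11] / 359.524, rep(1, 4))
  # unlimited variant keeps the uptake share on subsequent therapy
  sched_inf <- cycle_cost_schedule(arm, tr, patient(), other_costs(),
                                   default_prices(), s,
                                   subsequent_max_cycles = Inf)
  expect_equal(sched_inf$subsequent[2:11] / (854.050 * 0.442), rep(1, 10))
  expect_equal(sched_inf$bsc[2:11] / 359.524, rep(1 - 0.442, 10))
})
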