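test_that("param_spec validates its range and defaults to +/-25%", {
  s <- param_spec("x", c("utilities", "pfs"), 0.673, distribution = "beta",
                  role = "utility")
  expect_equal(s$low, 0.673 * 0.75)
  expect_equal(s$high, 0.673 * 1.25)
  expect_error(param_spec("x", "p", 1, low = 2, high = 3), "low <= base <= high")
})

test_that("the default parameter set covers every distributed table row", {
  cfg <- default_config()
  sp <- default_param_specs(cfg)
  expect_length(sp, 25)  # 3 prices + 4 AE costs + 3 other costs + BSA (gamma)
                         # + 2 utilities + 4 AE disutilities + 8 incidences (beta)
  expect_identical(names(sp), sort(names(sp)))
  roles <- vapply(sp, `[[`, character(1), "distribution")
  expect_equal(sum(roles == "gamma"), 11)
  expect_equal(sum(roles == "beta"), 14)
  # every path resolves to its base value
  for (s in sp)
    expect_equal(get_config_value(cfg, s$path), s$base, info = s$name)
})

test_that("zero-leverage and zero-perturbation parameters do not move the ICER", {
  cfg <- default_config()
  base_icer <- run_base_case(cfg)$incremental$icer
  # an AE cost whose incidence is forced to zero has no leverage
  cfg0 <- cfg
  for (a in names(cfg0$arms)) cfg0$arms[[a]]$ae_incidence$anemia <- 0
  specs <- list(param_spec("ae_cost_anemia", c("ae_costs", "anemia"),
                           cfg0$ae_costs$anemia, distribution = "gamma"))
  tor <- one_way_dsa(cfg0, specs)
  expect_equal(tor$swing, 0)
  # zero-width range reproduces the base case bit-for-bit
  degenerate <- list(param_spec("price_serplulimab",
                                c("prices", "serplulimab", "price"),
                                812.209, low = 812.209, high = 812.209))
  tor2 <- one_way_dsa(cfg, degenerate)
  expect_identical(tor2$icer_at_low, base_icer)
  expect_identical(tor2$icer_at_high, base_icer)
})

test_that("intervention-drug price moves the ICER monotonically", {
  cfg <- default_config()
  spec <- list(param_spec("price_serplulimab",
                          c("prices", "serplulimab", "price"), 812.209,
                          distribution = "gamma"))
  tor <- one_way_dsa(cfg, spec)
  expect_true(is.finite(tor$icer_at_low) && is.finite(tor$icer_at_high))
  expect_gt(tor$icer_at_high, tor$icer_at_low)
})

test_that("unknown parameter paths raise a configuration error", {
  bad <- list(param_spec("ghost", c("prices", "nivolumab", "price"), 1))
  expect_error(one_way_dsa(default_config(), bad), "path not found")
})

test_that("sampled parameters match their specified moments", {
  set.seed(99)
  g <- param_spec("price_serplulimab", c("prices", "serplulimab", "price"),
                  812.209, 609.382, 1015.261, distribution = "gamma")
  x <- sample_param(g, 1e5)
  expect_equal(mean(x), 812.209, tolerance = 0.01)
  expect_equal(sd(x), (1015.261 - 609.382) / (2 * 1.96), tolerance = 0.05)
  b <- param_spec("utility_pfs", c("utilities", "pfs"), 0.673, 0.505, 0.841,
                  distribution = "beta", role = "utility")
  y <- sample_param(b, 1e5)
  expect_true(all(y > 0 & y < 1))
  expect_equal(mean(y), 0.673, tolerance = 0.02)
  expect_equal(sd(y), (0.841 - 0.505) / (2 * 1.96), tolerance = 0.05)
  # fixed specs always return base
  f <- param_spec("fixed", c("utilities", "pfs"), 0.673, 0.673, 0.673,
                  distribution = "fixed")
  expect_equal(sample_param(f, 10), rep(0.673, 10))
})

test_that("infeasible beta moments are shrunk to the boundary with a warning", {
  wide <- param_spec("u", c("utilities", "pd"), 0.5, 0.001, 0.999,
                     distribution = "beta", role = "utility")
  # sd = 0.2546 < bound 0.5 -> feasible, no warning
  expect_silent(sample_param(wide, 1))
  crazy <- param_spec("u", c("utilities", "pd"), 0.02, low = 0.02 - 0.55,
                      high = 0.02 + 0.55, distribution = "beta")
  set.seed(1)
  expect_warning(x <- sample_param(crazy, 100), "infeasible")
  expect_true(all(x > 0 & x < 1))
})

test_that("PSA is reproducible, degenerate under fixed specs, and consistent with the CEAC", {
  cfg <- default_config()
  sp <- default_param_specs(cfg)
  p1 <- quiet_utilities(run_psa(cfg, sp, n_draws = 25, seed = 11))
  p2 <- quiet_utilities(run_psa(cfg, sp, n_draws = 25, seed = 11))
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$n_rejected, 0L)
  # all-fixed specs collapse every draw onto the base case
  fixed <- lapply(sp[1:3], function(s) {
    s$distribution <- "fixed"; s
  })
  base <- run_base_case(cfg)$incremental
  pf <- run_psa(cfg, fixed, n_draws = 5, seed = 2)
  expect_equal(unique(pf$draws$incremental_cost), base$incremental_cost)
  expect_true(pf$p_acceptable %in% c(0, 1))
  # CEAC at the analysis WTP equals the PSA acceptance probability exactly
  cc <- ceac(p1, c(0, cfg$settings$wtp_per_qaly, 1e9))
  expect_identical(cc$p_acceptable[2], p1$p_acceptable)
  # wtp = 0: acceptance means saving money
  expect_identical(cc$p_acceptable[1],
                   mean(p1$draws$incremental_cost <= 0))
  # huge wtp: acceptance means gaining QALYs (ties acceptable)
  expect_identical(cc$p_acceptable[3],
                   mean(p1$draws$incremental_qaly >= 0))
  expect_error(ceac(p1, numeric(0)), "empty")
})

test_that("CEAC is nondecreasing in WTP when every draw gains QALYs", {
  cfg <- default_config()
  p <- quiet_utilities(run_psa(cfg, default_param_specs(cfg),
                               n_draws = 40, seed = 3))
  stopifnot(all(p$draws$incremental_qaly > 0))
  cc <- ceac(p, seq(0, 2e5, length.out = 41))
  expect_true(all(diff(cc$p_acceptable) >= 0))
})
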