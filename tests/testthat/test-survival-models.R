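test_that("survivor functions satisfy S(0)=1, monotonicity and range for every family", {
  grid <- seq(0, 200, length.out = 1000)
  for (m in family_zoo()) {
    s <- survival_at(m, grid)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(diff(s) <= 1e-12), info = m$family)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
  }
})

test_that("log-logistic survivor function matches direct arithmetic", {
  m <- table1_models()$serp_os
  expect_identical(survival_at(m, 0), 1)
  # median satisfies lambda * t^gamma = 1
  t_med <- (1 / 0.00363)^(1 / 1.937)
  expect_equal(survival_at(m, t_med), 0.5, tolerance = 1e-12)
  # frozen high-precision evaluation of 1/(1 + 0.0129 * 10^2.1)
  pfs <- table1_models()$serp_pfs
  expect_equal(survival_at(pfs, 10), 0.3810955594666003, tolerance = 1e-12)
})

test_that("invalid inputs are rejected", {
  m <- table1_models()$serp_os
  expect_error(survival_at(m, -1), "nonnegative")
  expect_error(parametric_survival("loglogistic", c(shape = -1, rate = 0.1)),
               "positive")
  expect_error(parametric_survival("loglogistic", c(shape = 1, rate = Inf)),
               "finite")
  expect_error(parametric_survival("nbinom", c(1, 2)))
})

test_that("median survival: closed forms, root-finder agreement, no-median signalling", {
  expect_equal(median_survival(parametric_survival("exponential", c(rate = log(2)))), 1)
  m <- table1_models()$serp_os
  expect_equal(median_survival(m), (1 / 0.00363)^(1 / 1.937), tolerance = 1e-12)
  # closed form vs numeric root agree for every family
  for (mod in family_zoo()) {
    expect_equal(median_survival(mod, "numeric"), median_survival(mod),
                 tolerance = 1e-6, info = mod$family)
  }
  # Gompertz closed-form median ln(1 + shape*ln2/rate)/shape vs root-finder
  g <- parametric_survival("gompertz", c(shape = 0.13, rate = 0.045))
  expect_equal(median_survival(g), log(1 + 0.13 * log(2) / 0.045) / 0.13,
               tolerance = 1e-6)
  # negative-shape Gompertz with survival plateau above 0.5 has no median
  flat <- parametric_survival("gompertz", c(shape = -0.5, rate = 0.1))
  expect_error(median_survival(flat), class = "psmcea_no_median")
})

test_that("quantile_survival inverts survival_at", {
  for (m in family_zoo()) {
    s <- c(0.9, 0.5, 0.2)
    expect_equal(survival_at(m, quantile_survival(m, s)), s,
                 tolerance = 1e-8, info = m$family)
  }
})

test_that("exponential MLE matches the closed form n_events / sum(t)", {
  set.seed(101)
  tt <- rexp(5000, rate = 0.1)
  rep <- fit_parametric(tt, rep(TRUE, 5000), "exponential")
  expect_equal(unname(rep$params["rate"]), 5000 / sum(tt), tolerance = 1e-4)
  expect_equal(unname(rep$params["rate"]), 0.1, tolerance = 0.05)
})

test_that("log-logistic parameters are recovered under administrative censoring", {
  truth <- parametric_survival("loglogistic", c(shape = 2.1, rate = 0.0129))
  horizon <- censoring_horizon_for(truth, 0.20)
  dat <- simulate_survival(truth, 5000, horizon, seed = 7)
  expect_lt(abs(mean(!dat$event) - 0.20), 0.03)
  rep <- fit_parametric(dat$time, dat$event, "loglogistic")
  expect_lt(abs(rep$params["shape"] - 2.1) / 2.1, 0.10)
  expect_lt(abs(rep$params["rate"] - 0.0129) / 0.0129, 0.10)
})

test_that("fitting is deterministic and reports consistent bookkeeping", {
  set.seed(5)
  tt <- rweibull(200, 1.3, 10)
  ev <- tt < 15
  tt <- pmin(tt, 15)
  a <- fit_parametric(tt, ev, "weibull")
  b <- fit_parametric(tt, ev, "weibull")
  expect_identical(a$params, b$params)
  expect_identical(a$log_likelihood, b$log_likelihood)
  expect_equal(a$n_events + a$n_censored, length(tt))
  # AIC/BIC arithmetic identities hold exactly
  expect_identical(a$aic, 2 * a$k - 2 * a$log_likelihood)
  expect_identical(a$bic, a$k * log(a$n) - 2 * a$log_likelihood)
})

test_that("fit_parametric rejects degenerate inputs", {
  expect_error(fit_parametric(1:5, rep(TRUE, 5), "weibull"), "at least 10")
  expect_error(fit_parametric(1:20, rep(FALSE, 20), "weibull"),
               "unidentifiable")
  expect_error(fit_parametric(c(-1, 1:19), rep(TRUE, 20), "weibull"),
               "nonnegative")
})

test_that("select_best_fit is an argmin with deterministic tie-breaking", {
  mk <- function(family, aic, k) structure(
    list(family = family, aic = aic, bic = aic, k = k),
    class = "fit_report")
  reports <- list(mk("weibull", 100.0, 2), mk("lognormal", 98.5, 2),
                  mk("gamma", 103.2, 2))
  expect_identical(select_best_fit(reports, "aic")$family, "lognormal")
  expect_identical(select_best_fit(reports[2], "aic")$family, "lognormal")
  # tie: fewer parameters wins, then declared family order
  tie <- list(mk("gamma", 50, 2), mk("exponential", 50, 1), mk("weibull", 50, 2))
  expect_identical(select_best_fit(tie, "aic")$family, "exponential")
  tie2 <- list(mk("gamma", 50, 2), mk("weibull", 50, 2))
  expect_identical(select_best_fit(tie2, "aic")$family, "weibull")
  expect_error(select_best_fit(list(), "aic"), "empty")
})

test_that("fit_report_table flattens reports for export", {
  set.seed(11)
  tt <- rexp(200, 0.2)
  reps <- lapply(c("exponential", "weibull"), function(f)
    fit_parametric(tt, rep(TRUE, 200), f))
  tab <- fit_report_table(reps)
  expect_identical(tab$family, c("exponential", "weibull"))
  expect_true(all(c("aic", "bic", "log_likelihood", "n_events") %in% names(tab)))
})
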