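#' @importFrom stats rgamma rbeta
NULL

#' Sensitivity-analysis parameter specification
#'
#' Describes one uncertain input: where it lives in the configuration, its
#' base value and range, and the distribution used by the probabilistic
#' sensitivity analysis.  Where the source tabulates no range, low/high
#' default to +/-25% of the base value (the same perturbation used by the
#' one-way analysis).
#'
#' @param name Unique parameter name.
#' @param path Character vector addressing the value inside a
#'   `study_config` (e.g. `c("prices", "serplulimab", "price")`).
#' @param base Base-case value.
#' @param low,high Range bounds; default `base * 0.75` / `base * 1.25`.
#' @param distribution `"gamma"` (costs and other positive quantities),
#'   `"beta"` (utilities, probabilities) or `"fixed"`.
#' @param role `"cost"`, `"utility"`, `"probability"` or `"other"`.
#' @return A `param_spec`.
#' @export
param_spec <- function(name, path, base, low = base * 0.75,
                       high = base * 1.25,
                       distribution = c("gamma", "beta", "fixed"),
                       role = c("cost", "utility", "probability", "other")) {
  distribution <- match.arg(distribution)
  role <- match.arg(role)
  if (!(low <= base && base <= high))
    stop("param '", name, "': need low <= base <= high")
  structure(list(name = name, path = path, base = base, low = low,
                 high = high, distribution = distribution, role = role),
            class = "param_spec")
}

# read / write a nested config entry by path
get_config_value <- function(config, path) {
  x <- config
  for (key in path) {
    x <- x[[key]]
    if (is.null(x)) stop("path not found in configuration: ",
                         paste(path, collapse = "$"))
  }
  x
}

set_config_value <- function(config, path, value) {
  get_config_value(config, path)  # existence check
  config[[path]] <- value
  config
}

#' Default uncertain-parameter set of the bundled analysis
#'
#' Every tabulated input carrying a sampling distribution: the three drug
#' prices, the four adverse-event management costs, subsequent-therapy,
#' follow-up and best-supportive-care costs and the body surface area
#' (gamma); the two state utilities, four adverse-event disutilities and
#' eight per-arm adverse-event incidences (beta).  The survival shape/rate
#' parameters are held fixed, mirroring the source table.  Ranges are the
#' tabulated ones where printed (all equal to +/-25% of base) and +/-25%
#' otherwise.
#'
#' @param config A `study_config`.
#' @return Named list of [param_spec] objects, sorted by name (the PSA draw
#'   order).
#' @export
default_param_specs <- function(config = default_config()) {
  sp <- list()
  add <- function(s) sp[[s$name]] <<- s
  for (d in names(config$prices))
    add(param_spec(paste0("price_", d), c("prices", d, "price"),
                   config$prices[[d]]$price, distribution = "gamma",
                   role = "cost"))
  for (ev in names(config$ae_costs))
    add(param_spec(paste0("ae_cost_", ev), c("ae_costs", ev),
                   config$ae_costs[[ev]], distribution = "gamma",
                   role = "cost"))
  for (ev in names(config$ae_disutilities))
    add(param_spec(paste0("ae_disutility_", ev), c("ae_disutilities", ev),
                   config$ae_disutilities[[ev]], distribution = "beta",
                   role = "utility"))
  for (a in names(config$arms))
    for (ev in names(config$arms[[a]]$ae_incidence))
      add(param_spec(paste0("ae_incidence_", a, "_", ev),
                     c("arms", a, "ae_incidence", ev),
                     config$arms[[a]]$ae_incidence[[ev]],
                     distribution = "beta", role = "probability"))
  add(param_spec("utility_pfs", c("utilities", "pfs"),
                 config$utilities$pfs, distribution = "beta",
                 role = "utility"))
  add(param_spec("utility_pd", c("utilities", "pd"),
                 config$utilities$pd, distribution = "beta",
                 role = "utility"))
  for (f in names(config$other_costs))
    add(param_spec(paste0("cost_", sub("_per_cycle", "", f)),
                   c("other_costs", f), config$other_costs[[f]],
                   distribution = "gamma", role = "cost"))
  add(param_spec("body_surface_area", c("patient", "bsa_m2"),
                 config$patient$bsa_m2, distribution = "gamma",
                 role = "other"))
  sp[order(names(sp))]
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full base case with each parameter set to its low and then
#' its high value, all others held at base, and ranks parameters by the
#' absolute ICER swing.
#'
#' @param config A `study_config`.
#' @param specs List of [param_spec] objects (default
#'   [default_param_specs()]).
#' @return Data frame of class `tornado`: `param`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `swing`, sorted by descending swing,
#'   with the base-case ICER in attribute `base_icer`.
#' @export
one_way_dsa <- function(config = default_config(),
                        specs = default_param_specs(config)) {
  base <- run_base_case(config)$incremental
  eval_at <- function(s, value) {
    run_base_case(set_config_value(config, s$path, value))$incremental$icer
  }
  rows <- lapply(specs, function(s) {
    data.frame(param = s$name, low = s$low, high = s$high,
               icer_at_low = eval_at(s, s$low),
               icer_at_high = eval_at(s, s$high),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$swing <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  class(out) <- c("tornado", "data.frame")
  out
}

#' Sample one parameter for the probabilistic sensitivity analysis
#'
#' The tabulated range is read as a 95% interval, so `sd = (high - low) /
#' (2 * 1.96)`.  Gamma parameters come from method-of-moments
#' (`shape = mean^2/sd^2`, `rate = mean/sd^2`); beta likewise on the same
#' mean and sd, with the sd shrunk to 95% of the feasibility bound
#' `sqrt(m(1-m))` (with a warning) when the moments are infeasible.
#' `"fixed"` returns the base value.  Draws consume the current RNG state.
#'
#' @param spec A [param_spec].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws.
#' @export
sample_param <- function(spec, n = 1) {
  stopifnot(inherits(spec, "param_spec"))
  if (spec$distribution == "fixed") return(rep(spec$base, n))
  m <- spec$base
  sdev <- (spec$high - spec$low) / (2 * 1.96)
  if (sdev <= 0) return(rep(m, n))
  if (spec$distribution == "gamma") {
    shape <- m^2 / sdev^2
    rate <- m / sdev^2
    rgamma(n, shape = shape, rate = rate)
  } else {
    if (m <= 0 || m >= 1)
      stop("beta parameter '", spec$name, "' needs base in (0, 1)")
    bound <- sqrt(m * (1 - m))
    if (sdev >= bound) {
      warning("param '", spec$name,
              "': sd infeasible for a beta distribution; shrunk to bound")
      sdev <- 0.95 * bound
    }
    nu <- m * (1 - m) / sdev^2 - 1
    rbeta(n, shape1 = m * nu, shape2 = (1 - m) * nu)
  }
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the uncertain parameters: each draw resamples every
#' non-fixed parameter independently (in fixed alphabetical order for
#' cross-platform reproducibility), re-evaluates both arms on the shared
#' draw, and judges acceptability by net monetary benefit
#' `wtp * dQALY - dCost >= 0` (ties acceptable).  Draws whose configuration
#' fails validation are rejected and redrawn, with a counter.
#'
#' @param config A `study_config`.
#' @param specs List of [param_spec]s (default [default_param_specs()]).
#' @param n_draws Number of Monte Carlo iterations (default 1000).
#' @param seed Integer seed.
#' @return List of class `psa_result`: `draws` (one row per iteration with
#'   every sampled parameter, per-arm totals, increments and
#'   acceptability), `p_acceptable`, `n_rejected`, `wtp`, `seed`.
#' @export
run_psa <- function(config = default_config(),
                    specs = default_param_specs(config),
                    n_draws = 1000, seed = 1) {
  stopifnot(n_draws >= 1)
  specs <- specs[order(vapply(specs, `[[`, character(1), "name"))]
  set.seed(seed)
  wtp <- config$settings$wtp_per_qaly
  n_rejected <- 0L
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    for (attempt in seq_len(100)) {
      vals <- vapply(specs, sample_param, numeric(1))
      cfg <- config
      for (j in seq_along(specs))
        cfg <- set_config_value(cfg, specs[[j]]$path, vals[[j]])
      viol <- validate_config(cfg)
      if (length(viol) == 0) break
      n_rejected <- n_rejected + 1L
      if (attempt == 100) stop("100 consecutive rejected PSA draws")
    }
    bc <- run_base_case(cfg)
    r <- bc$incremental
    rows[[i]] <- c(vals,
                   cost_intervention = r$cost[1], qaly_intervention = r$qaly[1],
                   cost_comparator = r$cost[2], qaly_comparator = r$qaly[2],
                   incremental_cost = r$incremental_cost,
                   incremental_qaly = r$incremental_qaly,
                   nmb = r$nmb,
                   acceptable_at_wtp = as.numeric(r$nmb >= 0))
  }
  draws <- as.data.frame(do.call(rbind, rows))
  draws$draw <- seq_len(n_draws)
  structure(list(draws = draws,
                 p_acceptable = mean(draws$acceptable_at_wtp),
                 n_rejected = n_rejected, wtp = wtp, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %s), %d rejected\n",
              nrow(x$draws), format(x$seed), x$n_rejected))
  cat(sprintf("P(cost-effective at WTP %.3f) = %.2f%%\n",
              x$wtp, 100 * x$p_acceptable))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws with nonnegative net monetary benefit at each
#' willingness-to-pay value.
#'
#' @param psa A `psa_result` (or its `draws` data frame).
#' @param wtp_grid Non-empty numeric vector of WTP values (USD/QALY).
#' @return Data frame `wtp`, `p_acceptable`.
#' @export
ceac <- function(psa, wtp_grid) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  if (length(wtp_grid) == 0) stop("empty WTP grid")
  p <- vapply(wtp_grid, function(w)
    mean(w * draws$incremental_qaly - draws$incremental_cost >= 0),
    numeric(1))
  data.frame(wtp = wtp_grid, p_acceptable = p)
}
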