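#' @importFrom stats pweibull qweibull plnorm qlnorm pexp qexp pgamma qgamma
#'   runif uniroot setNames
NULL

# Declared screening order; also the tie-break order for model selection.
SURVIVAL_FAMILIES <- c("weibull", "loglogistic", "lognormal", "exponential",
                       "gompertz", "gamma")

# Named parameter slots per family.  The log-logistic uses the rate form
# S(t) = 1 / (1 + rate * t^shape), the parameterization under which the
# bundled (gamma, lambda) pairs yield medians on a clinically sensible scale.
FAMILY_PARAMS <- list(
  weibull     = c("shape", "scale"),
  loglogistic = c("shape", "rate"),
  lognormal   = c("meanlog", "sdlog"),
  exponential = c("rate"),
  gompertz    = c("shape", "rate"),
  gamma       = c("shape", "rate")
)

#' Parametric survival model
#'
#' Constructs a parametric survival distribution used to extrapolate overall
#' or progression-free survival beyond trial follow-up.  Six families are
#' supported: Weibull, log-logistic, log-normal, exponential, Gompertz and
#' gamma.  The log-logistic family uses the rate parameterization
#' \deqn{S(t) = 1 / (1 + \lambda t^\gamma)}
#' with `shape` = \eqn{\gamma} and `rate` = \eqn{\lambda}, so its median is
#' \eqn{(1/\lambda)^{1/\gamma}}.  Other families follow the standard
#' parameterizations of [stats] and [flexsurv].
#'
#' @param family One of `"weibull"`, `"loglogistic"`, `"lognormal"`,
#'   `"exponential"`, `"gompertz"`, `"gamma"`.
#' @param params Named numeric vector of parameters (see `FAMILY_PARAMS`
#'   internally); unnamed vectors are accepted in the declared order.
#' @param time_unit What one unit of `t` means: `"cycle"` (one model cycle),
#'   `"week"` or `"month"`.  The occupancy engine converts cycle boundaries
#'   into this unit before evaluating the curve.
#' @return An object of class `parametric_survival`.
#' @examples
#' os <- parametric_survival("loglogistic", c(shape = 1.937, rate = 0.00363))
#' survival_at(os, c(0, 10, 50))
#' @export
parametric_survival <- function(family, params, time_unit = c("cycle", "week", "month")) {
  family <- match.arg(family, SURVIVAL_FAMILIES)
  time_unit <- match.arg(time_unit)
  slots <- FAMILY_PARAMS[[family]]
  if (is.null(names(params)) || !all(nzchar(names(params)))) {
    if (length(params) != length(slots))
      stop("'params' must have ", length(slots), " entries for family '", family, "'")
    params <- setNames(as.numeric(params), slots)
  }
  if (!all(slots %in% names(params)))
    stop("missing parameter(s) for family '", family, "': ",
         paste(setdiff(slots, names(params)), collapse = ", "))
  params <- params[slots]
  if (any(!is.finite(params)))
    stop("non-finite survival parameters")
  # Gompertz shape may be negative (decreasing hazard); everything else that
  # must be positive, is.
  pos <- setdiff(slots, c("meanlog", if (family == "gompertz") "shape"))
  if (any(params[pos] <= 0))
    stop("parameters ", paste(pos, collapse = "/"), " must be strictly positive")
  structure(list(family = family, params = params, time_unit = time_unit),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("<parametric_survival> ", x$family, " [t in ", x$time_unit, "s]\n", sep = "")
  print(round(x$params, 6))
  invisible(x)
}

#' Survivor function S(t)
#'
#' Evaluates the survivor function of a [parametric_survival] model at
#' nonnegative times expressed in the model's own time unit.
#'
#' @param model A [parametric_survival] object.
#' @param t Nonnegative numeric vector of times.
#' @return Survival probabilities in `[0, 1]`; `S(0) = 1`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and nonnegative")
  p <- model$params
  s <- switch(model$family,
    weibull     = pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    loglogistic = 1 / (1 + p[["rate"]] * t^p[["shape"]]),
    lognormal   = plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    exponential = pexp(t, p[["rate"]], lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    gamma       = pgamma(t, p[["shape"]], p[["rate"]], lower.tail = FALSE)
  )
  pmin(pmax(s, 0), 1)
}

#' Quantile of survival time
#'
#' Inverse of the survivor function: the time `t` at which `S(t) = s`.
#' Used by [median_survival()] and by the inverse-CDF cohort simulator.
#'
#' @param model A [parametric_survival] object.
#' @param s Survival probabilities in `(0, 1]`.
#' @return Times in the model's time unit.
#' @export
quantile_survival <- function(model, s) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(s <= 0) || any(s > 1)) stop("'s' must be in (0, 1]")
  p <- model$params
  switch(model$family,
    weibull     = qweibull(s, p[["shape"]], p[["scale"]], lower.tail = FALSE),
    loglogistic = ((1 / s - 1) / p[["rate"]])^(1 / p[["shape"]]),
    lognormal   = qlnorm(s, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
    exponential = qexp(s, p[["rate"]], lower.tail = FALSE),
    gompertz    = flexsurv::qgompertz(s, p[["shape"]], p[["rate"]], lower.tail = FALSE),
    gamma       = qgamma(s, p[["shape"]], p[["rate"]], lower.tail = FALSE)
  )
}

#' Median survival time
#'
#' Solved in closed form where one exists (all families except Gompertz),
#' otherwise by a bracketing root-finder at relative tolerance 1e-9.  A
#' Gompertz model with negative shape has a survival plateau
#' `exp(rate/shape)`; if that plateau exceeds 0.5 the median does not exist
#' and an error of class `psmcea_no_median` is signalled.
#'
#' @param model A [parametric_survival] object.
#' @param method `"closed_form"` (default; falls back to numeric where no
#'   closed form exists) or `"numeric"` to force the root-finder.
#' @return Median survival time in the model's time unit.
#' @export
median_survival <- function(model, method = c("closed_form", "numeric")) {
  stopifnot(inherits(model, "parametric_survival"))
  method <- match.arg(method)
  p <- model$params
  if (model$family == "gompertz" && p[["shape"]] < 0 &&
      exp(p[["rate"]] / p[["shape"]]) > 0.5)
    stop(structure(class = c("psmcea_no_median", "error", "condition"),
                   list(message = "survival never reaches 0.5 for this Gompertz model",
                        call = sys.call())))
  if (method == "closed_form") {
    med <- switch(model$family,
      exponential = log(2) / p[["rate"]],
      weibull     = p[["scale"]] * log(2)^(1 / p[["shape"]]),
      loglogistic = (1 / p[["rate"]])^(1 / p[["shape"]]),
      lognormal   = exp(p[["meanlog"]]),
      NULL)
    if (!is.null(med)) return(med)
  }
  # bracketing root-finder on f(t) = S(t) - 0.5
  hi <- 1
  while (survival_at(model, hi) > 0.5 && hi < 1e12) hi <- hi * 2
  if (survival_at(model, hi) > 0.5)
    stop(structure(class = c("psmcea_no_median", "error", "condition"),
                   list(message = "survival never reaches 0.5 on the searchable horizon",
                        call = sys.call())))
  uniroot(function(t) survival_at(model, t) - 0.5, c(0, hi), tol = 1e-9 * hi)$root
}

# map between our family names and flexsurv distribution codes
.flexsurv_dist <- c(weibull = "weibull", loglogistic = "llogis",
                    lognormal = "lnorm", exponential = "exp",
                    gompertz = "gompertz", gamma = "gamma")

# flexsurv natural parameters -> our parameterization
.from_flexsurv <- function(family, est) {
  switch(family,
    weibull     = c(shape = unname(est["shape"]), scale = unname(est["scale"])),
    # flexsurv llogis: S(t) = 1/(1 + (t/scale)^shape)  =>  rate = scale^(-shape)
    loglogistic = c(shape = unname(est["shape"]),
                    rate  = unname(est["scale"])^(-unname(est["shape"]))),
    lognormal   = c(meanlog = unname(est["meanlog"]), sdlog = unname(est["sdlog"])),
    exponential = c(rate = unname(est["rate"])),
    gompertz    = c(shape = unname(est["shape"]), rate = unname(est["rate"])),
    gamma       = c(shape = unname(est["shape"]), rate = unname(est["rate"]))
  )
}

#' Fit a parametric family to right-censored survival data
#'
#' Maximum-likelihood fitting with right censoring: events contribute the
#' density, censored observations the survivor function.  Fitting is
#' delegated to [flexsurv::flexsurvreg()]; estimates are reported in this
#' package's parameterization (rate-form log-logistic).
#'
#' @param times Nonnegative observed times (event or censoring).
#' @param event_flags Logical/0-1 vector; `TRUE` = event observed.
#' @param family Candidate family name (see [parametric_survival()]).
#' @param time_unit Time unit the observations are expressed in.
#' @return A `fit_report`: family, fitted params, log-likelihood, AIC, BIC,
#'   event/censoring counts and a convergence flag.
#' @export
fit_parametric <- function(times, event_flags, family,
                           time_unit = c("cycle", "week", "month")) {
  family <- match.arg(family, SURVIVAL_FAMILIES)
  time_unit <- match.arg(time_unit)
  event_flags <- as.logical(event_flags)
  if (length(times) != length(event_flags)) stop("length mismatch")
  if (length(times) < 10) stop("need at least 10 observations")
  if (any(!is.finite(times)) || any(times < 0)) stop("times must be nonnegative")
  if (!any(event_flags))
    stop("all observations censored: parameters are unidentifiable")
  fit <- flexsurv::flexsurvreg(
    survival::Surv(times, event_flags) ~ 1,
    dist = .flexsurv_dist[[family]]
  )
  if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0)
    stop("optimizer failed to converge for family '", family, "'")
  est <- setNames(fit$res[, "est"], rownames(fit$res))
  k <- fit$npars
  n <- length(times)
  ll <- fit$loglik
  structure(list(
    family        = family,
    params        = .from_flexsurv(family, est),
    time_unit     = time_unit,
    log_likelihood = ll,
    k             = k,
    aic           = 2 * k - 2 * ll,
    bic           = k * log(n) - 2 * ll,
    n             = n,
    n_events      = sum(event_flags),
    n_censored    = sum(!event_flags),
    converged     = TRUE
  ), class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %s: loglik %.3f, AIC %.3f, BIC %.3f (%d events / %d censored)\n",
              x$family, x$log_likelihood, x$aic, x$bic, x$n_events, x$n_censored))
  print(round(x$params, 6))
  invisible(x)
}

#' Coerce a fit report to the fitted survival model
#' @param report A `fit_report`.
#' @return A [parametric_survival] with the fitted parameters.
#' @export
as_parametric_survival <- function(report) {
  stopifnot(inherits(report, "fit_report"))
  parametric_survival(report$family, report$params, report$time_unit)
}

#' Select the best-fitting family by information criterion
#'
#' Returns the report minimising AIC (or BIC).  Ties are broken first by
#' parsimony (fewer free parameters) and then by the declared family order,
#' so selection is deterministic.
#'
#' @param reports Non-empty list of `fit_report` objects.
#' @param criterion `"aic"` or `"bic"`.
#' @return The winning `fit_report`.
#' @export
select_best_fit <- function(reports, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(reports) == 0) stop("empty report list")
  stopifnot(all(vapply(reports, inherits, TRUE, "fit_report")))
  crit <- vapply(reports, `[[`, numeric(1), criterion)
  k    <- vapply(reports, `[[`, numeric(1), "k")
  ord  <- match(vapply(reports, `[[`, character(1), "family"), SURVIVAL_FAMILIES)
  reports[[order(crit, k, ord)[1]]]
}

#' Tabulate fit reports
#'
#' Flattens a list of fit reports into a data frame (one row per family)
#' suitable for export as the model-selection supplementary table.
#'
#' @param reports List of `fit_report` objects.
#' @return A data frame with family, parameters, log-likelihood, AIC, BIC
#'   and event counts.
#' @export
fit_report_table <- function(reports) {
  stopifnot(length(reports) > 0)
  do.call(rbind, lapply(reports, function(r) {
    data.frame(family = r$family,
               params = paste(sprintf("%s=%.6g", names(r$params), r$params),
                              collapse = "; "),
               log_likelihood = r$log_likelihood,
               k = r$k, aic = r$aic, bic = r$bic,
               n_events = r$n_events, n_censored = r$n_censored,
               stringsAsFactors = FALSE)
  }))
}
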