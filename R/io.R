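#' @importFrom utils write.csv packageVersion
NULL

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Write analysis reports to a directory
#'
#' Writes delimited-table and structured-text reports for whichever results
#' are supplied: per-arm occupancy traces and cost schedules plus a JSON
#' base-case summary, the tornado table, the PSA draw table with a CEAC,
#' and the parametric fit-report table.  A plain-text run log records the
#' seed, configuration hash and every convention toggle.
#'
#' @param out_dir Output directory (created if absent).
#' @param base_case Optional `base_case` from [run_base_case()].
#' @param tornado Optional `tornado` from [one_way_dsa()].
#' @param psa Optional `psa_result` from [run_psa()].
#' @param fit_reports Optional list of `fit_report`s.
#' @param config The configuration used (for the log; defaults to the
#'   base case's).
#' @param seed Seed to record in the log.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(out_dir, base_case = NULL, tornado = NULL,
                          psa = NULL, fit_reports = NULL,
                          config = if (!is.null(base_case)) base_case$config,
                          seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(x, file, writer = write.csv) {
    p <- file.path(out_dir, file)
    writer(x, p)
    written <<- c(written, p)
  }
  if (!is.null(base_case)) {
    for (a in names(base_case$arms)) {
      put(base_case$arms[[a]]$trace, paste0("trace_", a, ".csv"),
          function(x, p) write.csv(x, p, row.names = FALSE))
      put(base_case$arms[[a]]$schedule, paste0("schedule_", a, ".csv"),
          function(x, p) write.csv(x, p, row.names = FALSE))
    }
    r <- base_case$incremental
    put(list(arms = stats::setNames(
               lapply(seq_along(r$labels), function(i)
                 list(cost = r$cost[i], qaly = r$qaly[i])), r$labels),
             incremental_cost = r$incremental_cost,
             incremental_qaly = r$incremental_qaly,
             icer = r$icer, dominance = r$dominance,
             wtp_per_qaly = r$wtp_per_qaly,
             cost_effective_at_wtp = r$cost_effective_at_wtp),
        "base_case.json",
        function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                            digits = NA, pretty = TRUE))
  }
  if (!is.null(tornado))
    put(as.data.frame(tornado), "tornado.csv",
        function(x, p) write.csv(x, p, row.names = FALSE))
  if (!is.null(psa)) {
    put(psa$draws, "psa_draws.csv",
        function(x, p) write.csv(x, p, row.names = FALSE))
    grid <- seq(0, 2 * psa$wtp, length.out = 101)
    put(ceac(psa, grid), "ceac.csv",
        function(x, p) write.csv(x, p, row.names = FALSE))
  }
  if (!is.null(fit_reports))
    put(fit_report_table(fit_reports), "fit_reports.csv",
        function(x, p) write.csv(x, p, row.names = FALSE))

  log_lines <- c(
    paste0("psmcea ", as.character(packageVersion("psmcea"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("seed: ", if (is.null(seed)) "<not set>" else seed),
    if (!is.null(config)) c(
      paste0("config_md5: ", .config_hash(config)),
      paste0("time_unit: ", config$time_unit),
      paste0("half_cycle_correction: ",
             isTRUE(config$settings$half_cycle_correction)),
      paste0("discounting: ", config$settings$discounting),
      paste0("vial_policy: ", config$conventions$vial_policy),
      paste0("ae_application: ", config$conventions$ae_application),
      paste0("subsequent_max_cycles: ",
             config$conventions$subsequent_max_cycles),
      vapply(names(config$arms), function(a)
        paste0("maintenance_max_cycles[", a, "]: ",
               config$arms[[a]]$maintenance_max_cycles), character(1))
    )
  )
  logp <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, logp)
  invisible(c(written, logp))
}
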