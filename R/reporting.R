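# Run configuration and file-based reporting: base case, tornado, PSA/CEAC
# exports with an audit trail of every resolved assumption.

#' Build a run configuration
#'
#' Collects everything a reporting run needs: the configuration source (a
#' parameter file path or an in-memory `ad_parameters` object), the output
#' directory, the model options with their base-case defaults (3% discount
#' via the parameter file, multiplicative hazard-ratio transform,
#' treat-while-early-AD, no half-cycle correction, age cap 100, WTP
#' $150,000/QALY, 1,000 PSA draws), and optional per-parameter overrides
#' applied with [set_param()].
#'
#' @param params_file Path to a YAML configuration (default: the shipped
#'   base case).
#' @param params Optional `ad_parameters` object (takes precedence).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the PSA.
#' @param n_draws Number of PSA draws.
#' @param wtp Willingness-to-pay threshold, US$/QALY.
#' @param wtp_grid CEAC grid.
#' @param hr_method,half_cycle,age_cap Model options, see [cea_model()].
#' @param treatment_rule Optional override of every drug arm's treatment
#'   rule (`"while_early_AD"` or `"lifetime"`).
#' @param discount Optional override of all discount rates.
#' @param overrides Named list of dotted parameter paths to values.
#' @return A list of class `"run_config"`.
#' @export
make_run_config <- function(params_file = NULL, params = NULL,
                            out_dir = tempdir(),
                            seed = 1L, n_draws = 1000,
                            wtp = 150000,
                            wtp_grid = seq(0, 2e6, by = 1e4),
                            hr_method = "multiplicative",
                            half_cycle = FALSE,
                            age_cap = NULL,
                            treatment_rule = NULL,
                            discount = NULL,
                            overrides = list()) {
  structure(list(
    params_file = params_file, params = params, out_dir = out_dir,
    seed = seed, n_draws = n_draws, wtp = wtp, wtp_grid = wtp_grid,
    hr_method = hr_method, half_cycle = half_cycle, age_cap = age_cap,
    treatment_rule = treatment_rule, discount = discount,
    overrides = overrides
  ), class = "run_config")
}

resolve_config_params <- function(config) {
  params <- config$params
  if (is.null(params)) {
    path <- config$params_file %||%
      system.file("extdata", "table1_params.yaml", package = "adcea")
    params <- load_parameters(path)
  }
  if (!is.null(config$discount)) {
    params$discount_rate <- config$discount
    for (nm in names(params$strategies)) {
      if (!is.null(params$strategies[[nm]]$discount_rate)) {
        params$strategies[[nm]]$discount_rate <- config$discount
      }
    }
  }
  if (!is.null(config$age_cap)) params$age_cap <- config$age_cap
  if (!is.null(config$treatment_rule)) {
    for (nm in treated_strategy_names(params)) {
      params$strategies[[nm]]$treatment_rule <- config$treatment_rule
    }
  }
  params$wtp_default <- config$wtp %||% params$wtp_default
  for (nm in names(config$overrides)) {
    params <- set_param(params, nm, config$overrides[[nm]])
  }
  v <- validate_parameters(params)
  if (length(v)) {
    stop("run configuration is invalid:\n  - ", paste(v, collapse = "\n  - "),
         call. = FALSE)
  }
  params
}

write_run_log <- function(config, params, path, extra = character(0)) {
  lines <- c(
    sprintf("timestamp=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("hr_method=%s", config$hr_method),
    sprintf("half_cycle=%s", config$half_cycle),
    sprintf("treatment_rule=%s",
            paste(vapply(params$strategies, `[[`, character(1), "treatment_rule"),
                  collapse = ",")),
    sprintf("age_cap=%s", params$age_cap),
    sprintf("discount_rate=%s", params$discount_rate),
    sprintf("wtp=%s", params$wtp_default),
    sprintf("seed=%s", config$seed %||% NA),
    sprintf("n_draws=%s", config$n_draws),
    extra
  )
  writeLines(lines, path)
  invisible(path)
}

#' Run the base case and write its report files
#'
#' Evaluates the model under the run configuration and writes
#' `base_case.csv` (per-strategy discounted and undiscounted outcomes, then
#' one row per pairwise comparison), `params_audit.csv`, and `run_log.txt`
#' recording every resolved model option. Validation failures abort with
#' the violation list before anything is written.
#'
#' @param config A [make_run_config()] object.
#' @return Invisibly, a list with the fitted `cea_model` and the written
#'   file paths.
#' @export
run_base_case <- function(config = make_run_config()) {
  params <- resolve_config_params(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- cea_model(params, hr_method = config$hr_method,
                   half_cycle = config$half_cycle, wtp = params$wtp_default)

  res <- fit$results
  strat_tab <- data.frame(
    row_type = "strategy",
    name = names(res),
    intervention = NA, reference = NA,
    cost = vapply(res, `[[`, numeric(1), "cost"),
    ly = vapply(res, `[[`, numeric(1), "ly"),
    qaly = vapply(res, `[[`, numeric(1), "qaly"),
    cost_undisc = vapply(res, `[[`, numeric(1), "cost_undisc"),
    ly_undisc = vapply(res, `[[`, numeric(1), "ly_undisc"),
    qaly_undisc = vapply(res, `[[`, numeric(1), "qaly_undisc"),
    delta_cost = NA, delta_ly = NA, delta_qaly = NA,
    icer_per_ly = NA, icer_per_qaly = NA, dominance = NA, cost_effective = NA,
    row.names = NULL
  )
  cmp <- fit$comparisons
  cmp_tab <- data.frame(
    row_type = "comparison",
    name = paste(cmp$intervention, "vs", cmp$reference),
    intervention = cmp$intervention, reference = cmp$reference,
    cost = NA, ly = NA, qaly = NA,
    cost_undisc = NA, ly_undisc = NA, qaly_undisc = NA,
    delta_cost = round(cmp$delta_cost, 2),
    delta_ly = round(cmp$delta_ly, 2),
    delta_qaly = round(cmp$delta_qaly, 2),
    icer_per_ly = round(cmp$icer_per_ly, 2),
    icer_per_qaly = round(cmp$icer_per_qaly, 2),
    dominance = cmp$dominance,
    cost_effective = cmp$cost_effective
  )
  files <- list(
    base_case = file.path(config$out_dir, "base_case.csv"),
    params_audit = file.path(config$out_dir, "params_audit.csv"),
    run_log = file.path(config$out_dir, "run_log.txt")
  )
  utils::write.csv(rbind(strat_tab, cmp_tab), files$base_case, row.names = FALSE)
  utils::write.csv(params_audit(params), files$params_audit, row.names = FALSE)
  write_run_log(config, params, files$run_log)
  invisible(list(model = fit, files = files))
}

#' Run the one-way sensitivity analysis and write tornado.csv
#'
#' @param config A [make_run_config()] object.
#' @param comparison Character pair `c(intervention, reference)`.
#' @return Invisibly, a list with the `cea_tornado` table and file paths.
#' @export
run_osa <- function(config = make_run_config(),
                    comparison = c("lecanemab", "aducanumab")) {
  params <- resolve_config_params(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tor <- one_way_sensitivity(params, comparison,
                             hr_method = config$hr_method,
                             half_cycle = config$half_cycle)
  path <- file.path(config$out_dir, "tornado.csv")
  utils::write.csv(as.data.frame(tor), path, row.names = FALSE)
  write_run_log(config, params, file.path(config$out_dir, "run_log.txt"),
                extra = sprintf("osa_comparison=%s_vs_%s", comparison[1], comparison[2]))
  invisible(list(tornado = tor, files = list(tornado = path)))
}

#' Run the PSA and write psa_samples.csv and ceac.csv
#'
#' Both files start with comment lines (prefixed `#`) embedding the seed,
#' the number of draws and the WTP grid, so two runs are comparable by
#' diffing headers; read them back with `read.csv(..., comment.char =
#' "#")`.
#'
#' @param config A [make_run_config()] object.
#' @return Invisibly, a list with the `cea_psa` object, the CEAC table and
#'   file paths.
#' @export
run_psa_report <- function(config = make_run_config()) {
  params <- resolve_config_params(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(params, n_draws = config$n_draws, seed = config$seed,
                 hr_method = config$hr_method, half_cycle = config$half_cycle)
  cc <- ceac(psa, wtp_grid = config$wtp_grid)
  header <- c(
    sprintf("# seed=%s", config$seed %||% NA),
    sprintf("# n_draws=%s", config$n_draws),
    sprintf("# wtp_grid=%s:%s:%s", min(config$wtp_grid), max(config$wtp_grid),
            length(config$wtp_grid))
  )
  files <- list(psa_samples = file.path(config$out_dir, "psa_samples.csv"),
                ceac = file.path(config$out_dir, "ceac.csv"))
  for (f in names(files)) {
    tab <- if (f == "psa_samples") psa$samples else as.data.frame(cc)
    con <- file(files[[f]], "w")
    writeLines(header, con)
    utils::write.csv(tab, con, row.names = FALSE)
    close(con)
  }
  write_run_log(config, params, file.path(config$out_dir, "run_log.txt"))
  invisible(list(psa = psa, ceac = cc, files = files))
}
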