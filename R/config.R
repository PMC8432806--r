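# Experiment drivers behind the command-line surface (inst/cli/phenoswitch).
# Configuration is a JSON (or YAML, when the yaml package is available)
# document with blocks: model (flat parameter keys as in write_params),
# pk (t_half, vol, c_half, t_admin), schedule ({start_days, end_days,
# period_days, dose} or a CSV path), experiment, seed, n0.  Times in the
# config are in days; everything internal is hours.

#' Read a run configuration
#'
#' @param path JSON or YAML configuration file.
#' @return A validated list of class `run_config` with elements `params`
#'   ([model_params()]), `pk` ([pk_params()] or `NULL`), `schedule`
#'   ([dose_schedule()] or `NULL`), `n0`, `seed`, `experiment`, and the
#'   raw document under `raw`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs need the yaml package; use JSON")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param raw A configuration list.
#' @export
as_run_config <- function(raw) {
  bad <- setdiff(names(raw), c("model", "pk", "schedule", "experiment",
                               "scenario", "n0", "seed", "t_span_days",
                               "window_days", "dose", "period_days",
                               "theta_threshold", "candidates_days", "D_MTD"))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  params <- if (!is.null(raw$scenario)) scenario(raw$scenario)
  else if (!is.null(raw$model)) {
    m <- raw$model
    model_params(m$r_A, m$r_B, m$d_A,
                 if (is.null(m$d_B)) m$d_A else m$d_B,
                 if (is.null(m$d_A_max)) m$d_A else m$d_A_max,
                 strategy_A = switching_strategy(m$p_min_AA, m$p_max_AA,
                                                 m$sigma_A),
                 strategy_B = switching_strategy(m$p_min_BB, m$p_max_BB,
                                                 m$sigma_B),
                 growth = growth_law(m$growth_mode,
                                     K = if (is.null(m$K)) NA_real_ else m$K,
                                     n = if (is.null(m$n)) 1 else m$n))
  } else stop("config needs a model block or a scenario name")
  pk <- if (!is.null(raw$pk))
    pk_params(raw$pk$t_half, raw$pk$vol %||% 1, raw$pk$c_half %||% 1,
              raw$pk$t_admin %||% 1)
  else if (!is.null(raw$scenario)) scenario_pk(raw$scenario)
  sched <- if (!is.null(raw$schedule)) {
    s <- raw$schedule
    if (!is.null(s$csv)) {
      d <- utils::read.csv(s$csv)
      dose_schedule(d$time_hours, d$dose,
                    t_admin = if (is.null(pk)) 1 else pk$t_admin)
    } else periodic_schedule(s$start_days * 24, s$end_days * 24,
                             s$period_days * 24, s$dose,
                             t_admin = if (is.null(pk)) 1 else pk$t_admin)
  }
  structure(list(params = params, pk = pk, schedule = sched,
                 n0 = raw$n0 %||% 1000, seed = raw$seed %||% 1,
                 experiment = raw$experiment %||% "custom", raw = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation driver
#'
#' Runs [simulate_population()] under a configuration and writes the
#' trajectory CSV plus a JSON run summary (final state, burden when a
#' carrying capacity is defined, parameters, seed).
#'
#' @param config A `run_config` (or path to one).
#' @param out_dir Output directory (created if needed).
#' @return The trajectory, invisibly.
#' @export
cmd_simulate <- function(config, out_dir = ".") {
  config <- .ensure_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  span <- (config$raw$t_span_days %||% c(0, 100)) * 24
  tr <- simulate_population(config$params, config$pk, config$schedule,
                            t_span = span, n0 = config$n0)
  write_trajectory(tr, file.path(out_dir, "trajectory.csv"))
  fin <- tr$states[nrow(tr$states), ]
  summ <- list(final_state = as.list(fin), seed = config$seed,
               experiment = config$experiment,
               burden = if (is.finite(config$params$growth$K))
                 burden(tr) else NULL)
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(tr)
}

#' Fitness-analysis driver
#'
#' Writes the scalar fitness report and, for Malthusian configurations, a
#' grid of the population growth rate over the constituent net growth
#' rates `(lambda_A, lambda_B)` (one CSV per run).
#'
#' @param config A `run_config` (or path).
#' @param out_dir Output directory.
#' @param grid_lambda Net-rate grid (per hour) for the lambda_P surface.
#' @return The report list, invisibly.
#' @export
cmd_analyze <- function(config, out_dir = ".",
                        grid_lambda = seq(-0.02, 0.04, by = 0.005)) {
  config <- .ensure_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  pm <- model_params(p$r_A, p$r_B, p$d_A, p$d_B, p$d_A_max,
                     strategy_A = p$strategy_A, strategy_B = p$strategy_B)
  rep <- fitness_report(pm, config$pk, periods_days = 1:7)
  write_fitness_report(rep, file.path(out_dir, "fitness.json"))
  g <- malthusian_grid(grid_lambda, grid_lambda, pm$strategy_A,
                       pm$strategy_B, d = pm$d_A,
                       sigma = pm$strategy_A$sigma)
  utils::write.csv(
    data.frame(lambda_A = rep(grid_lambda, each = length(grid_lambda)),
               lambda_B = rep(grid_lambda, times = length(grid_lambda)),
               lambda_P = as.vector(t(g))),
    file.path(out_dir, "lambda_grid.csv"), row.names = FALSE)
  invisible(rep)
}

#' Population growth rate over a grid of constituent rates
#'
#' Evaluates [malthusian_parameter()] on a grid of `(lambda_A, lambda_B)`
#' by holding the death rates at `d` and setting `r_i = lambda_i + d`;
#' entries where a division rate would be negative are `NA`.
#'
#' @param lambda_A_seq,lambda_B_seq Net rates, per hour.
#' @param strategy_A,strategy_B Switching strategies.
#' @param d Common death rate, per hour.
#' @param sigma Unused placeholder kept for config symmetry.
#' @return Matrix `length(lambda_A_seq) x length(lambda_B_seq)`.
#' @export
malthusian_grid <- function(lambda_A_seq, lambda_B_seq, strategy_A,
                            strategy_B, d = 0.01, sigma = 0.01) {
  outer(lambda_A_seq, lambda_B_seq, Vectorize(function(la, lb) {
    if (la + d <= 0 || lb + d <= 0) return(NA_real_)
    malthusian_parameter(model_params(la + d, lb + d, d, d,
                                      strategy_A = strategy_A,
                                      strategy_B = strategy_B,
                                      check_cost = FALSE))
  }))
}

#' Fitting driver
#'
#' @param config A `run_config` (or path).
#' @param dataset_files Paths to growth-assay CSVs ([read_assay()] format).
#' @param out_dir Output directory.
#' @param ... Passed to [fit_growth_model()].
#' @return The fit, invisibly.
#' @export
cmd_fit <- function(config, dataset_files, out_dir = ".", ...) {
  config <- .ensure_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  datasets <- do.call(c, lapply(dataset_files, read_assay))
  fit <- fit_growth_model(datasets, seed = config$seed, ...)
  write_fit(fit, file.path(out_dir, "fit.json"))
  invisible(fit)
}

#' Therapy-comparison driver
#'
#' Selects the dosing period for model-informed therapy, runs the
#' informed and the weekly periodic comparator schedules, and writes both
#' trajectories, the decision log, and a JSON outcome summary with the
#' burden ratio.
#'
#' @param config A `run_config` (or path); the `window_days` key sets the
#'   dosing window (default days 50 to 150).
#' @param out_dir Output directory.
#' @return List with the selection result, both outcomes, and the burden
#'   ratio, invisibly.
#' @export
cmd_schedule <- function(config, out_dir = ".") {
  config <- .ensure_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  window <- (config$raw$window_days %||% c(50, 150)) * 24
  sel <- select_period(p, config$pk,
                       candidates_days = config$raw$candidates_days %||% 1:7,
                       D_MTD = config$raw$D_MTD,
                       window = window, n0 = config$n0)
  if (is.na(sel$T_days)) {
    jsonlite::write_json(list(feasible = FALSE,
                              diagnostics = sel$diagnostics),
                         file.path(out_dir, "schedule.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(sel))
  }
  per <- run_periodic(p, config$pk, sel$D_MTD, 7 * 24, window,
                      n0 = config$n0)
  ratio <- compare_burden(sel$outcome, per)
  write_trajectory(sel$outcome$trajectory,
                   file.path(out_dir, "informed_trajectory.csv"))
  write_trajectory(per$trajectory,
                   file.path(out_dir, "periodic_trajectory.csv"))
  utils::write.csv(sel$outcome$decisions,
                   file.path(out_dir, "decisions.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(feasible = TRUE, chosen_T_days = sel$T_days, dose = sel$dose,
         D_MTD = sel$D_MTD, burden_informed = sel$outcome$burden,
         burden_periodic = per$burden, burden_ratio = ratio,
         doses_given = sel$outcome$doses_given,
         doses_skipped = sel$outcome$doses_skipped,
         resistance_informed = sel$outcome$resistance_established,
         resistance_periodic = per$resistance_established,
         seed = config$seed),
    file.path(out_dir, "schedule.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(selection = sel, periodic = per, burden_ratio = ratio))
}

#' Synthetic-data driver
#'
#' @param config A `run_config` (or path); the scenario or model block
#'   provides the generating truth.
#' @param out_dir Output directory.
#' @param design An [assay_design()]; defaults to the standard design with
#'   the config's seed.
#' @return The dataset list, invisibly.
#' @export
cmd_generate <- function(config, out_dir = ".", design = NULL) {
  config <- .ensure_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design)) design <- assay_design(seed = config$seed)
  p <- config$params
  pm <- model_params(p$r_A, p$r_B, p$d_A, p$d_B, p$d_A_max,
                     strategy_A = p$strategy_A, strategy_B = p$strategy_B)
  datasets <- generate_assays(pm, design, n0 = config$n0)
  write_assay(datasets, file.path(out_dir, "assays.csv"))
  jsonlite::write_json(unclass(design), file.path(out_dir, "design.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(datasets)
}

.ensure_config <- function(config) {
  if (is.character(config)) read_run_config(config)
  else if (inherits(config, "run_config")) config
  else as_run_config(config)
}
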