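#' Growth-assay design
#'
#' Describes the emulated in vitro spheroid growth assay: cells counted on
#' a handful of days, with the drug condition switching to a constant
#' lethal bath after an initial untreated growth phase, and multiplicative
#' (mean-preserving lognormal) count noise.
#'
#' @param days Observation days (default `c(1, 3, 5, 7)`).
#' @param t_treat Start of the constant lethal drug exposure, hours
#'   (default 72).
#' @param conditions Subset of `c("untreated", "drug")`.
#' @param noise `"none"` or `"lognormal"`.
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.10).
#' @param n_replicates Replicates per condition.
#' @param seed RNG seed; the generator is fully deterministic given the
#'   design.
#' @return An object of class `assay_design`.
#' @export
assay_design <- function(days = c(1, 3, 5, 7), t_treat = 72,
                         conditions = c("untreated", "drug"),
                         noise = c("lognormal", "none"), cv = 0.10,
                         n_replicates = 1, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(cv >= 0, !is.unsorted(days, strictly = TRUE))
  conditions <- match.arg(conditions, c("untreated", "drug"),
                          several.ok = TRUE)
  structure(list(days = days, t_treat = t_treat, conditions = conditions,
                 noise = noise, cv = cv, n_replicates = n_replicates,
                 seed = seed),
            class = "assay_design")
}

#' Generate synthetic growth-assay datasets
#'
#' Simulates the model per condition (the drug condition switches the
#' sensitive death rate to `d_A_max` at `t_treat`), samples the total
#' count at the design days, and applies mean-preserving lognormal noise
#' with the design's coefficient of variation.  Deterministic given
#' `design$seed`.
#'
#' @param params_true A [model_params()].
#' @param design An [assay_design()].
#' @param n0 Initial total population at time 0, cells.
#' @param drug_name Label recorded in the datasets.
#' @return A list of growth-assay data frames (columns `time_hours`,
#'   `count`, `condition`, `drug`, `t_treat_hours`, `replicate`), one per
#'   condition and replicate.
#' @export
generate_assays <- function(params_true, design, n0 = 1000,
                            drug_name = "drug") {
  stopifnot(inherits(design, "assay_design"))
  tt <- design$days * 24
  init <- initial_state(params_true, n0)
  noiseless <- lapply(design$conditions, function(cond) {
    d <- data.frame(time_hours = c(0, tt), count = n0, condition = cond,
                    drug = drug_name, t_treat_hours = design$t_treat)
    d$count <- predicted_total(params_true, d)
    d[-1, , drop = FALSE]          # drop the t = 0 anchor row
  })
  names(noiseless) <- design$conditions
  set.seed(design$seed)
  sdlog <- sqrt(log(1 + design$cv^2))
  out <- list()
  for (r in seq_len(design$n_replicates)) {
    for (cond in design$conditions) {
      d <- noiseless[[cond]]
      if (design$noise == "lognormal" && design$cv > 0)
        d$count <- d$count * stats::rlnorm(nrow(d), -sdlog^2 / 2, sdlog)
      d$replicate <- r
      rownames(d) <- NULL
      out[[length(out) + 1L]] <- d
    }
  }
  out
}

#' Named parameter scenarios
#'
#' Fully populated parameter sets used by the packaged experiments.  The
#' `switch`, `stay` and `symmetric` scenarios share a generic tumour
#' parameter set and differ only in the tolerant retention strategy
#' (`(0, 0.9)`, `(0.95, 1)` and `(0.9, 0.95)` respectively, with the
#' sensitive side fixed at `(0.9, 0.95)`).  The `wt_like` and `m1_like`
#' scenarios are synthetic stand-ins for docetaxel-treated NSCLC lineages:
#' they satisfy the fitted regime `lambda_A > 0 > lambda_B` (tolerant
#' cells decay when rare) and `lambda_A_star < 0` (treatment reverses
#' sensitive growth), with the faster-growing, more drug-responsive
#' `m1_like` variant mirroring the reported difference between the
#' lineages.  They are not measured values.
#'
#' @param name One of `"switch"`, `"stay"`, `"symmetric"`, `"wt_like"`,
#'   `"m1_like"`.
#' @return A [model_params()] object.
#' @export
scenario <- function(name = c("switch", "stay", "symmetric",
                              "wt_like", "m1_like")) {
  name <- match.arg(name)
  gen_A <- switching_strategy(0.9, 0.95, 0.01)
  gen_growth <- growth_law("logistic_allee", K = 1e6, n = 1)
  fit_A <- switching_strategy(0, 0.95, 0.01)   # fitting convention
  switch(name,
    switch = model_params(0.04, 0.02, 0.005, 0.005, 0.12,
                          strategy_A = gen_A,
                          strategy_B = switching_strategy(0, 0.9, 0.01),
                          growth = gen_growth),
    stay = model_params(0.04, 0.02, 0.005, 0.005, 0.12,
                        strategy_A = gen_A,
                        strategy_B = switching_strategy(0.95, 1, 0.01),
                        growth = gen_growth),
    symmetric = model_params(0.04, 0.02, 0.005, 0.005, 0.12,
                             strategy_A = gen_A,
                             strategy_B = switching_strategy(0.9, 0.95, 0.01),
                             growth = gen_growth),
    wt_like = model_params(0.05, 0.006, 0.03, 0.03, 0.09,
                           strategy_A = fit_A,
                           strategy_B = switching_strategy(0.5, 0.9, 0.01),
                           growth = growth_law("logistic_allee", K = 1e8,
                                               n = 1)),
    m1_like = model_params(0.05, 0.006, 0.03, 0.03, 0.11,
                           strategy_A = fit_A,
                           strategy_B = switching_strategy(0.5, 0.9, 0.01),
                           growth = growth_law("logistic_allee", K = 1e8,
                                               n = 1)))
}

#' Pharmacokinetic scenarios
#'
#' Drug models paired with [scenario()]: the generic strategy experiments
#' use a short-lived cytotoxic (`t_half = 6` h); the NSCLC stand-ins use a
#' docetaxel-like half-life of 11 h.  Doses are in units of
#' `c_half * vol` throughout.
#'
#' @param name As in [scenario()].
#' @return A [pk_params()].
#' @export
scenario_pk <- function(name = c("switch", "stay", "symmetric",
                                 "wt_like", "m1_like")) {
  name <- match.arg(name)
  if (name %in% c("wt_like", "m1_like")) pk_params(t_half = 11)
  else pk_params(t_half = 6)
}

#' Scenario weekly dose caps
#'
#' The maximally tolerated weekly dose paired with each NSCLC stand-in
#' (units of `c_half * vol`).  The cap bounds the per-period dose of the
#' informed scheduler through `D_MTD * T / 7` and is the per-dose size of
#' the weekly periodic comparator.
#'
#' @param name As in [scenario()].
#' @return Weekly dose, or `NULL` for the generic strategy scenarios.
#' @export
scenario_mtd <- function(name = c("switch", "stay", "symmetric",
                                  "wt_like", "m1_like")) {
  name <- match.arg(name)
  switch(name, wt_like = 16, m1_like = 14, NULL)
}

#' Read / write growth-assay datasets
#'
#' CSV with columns `time_hours, count, condition, drug, t_treat_hours`
#' (and optionally `replicate`).
#'
#' @param path File path.
#' @return `read_assay` returns one data frame per `(condition, replicate)`
#'   group, as a list.
#' @export
read_assay <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_hours", "count", "condition", "t_treat_hours")
  if (!all(need %in% names(d)))
    stop("assay file must have columns: ", paste(need, collapse = ", "))
  if (is.null(d$replicate)) d$replicate <- 1L
  if (is.null(d$drug)) d$drug <- "drug"
  sp <- split(d, interaction(d$condition, d$replicate, drop = TRUE))
  lapply(unname(sp), function(g) g[order(g$time_hours), , drop = FALSE])
}

#' @rdname read_assay
#' @param datasets A data frame or list of data frames.
#' @export
write_assay <- function(datasets, path) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  utils::write.csv(do.call(rbind, datasets), path, row.names = FALSE)
  invisible(path)
}
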