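#' Therapy outcome container
#'
#' Returned by [run_periodic()] and [run_informed()]: the trajectory, a log
#' of every scheduled decision (given or skipped, with the gating ratio at
#' the decision time), the burden over the horizon, the resistance
#' classification and the maximal tolerant-to-sensitive ratio reached.
#'
#' @name therapy_outcome
NULL

.outcome <- function(trajectory, decisions, window, K, theta_threshold,
                     chosen_T = NA_real_) {
  traj_theta <- ifelse(trajectory$states[, "A"] > 0,
                       trajectory$states[, "B"] / trajectory$states[, "A"], Inf)
  structure(list(
    trajectory = trajectory,
    decisions = decisions,
    doses_given = sum(decisions$given),
    doses_skipped = sum(!decisions$given),
    window = window,
    burden = burden(trajectory, K = K),
    resistance_established = resistance_established(trajectory, window,
                                                    theta_threshold),
    theta_max = max(traj_theta[trajectory$times >= window[1] &
                                 trajectory$times <= window[2]]),
    theta_threshold = theta_threshold,
    chosen_T = chosen_T), class = "therapy_outcome")
}

#' @export
print.therapy_outcome <- function(x, ...) {
  cat(sprintf("therapy outcome: %d doses given, %d skipped over [%g, %g] d\n",
              x$doses_given, x$doses_skipped,
              x$window[1] / 24, x$window[2] / 24))
  cat(sprintf("  burden = %.4g, resistance established: %s, max theta = %.4g\n",
              x$burden, x$resistance_established, x$theta_max))
  invisible(x)
}

#' Unconditional periodic therapy
#'
#' Administers `dose` every `period` hours throughout the dosing window.
#'
#' @param params A [model_params()] (logistic growth recommended so the
#'   burden is defined).
#' @param pk A [pk_params()].
#' @param dose Per-administration amount (units of `c_half * vol`).
#' @param period Dosing interval, hours.
#' @param window `c(first dose, last decision)` in hours.
#' @param t_span Simulation horizon, hours; defaults to
#'   `c(0, window[2] + 100 days)`.
#' @param n0 Initial population (eigen composition); or supply `init`.
#' @param init Optional full initial state.
#' @param dt_out Output grid spacing, hours.
#' @return A `therapy_outcome`.
#' @export
run_periodic <- function(params, pk, dose, period, window, t_span = NULL,
                         n0 = 1000, init = NULL, dt_out = 2) {
  if (is.null(t_span)) t_span <- c(0, window[2] + 2400)
  sched <- periodic_schedule(window[1], window[2], period, dose,
                             t_admin = pk$t_admin)
  tr <- simulate_population(params, pk, sched, t_span, n0 = n0, init = init,
                            dt_out = dt_out)
  th <- vapply(sched$times, function(tm) {
    i <- which.min(abs(tr$times - tm))
    st <- tr$states[i, ]
    if (st["A"] > 0) st["B"] / st["A"] else Inf
  }, numeric(1))
  dec <- data.frame(time = sched$times, given = rep(TRUE, length(sched$times)),
                    theta = th)
  .outcome(tr, dec, window, params$growth$K, theta_threshold = Inf)
}

#' Model-informed (biomarker-gated) therapy
#'
#' At each decision time `window[1] + k * period` the dose is administered
#' iff the tolerant-to-sensitive ratio `theta(t) = B/A` is strictly below
#' `theta_threshold` (by default theta*, the self-sustainability threshold
#' from [theta_star()]); otherwise the dose is skipped so the sensitive
#' population can suppress the tolerant one by competition.  When the
#' sensitive population is extinct at a decision point, theta is infinite
#' and the dose is skipped (flagged in the decision log).
#'
#' @inheritParams run_periodic
#' @param theta_threshold Gate on `B/A`; `Inf` reproduces [run_periodic()],
#'   `0` never doses.
#' @return A `therapy_outcome`.
#' @export
run_informed <- function(params, pk, dose, period, window,
                         theta_threshold = theta_star(params),
                         t_span = NULL, n0 = 1000, init = NULL, dt_out = 2) {
  if (theta_threshold < 0) stop("theta_threshold must be nonnegative")
  if (is.null(t_span)) t_span <- c(0, window[2] + 2400)
  if (is.null(init)) init <- initial_state(params, n0)
  decision_times <- seq(window[1], window[2], by = period)
  edges <- sort(unique(c(t_span[1], decision_times, t_span[2])))
  edges <- edges[edges >= t_span[1] & edges <= t_span[2]]

  times_all <- numeric(0)
  states_all <- NULL
  given <- logical(length(decision_times))
  theta_at <- numeric(length(decision_times))
  y <- init
  for (k in seq_len(length(edges) - 1L)) {
    a <- edges[k]; b <- edges[k + 1L]
    di <- match(a, decision_times)
    sched <- NULL
    if (!is.na(di)) {
      theta_at[di] <- if (y["A"] > 0) unname(y["B"] / y["A"]) else Inf
      given[di] <- theta_at[di] < theta_threshold
      if (given[di])
        sched <- dose_schedule(a, dose, t_admin = pk$t_admin)
    }
    tr <- simulate_population(params, pk, sched, c(a, b), init = y,
                              dt_out = dt_out)
    y <- stats::setNames(tr$states[nrow(tr$states), ], .state_names)
    keep <- if (length(times_all)) tr$times > a else rep(TRUE, length(tr$times))
    times_all <- c(times_all, tr$times[keep])
    states_all <- rbind(states_all, tr$states[keep, , drop = FALSE])
  }
  traj <- structure(list(times = times_all, states = states_all,
                         schedule = dose_schedule(decision_times[given], dose,
                                                  t_admin = pk$t_admin),
                         params = params, pk = pk, lethal_from = NULL),
                    class = "pheno_trajectory")
  dec <- data.frame(time = decision_times, given = given, theta = theta_at)
  .outcome(traj, dec, window, params$growth$K, theta_threshold)
}

#' Classify establishment of treatment resistance
#'
#' Resistance is called when, over the final 20% of the dosing window, the
#' tolerant population dominates beyond the gating threshold (median
#' `theta > theta_threshold`) while dosing no longer controls growth
#' (least-squares slope of `log N(t)` >= 0).  Both conditions are required.
#' When the self-sustainability threshold theta* is undefined (tolerant
#' cells viable on their own, `lambda_B >= 0`), the dominance threshold
#' defaults to `theta = 1`.
#'
#' @param trajectory A `pheno_trajectory`.
#' @param window Dosing window `c(start, end)` in hours; `NULL` (no dosing)
#'   returns `FALSE` with attribute `applicable = FALSE`.
#' @param theta_threshold Dominance threshold; default theta* when defined,
#'   else 1.
#' @param tail_fraction Fraction of the window used for the classification.
#' @return Logical flag.
#' @export
resistance_established <- function(trajectory, window,
                                   theta_threshold = NULL,
                                   tail_fraction = 0.2) {
  if (is.null(window))
    return(structure(FALSE, applicable = FALSE))
  if (is.null(theta_threshold) || !is.finite(theta_threshold)) {
    theta_threshold <- tryCatch(theta_star(trajectory$params),
                                error = function(e) 1)
  }
  t0 <- window[2] - tail_fraction * (window[2] - window[1])
  sel <- trajectory$times >= t0 & trajectory$times <= window[2]
  if (sum(sel) < 3) return(structure(FALSE, applicable = FALSE))
  A <- trajectory$states[sel, "A"]
  B <- trajectory$states[sel, "B"]
  N <- A + B
  th <- ifelse(A > 0, B / A, Inf)
  slope <- stats::coef(stats::lm(log(pmax(N, .Machine$double.xmin)) ~
                                   trajectory$times[sel]))[2]
  isTRUE(stats::median(th) > theta_threshold && slope >= 0)
}

#' Choose the dosing period for model-informed therapy
#'
#' For each candidate period `T` (days) the per-administration dose is the
#' minimal dose that forces per-period decay ([min_effective_dose()]),
#' capped at `D_MTD * T / 7` so the cumulative dose never exceeds the
#' weekly maximally tolerated amount.  A biomarker-gated run is then
#' simulated and `T` is feasible when the population shows sustained decay
#' (final `N` below `N` at treatment start and negative log-slope over the
#' final 30 days) without established resistance.  The largest feasible
#' period is returned.
#'
#' @param params A [model_params()].
#' @param pk A [pk_params()].
#' @param candidates_days Candidate periods, days.
#' @param D_MTD Weekly maximally tolerated dose (units of `c_half * vol`);
#'   default 1.5 times the minimal effective weekly dose.
#' @param window Dosing window, hours.
#' @param t_span Simulation horizon, hours.
#' @param n0,init Initial condition (see [run_periodic()]).
#' @param criterion Dose-threshold criterion passed to
#'   [min_effective_dose()]; the default `"sensitive"` doses to force
#'   per-period decay of the drug-sensitive compartment (the gate keeps the
#'   tolerant compartment below theta*).
#' @param decay_margin Targeted decay rate of the gated compartment, per
#'   hour: the bisection aims at a per-period multiplier
#'   `exp(-decay_margin * T)` rather than exactly 1, since the threshold
#'   dose is only a sufficient condition at the linearized level and a
#'   neutral dose leaves no room for skipped administrations.
#' @return List with `T_days`, `dose`, the winning `outcome`, and a
#'   per-candidate `diagnostics` data frame.  When no candidate is feasible
#'   `T_days` is `NA` and the diagnostics explain each failure.
#' @export
select_period <- function(params, pk, candidates_days = 1:7, D_MTD = NULL,
                          window, t_span = NULL, n0 = 1000, init = NULL,
                          criterion = "sensitive", decay_margin = 0.002) {
  if (!length(candidates_days)) stop("no candidate periods")
  if (is.null(D_MTD)) {
    wk <- min_effective_dose(params, pk, 7 * 24,
                             cap = .default_dose_cap(params, pk),
                             criterion = criterion,
                             rho_target = exp(-decay_margin * 7 * 24))
    if (!wk$feasible) {
      diag <- data.frame(T_days = candidates_days, dose = NA_real_,
                         feasible_dose = FALSE, sustained_decay = FALSE,
                         resistance = NA)
      return(list(T_days = NA_real_, dose = NA_real_, outcome = NULL,
                  D_MTD = NA_real_, diagnostics = diag))
    }
    D_MTD <- 1.5 * wk$dose
  }
  diag <- data.frame(T_days = candidates_days, dose = NA_real_,
                     feasible_dose = FALSE, sustained_decay = FALSE,
                     resistance = NA)
  outcomes <- vector("list", length(candidates_days))
  for (i in seq_along(candidates_days)) {
    Td <- candidates_days[i]
    md <- min_effective_dose(params, pk, Td * 24, cap = D_MTD * Td / 7,
                             criterion = criterion,
                             rho_target = exp(-decay_margin * Td * 24))
    diag$dose[i] <- md$dose
    diag$feasible_dose[i] <- md$feasible
    if (!md$feasible) next
    out <- run_informed(params, pk, md$dose, Td * 24, window,
                        t_span = t_span, n0 = n0, init = init)
    outcomes[[i]] <- out
    diag$resistance[i] <- out$resistance_established
    diag$sustained_decay[i] <- .sustained_decay(out$trajectory, window)
  }
  ok <- which(diag$feasible_dose & diag$sustained_decay &
                !vapply(diag$resistance, isTRUE, logical(1)))
  if (!length(ok))
    return(list(T_days = NA_real_, dose = NA_real_, outcome = NULL,
                D_MTD = D_MTD, diagnostics = diag))
  best <- ok[which.max(candidates_days[ok])]
  list(T_days = candidates_days[best], dose = diag$dose[best],
       outcome = outcomes[[best]], D_MTD = D_MTD, diagnostics = diag)
}

# Sustained decay: N(end of window) < N(treatment start) and negative
# log-slope over the final 30 days of the window.
.sustained_decay <- function(trajectory, window, tail_days = 30) {
  tt <- trajectory$times
  N <- trajectory$states[, "A"] + trajectory$states[, "B"]
  n_start <- N[which.min(abs(tt - window[1]))]
  n_end <- N[which.min(abs(tt - window[2]))]
  sel <- tt >= window[2] - tail_days * 24 & tt <= window[2]
  slope <- stats::coef(stats::lm(log(pmax(N[sel], .Machine$double.xmin)) ~
                                   tt[sel]))[2]
  isTRUE(n_end < n_start && slope < 0)
}

# Generous default bisection cap: enough drug to keep delta_A near d_A_max
# for most of a week.
.default_dose_cap <- function(params, pk) {
  100
}

#' Burden ratio of two therapy outcomes
#'
#' @param outcome_a,outcome_b `therapy_outcome`s over the same horizon and
#'   carrying capacity (typically model-informed vs periodic).
#' @param window Optional common window `c(w1, w2)` in hours over which the
#'   burdens are recomputed; default each outcome's stored burden.
#' @return `burden(a) / burden(b)`.
#' @export
compare_burden <- function(outcome_a, outcome_b, window = NULL) {
  K <- outcome_a$trajectory$params$growth$K
  ba <- if (is.null(window)) outcome_a$burden
        else burden(outcome_a$trajectory, K = K, window = window)
  bb <- if (is.null(window)) outcome_b$burden
        else burden(outcome_b$trajectory, K = K, window = window)
  if (bb == 0) stop("reference burden is zero")
  ba / bb
}
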