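#' Linear generator of the population model
#'
#' The 4x4 rate matrix governing `(A, B, N_AA, N_BB)` at a fixed drug
#' concentration under Malthusian growth (reproduction rates constant).
#' Its dominant eigenvalue is the Malthusian parameter of the (possibly
#' treated) population.
#'
#' @param params A [model_params()] (Malthusian-type growth assumed:
#'   the logistic factor and cooperation factor are frozen at 1 unless
#'   `f_B` is supplied).
#' @param concentration Fixed drug concentration (needs `pk` for `c_half`).
#' @param pk A [pk_params()], required when `concentration > 0`.
#' @param f_B Multiplier applied to the tolerant division rate (used by the
#'   cooperation-aware eigenproblem); default 1.
#' @param delta_A Optional direct override of the sensitive death rate
#'   (e.g. `d_A_max` for a lethal bath); overrides `concentration`.
#' @return 4x4 numeric matrix.
#' @export
linear_generator <- function(params, concentration = 0, pk = NULL, f_B = 1,
                             delta_A = NULL) {
  rA <- params$r_A
  rB <- params$r_B * f_B
  dB <- params$d_B
  if (is.null(delta_A)) {
    delta_A <- if (concentration > 0) {
      if (is.null(pk)) stop("concentration > 0 requires pk for c_half")
      treated_death_rate(params$d_A, params$d_A_max, concentration, pk$c_half)
    } else params$d_A
  }
  sA <- params$strategy_A; sB <- params$strategy_B
  m <- matrix(0, 4, 4,
              dimnames = list(.state_names[1:4], .state_names[1:4]))
  m["A", ] <- c(-(rA + delta_A), 2 * rB, 2 * rA, -2 * rB)
  m["B", ] <- c(2 * rA, -(rB + dB), -2 * rA, 2 * rB)
  m["N_AA", ] <- c(sA$sigma * sA$p_min,
                   sA$p_max * 2 * rB,
                   sA$p_max * 2 * rA - (rA + delta_A) - sA$sigma,
                   -sA$p_max * 2 * rB)
  m["N_BB", ] <- c(sB$p_max * 2 * rA,
                   sB$sigma * sB$p_min,
                   -sB$p_max * 2 * rA,
                   sB$p_max * 2 * rB - (rB + dB) - sB$sigma)
  m
}

#' Dominant eigenpair of a generator matrix
#'
#' Largest-real-part eigenvalue (real for these generators, which are
#' similar to positive operators of the underlying age-structured
#' semigroup) and its eigenvector, sign-fixed so the population components
#' are nonnegative.
#'
#' @param m Square matrix.
#' @return List with `value` (real scalar) and `vector`.
#' @export
dominant_eigen <- function(m) {
  e <- eigen(m)
  i <- order(-Re(e$values), -Mod(e$values))[1]
  val <- e$values[i]
  if (abs(Im(val)) > 1e-8 * max(1, abs(Re(val))))
    stop("dominant eigenvalue has a non-negligible imaginary part")
  v <- Re(e$vectors[, i])
  if (sum(v[1:2]) < 0) v <- -v
  list(value = Re(val), vector = v)
}

#' Malthusian parameter of the mixed population
#'
#' Long-run exponential growth rate lambda_P: the dominant eigenvalue of
#' the untreated linear generator.  For plastic populations lambda_P lies
#' strictly between the constituent rates `lambda_B` and `lambda_A`; with
#' no switching (both strategies `(1, 1, sigma)`) it equals
#' `max(lambda_A, lambda_B)`.
#'
#' @param params A [model_params()] (Malthusian growth, no cooperation).
#' @return Growth rate, per hour.
#' @export
malthusian_parameter <- function(params) {
  dominant_eigen(linear_generator(params))$value
}

#' Malthusian parameter with tolerant-cell cooperation
#'
#' Solves the nonlinear eigenproblem in which the tolerant division rate is
#' scaled by the cooperation factor evaluated at the population's own
#' stable composition: starting from theta_0, form the generator with
#' `f_n(theta_k)`, take the dominant eigenvector ratio `B/A` as
#' `theta_{k+1}`, and iterate to a fixed point.
#'
#' @param params A [model_params()] whose growth law has a Hill
#'   coefficient `n`.
#' @param theta0 Starting ratio.
#' @param tol Convergence tolerance on `|theta_{k+1} - theta_k|`.
#' @param max_iter Iteration cap.
#' @return List with `lambda` (per hour) and `theta` (equilibrium B/A).
#' @export
malthusian_parameter_allee <- function(params, theta0 = 0.1, tol = 1e-10,
                                       max_iter = 1e4) {
  n <- params$growth$n
  theta <- theta0
  for (k in seq_len(max_iter)) {
    f <- cooperation_factor(theta, n, params$r_A, params$r_B)
    ev <- dominant_eigen(linear_generator(params, f_B = f))
    v <- pmax(Re(ev$vector), 0)
    theta_new <- v[2] / v[1]
    if (abs(theta_new - theta) < tol)
      return(list(lambda = ev$value, theta = theta_new, iterations = k))
    theta <- 0.5 * theta + 0.5 * theta_new  # damped for robustness
  }
  stop(sprintf("cooperation eigenproblem did not converge (last theta %.6g)",
               theta))
}

#' Basic reproduction number
#'
#' Next-generation decomposition of the untreated generator `M = F + V`,
#' where `F` collects every birth term (the entries carrying the factor
#' `2 R_i`, including their `Pmax`-weighted images in the retention-moment
#' rows) and `V` the remaining transition/loss terms.  `R0` is the
#' spectral radius of `F (-V)^{-1}`; the sign relation
#' `sign(lambda_P) = sign(R0 - 1)` holds.
#'
#' @param params A [model_params()] (Malthusian growth).
#' @return Nonnegative scalar.
#' @export
basic_reproduction_number <- function(params) {
  rA <- params$r_A; rB <- params$r_B
  sA <- params$strategy_A; sB <- params$strategy_B
  f <- matrix(0, 4, 4)
  f[1, ] <- c(0, 2 * rB, 2 * rA, -2 * rB)
  f[2, ] <- c(2 * rA, 0, -2 * rA, 2 * rB)
  f[3, ] <- sA$p_max * f[1, ]
  f[4, ] <- sB$p_max * f[2, ]
  v <- linear_generator(params) - f
  if (abs(det(v)) < 1e-300) stop("loss matrix is singular; need positive rates")
  max(Mod(eigen(f %*% solve(-v), only.values = TRUE)$values))
}

#' Stable fraction of drug-sensitive cells
#'
#' The `A` share of the normalized dominant eigenvector of the untreated
#' generator: the sensitive proportion the population settles to during
#' sustained exponential (Malthusian) growth.
#'
#' @param params A [model_params()].
#' @return Fraction in `[0, 1]`.
#' @export
sensitive_fraction_stable <- function(params) {
  v <- pmax(dominant_eigen(linear_generator(params))$vector, 0)
  v[1] / (v[1] + v[2])
}

#' Sensitive fraction under limited resources
#'
#' Simulates the logistic model to a fixed horizon and reports
#' `A / (A + B)` there; contrasts with the strictly decreasing
#' Malthusian-stage behaviour by plateauing once resources bind.
#'
#' @param params A [model_params()] with a logistic growth law.
#' @param horizon_days Simulation horizon, days (default 500).
#' @param n0 Initial population, cells.
#' @return Fraction in `[0, 1]`.
#' @export
sensitive_fraction_limited <- function(params, horizon_days = 500, n0 = 1000) {
  if (!params$growth$logistic) stop("requires a logistic growth law")
  tr <- simulate_population(params, t_span = c(0, horizon_days * 24),
                            n0 = n0, dt_out = 24)
  st <- tr$states[nrow(tr$states), ]
  unname(st["A"] / (st["A"] + st["B"]))
}

#' Per-period growth multiplier under periodic dosing (Floquet)
#'
#' Integrates the fundamental matrix of the 4x4 time-periodic linear system
#' obtained by evaluating the sensitive death rate along the periodic
#' steady-state drug concentration, over one dosing period.  The dominant
#' eigenvalue modulus rho of the monodromy matrix is the per-period growth
#' factor: the tumour decays in the periodic treated environment iff
#' `rho < 1` (the operational treated-R0 criterion).
#'
#' @param params A [model_params()] (Malthusian growth).
#' @param pk A [pk_params()].
#' @param dose Per-administration amount (units of `c_half * vol`).
#' @param period Dosing period, hours.
#' @param rtol Solver tolerance for the fundamental system.
#' @return Floquet multiplier rho (>= 0).
#' @export
treated_period_multiplier <- function(params, pk, dose, period, rtol = 1e-10) {
  if (dose == 0) return(exp(malthusian_parameter(params) * period))
  m0 <- linear_generator(params)           # untreated baseline
  gap <- params$d_A_max - params$d_A
  rhs <- function(t, y, p) {
    cc <- periodic_steady_concentration(pk, dose, period, t %% period)
    extra <- gap * cc / (cc + pk$c_half)   # delta_A(t) - d_A
    m <- m0
    m[1, 1] <- m[1, 1] - extra
    m[3, 3] <- m[3, 3] - extra
    list(as.vector(m %*% matrix(y, 4, 4)))
  }
  tt <- sort(unique(c(0, min(pk$t_admin, period), period)))
  sol <- deSolve::lsoda(as.vector(diag(4)), tt, rhs, parms = NULL,
                        rtol = rtol, atol = rtol)
  phi <- matrix(sol[nrow(sol), -1], 4, 4)
  max(Mod(eigen(phi, only.values = TRUE)$values))
}

#' Per-period growth multiplier of the drug-sensitive compartment
#'
#' The classical dose threshold treats the sensitive population as
#' approximately closed: its log-size changes per period by
#' `lambda_A * T - (d_A_max - d_A) * int_0^T C(tau) / (C(tau) + c_half) dtau`
#' along the periodic steady-state concentration.  The returned multiplier
#' is the exponential of that quantity; the sensitive compartment decays on
#' average iff it is `< 1`.  This is the operational counterpart of the
#' closed-form minimal dose `Dose* = (lambda_A - lambda_A*) / alpha_T`.
#'
#' @inheritParams treated_period_multiplier
#' @return Per-period multiplier (>= 0).
#' @export
sensitive_period_multiplier <- function(params, pk, dose, period) {
  lam_A <- params$r_A - params$d_A
  if (dose == 0) return(exp(lam_A * period))
  kill <- stats::integrate(function(tau) {
    cc <- periodic_steady_concentration(pk, dose, period, tau)
    cc / (cc + pk$c_half)
  }, 0, period, rel.tol = 1e-10, subdivisions = 500L)$value
  exp(lam_A * period - (params$d_A_max - params$d_A) * kill)
}

#' Minimal per-period dose achieving decay
#'
#' Bisects a per-period growth multiplier in the dose to find the smallest
#' dose at the decay threshold (`rho(dose) = 1`), capped at `cap`.  With
#' `criterion = "population"` the multiplier is the full 4x4 Floquet
#' multiplier [treated_period_multiplier()] (mixed population decays);
#' with `criterion = "sensitive"` (used by the model-informed scheduler)
#' it is [sensitive_period_multiplier()], the dose that forces the
#' drug-sensitive compartment itself to decay -- the biomarker gate takes
#' care of the tolerant compartment separately.
#'
#' @param params A [model_params()] with `lambda_A > 0 > lambda_A_star`.
#' @param pk A [pk_params()].
#' @param period Dosing period, hours.
#' @param cap Largest admissible dose (e.g. an MTD-derived per-period cap).
#' @param criterion `"population"` or `"sensitive"`.
#' @param rho_target Per-period multiplier targeted by the bisection.  The
#'   default 1 is the exact decay threshold; schedulers may dose to a
#'   stricter target (< 1) because the periodic-decay condition is only a
#'   sufficient condition at the linearized level and leaves no margin for
#'   skipped administrations or cooperation-driven fitness gains.
#' @param tol Relative bisection tolerance on the dose.
#' @return List with `dose`, `rho` at the returned dose, and logical
#'   flags `feasible` and `capped`.
#' @export
min_effective_dose <- function(params, pk, period, cap,
                               criterion = c("population", "sensitive"),
                               rho_target = 1, tol = 1e-6) {
  criterion <- match.arg(criterion)
  mult <- switch(criterion,
                 population = treated_period_multiplier,
                 sensitive = sensitive_period_multiplier)
  lam <- lambda_rates(params)
  rho0 <- mult(params, pk, 0, period)
  if (rho0 <= rho_target)
    return(list(dose = 0, rho = rho0, feasible = TRUE, capped = FALSE))
  if (params$d_A_max == params$d_A)
    return(list(dose = NA_real_, rho = NA_real_,
                feasible = FALSE, capped = FALSE))
  rho_cap <- mult(params, pk, cap, period)
  if (rho_cap >= rho_target)
    return(list(dose = cap, rho = rho_cap, feasible = FALSE, capped = TRUE))
  lo <- 0; hi <- cap
  while ((hi - lo) > tol * max(hi, 1e-12)) {
    mid <- (lo + hi) / 2
    if (mult(params, pk, mid, period) < rho_target) hi <- mid
    else lo <- mid
  }
  list(dose = hi, rho = mult(params, pk, hi, period),
       feasible = TRUE, capped = FALSE)
}

#' Scalar fitness report
#'
#' Convenience summary of the analytic quantities used by the schedulers.
#'
#' @param params A [model_params()].
#' @param pk Optional [pk_params()] for the per-period dose table.
#' @param periods_days Periods (days) for the minimal-dose table.
#' @param cap Dose cap passed to [min_effective_dose()].
#' @return A list; written as JSON by [write_fitness_report()].
#' @export
fitness_report <- function(params, pk = NULL, periods_days = NULL, cap = 50) {
  lam <- lambda_rates(params)
  rep <- list(lambda_A = unname(lam["lambda_A"]),
              lambda_B = unname(lam["lambda_B"]),
              lambda_A_star = unname(lam["lambda_A_star"]),
              lambda_P = malthusian_parameter(params),
              R0 = basic_reproduction_number(params),
              sensitive_fraction = sensitive_fraction_stable(params))
  rep$theta_star <- tryCatch(theta_star(params), error = function(e) NA_real_)
  if (!is.null(pk) && !is.null(periods_days)) {
    rep$min_dose <- lapply(periods_days, function(Td) {
      md <- min_effective_dose(params, pk, Td * 24, cap = cap)
      list(period_days = Td, dose = md$dose, feasible = md$feasible)
    })
  }
  rep
}

#' @rdname fitness_report
#' @param report A list from `fitness_report`.
#' @param path Output JSON file.
#' @export
write_fitness_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
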