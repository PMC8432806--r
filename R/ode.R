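# State ordering used throughout: (A, B, N_AA, N_BB, C).
.state_names <- c("A", "B", "N_AA", "N_BB", "C")

# Reproduction rates for both phenotypes at a population state, vector of 2.
.repro_rates <- function(abar, bbar, params) {
  g <- params$growth
  rA <- params$r_A
  rB <- params$r_B
  if (g$logistic) {
    fac <- max(0, 1 - (abar + bbar) / g$K)
    rA <- rA * fac
    rB <- rB * fac
  }
  if (g$allee) {
    theta <- if (abar <= 0) Inf else bbar / abar
    rB <- rB * cooperation_factor(theta, g$n, params$r_A, params$r_B)
  }
  c(rA, rB)
}

#' Right-hand side of the five-dimensional population model
#'
#' The age-structured transport model with age-dependent phenotype
#' inheritance reduces exactly to five ODEs for the sensitive and tolerant
#' totals (`A`, `B`), the phenotype-retention moments
#' `N_AA = int beta_AA(a) A(t,a) da` and `N_BB` (the pools of cells whose
#' offspring keep the parental phenotype), and the drug concentration `C`:
#'
#'   dA    = -(R_A + delta_A) A + 2 R_A N_AA + 2 R_B (B - N_BB)
#'   dB    = -(R_B + d_B)  B + 2 R_A (A - N_AA) + 2 R_B N_BB
#'   dN_AA = Pmax_AA [2 R_A N_AA + 2 R_B (B - N_BB)] - (R_A + delta_A) N_AA
#'           + sigma_A (Pmin_AA A - N_AA)
#'   dN_BB = Pmax_BB [2 R_A (A - N_AA) + 2 R_B N_BB] - (R_B + d_B) N_BB
#'           - sigma_B N_BB + sigma_B Pmin_BB B
#'   dC    = I(t) - k_elim C
#'
#' with `delta_A = treated_death_rate(d_A, d_A_max, C, c_half)`.
#'
#' @param state Numeric vector `(A, B, N_AA, N_BB, C)`.
#' @param t Time, hours (enters only through `rate_in` and `lethal`).
#' @param params A [model_params()].
#' @param pk A [pk_params()] or `NULL` (no drug effect).
#' @param rate_in Current infusion rate `I(t)` (constant within a dosing
#'   segment), per hour.
#' @param lethal If `TRUE`, overrides the PD law with `delta_A = d_A_max`
#'   (constant lethal drug bath, as in the treated growth assays).
#' @return Derivative vector of length 5.
#' @export
population_rhs <- function(state, t, params, pk = NULL, rate_in = 0,
                           lethal = FALSE) {
  A <- state[1]; B <- state[2]; NAA <- state[3]; NBB <- state[4]; C <- state[5]
  R <- .repro_rates(A, B, params)
  RA <- R[1]; RB <- R[2]
  deltaA <- if (lethal) params$d_A_max
            else if (is.null(pk)) params$d_A
            else treated_death_rate(params$d_A, params$d_A_max, max(C, 0),
                                    pk$c_half)
  sA <- params$strategy_A; sB <- params$strategy_B
  birthsA <- 2 * RA * NAA + 2 * RB * (B - NBB)
  birthsB <- 2 * RA * (A - NAA) + 2 * RB * NBB
  c(-(RA + deltaA) * A + birthsA,
    -(RB + params$d_B) * B + birthsB,
    sA$p_max * birthsA - (RA + deltaA) * NAA + sA$sigma * (sA$p_min * A - NAA),
    sB$p_max * birthsB - (RB + params$d_B) * NBB -
      sB$sigma * NBB + sB$sigma * sB$p_min * B,
    rate_in - (if (is.null(pk)) 0 else pk$k_elim) * C)
}

#' Initial population state
#'
#' `eigen` mode (the default) places the population on the dominant
#' eigenvector of the untreated linear generator, i.e. a tumour in
#' exponential growth with its stable phenotype composition and retention
#' moments; `explicit` mode takes user-specified `(abar, bbar)` and sets the
#' retention moments at the midpoint of their admissible band
#' `[p_min * pop, p_max * pop]`.
#'
#' @param params A [model_params()].
#' @param n0 Total initial population, cells (> 0).
#' @param mode `"eigen"` or `"explicit"`.
#' @param abar,bbar Explicit sensitive/tolerant splits (explicit mode only;
#'   must sum to `n0`).
#' @return Named state vector `(A, B, N_AA, N_BB, C)` with `C = 0`.
#' @export
initial_state <- function(params, n0, mode = c("eigen", "explicit"),
                          abar = NULL, bbar = NULL) {
  mode <- match.arg(mode)
  stopifnot(n0 > 0)
  if (mode == "eigen") {
    ev <- dominant_eigen(linear_generator(params))
    v <- ev$vector
    if (any(v[1:2] < -1e-10 * max(abs(v))))
      stop("dominant eigenvector has negative population components")
    v <- pmax(v, 0)
    st <- c(n0 * v[1:4] / (v[1] + v[2]), 0)
  } else {
    if (is.null(abar) || is.null(bbar)) stop("explicit mode needs abar, bbar")
    if (abs(abar + bbar - n0) > 1e-8 * n0) stop("abar + bbar must equal n0")
    sA <- params$strategy_A; sB <- params$strategy_B
    st <- c(abar, bbar,
            (sA$p_min + sA$p_max) / 2 * abar,
            (sB$p_min + sB$p_max) / 2 * bbar, 0)
  }
  stats::setNames(st, .state_names)
}

#' Simulate the population model
#'
#' Integrates [population_rhs()] with `deSolve::lsoda`, restarting the
#' integration at every dose administration start and end so that the
#' discontinuous infusion rate never crosses a solver step.  Output is
#' sampled on a uniform grid plus all dosing breakpoints.
#'
#' @param params A [model_params()].
#' @param pk A [pk_params()] or `NULL`.
#' @param schedule A [dose_schedule()] or `NULL` (untreated).
#' @param t_span `c(t0, t1)`, hours.
#' @param n0 Total initial population (eigen initial state); ignored when
#'   `init` is given.
#' @param init Full initial state vector `(A, B, N_AA, N_BB, C)`.
#' @param dt_out Output grid spacing, hours.
#' @param lethal_from If non-`NULL`, time (hours) from which the sensitive
#'   death rate steps to `d_A_max` regardless of `C` (constant lethal drug
#'   bath used in the treated growth assays).
#' @param rtol,atol Solver tolerances; `atol` defaults to `1e-8` times the
#'   initial population.
#' @return An object of class `pheno_trajectory`: list with `times`,
#'   `states` (matrix with columns `A, B, N_AA, N_BB, C`), the schedule,
#'   and the parameter objects used.
#' @export
simulate_population <- function(params, pk = NULL, schedule = NULL,
                                t_span, n0 = NULL, init = NULL, dt_out = 1,
                                lethal_from = NULL,
                                rtol = 1e-8, atol = NULL) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(init)) {
    if (is.null(n0)) stop("supply n0 or init")
    init <- initial_state(params, n0)
  }
  if (is.null(atol)) atol <- 1e-8 * max(sum(init[1:2]), 1)
  brk <- numeric(0)
  if (!is.null(schedule) && length(schedule$times)) {
    if (is.null(pk)) stop("a dose schedule requires pk parameters")
    brk <- c(schedule$times, schedule$times + schedule$t_admin)
  }
  if (!is.null(lethal_from)) brk <- c(brk, lethal_from)
  brk <- sort(unique(brk[brk > t_span[1] & brk < t_span[2]]))
  grid <- sort(unique(c(seq(t_span[1], t_span[2], by = dt_out), t_span[2], brk)))
  seg_edges <- c(t_span[1], brk, t_span[2])

  out_t <- grid[1]
  out_s <- matrix(init, nrow = 1)
  y <- as.numeric(init)
  for (k in seq_len(length(seg_edges) - 1L)) {
    a <- seg_edges[k]; b <- seg_edges[k + 1L]
    tt <- grid[grid >= a & grid <= b]
    if (tt[1] > a) tt <- c(a, tt)
    if (tt[length(tt)] < b) tt <- c(tt, b)
    mid <- (a + b) / 2
    rate_in <- if (length(brk) && !is.null(schedule))
      infusion_rate(schedule, pk, mid) else 0
    lethal <- !is.null(lethal_from) && mid >= lethal_from
    sol <- deSolve::lsoda(
      y, tt,
      function(t, y, p) list(population_rhs(y, t, params, pk, rate_in, lethal)),
      parms = NULL, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failure at t = %.3f h; last state: %s",
                   sol[nrow(sol), 1],
                   paste(signif(sol[nrow(sol), -1], 6), collapse = ", ")))
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] > out_t[length(out_t)] & sol[, 1] %in% grid
    out_t <- c(out_t, sol[keep, 1])
    out_s <- rbind(out_s, sol[keep, -1, drop = FALSE])
  }
  colnames(out_s) <- .state_names
  structure(list(times = out_t, states = out_s, schedule = schedule,
                 params = params, pk = pk, lethal_from = lethal_from),
            class = "pheno_trajectory")
}

#' @export
print.pheno_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("population trajectory: %d points over [%g, %g] h\n",
              n, x$times[1], x$times[n]))
  fin <- x$states[n, ]
  cat(sprintf("  final: A = %.4g, B = %.4g, N = %.4g, C = %.4g\n",
              fin["A"], fin["B"], fin["A"] + fin["B"], fin["C"]))
  invisible(x)
}

#' @export
as.data.frame.pheno_trajectory <- function(x, ...) {
  df <- data.frame(t_hours = x$times, x$states, check.names = FALSE)
  df$N_total <- df$A + df$B
  df$theta <- ifelse(df$A > 0, df$B / df$A, Inf)
  df
}

#' @export
plot.pheno_trajectory <- function(x, which = c("population", "theta"), ...) {
  which <- match.arg(which)
  df <- as.data.frame(x)
  days <- df$t_hours / 24
  if (which == "population") {
    graphics::matplot(days, cbind(df$N_total, df$A, df$B), type = "l",
                      lty = c(1, 2, 3), col = c("black", "firebrick", "navy"),
                      xlab = "time (days)", ylab = "cells", log = "y", ...)
    graphics::legend("topleft", c("total", "sensitive", "tolerant"),
                     lty = c(1, 2, 3), col = c("black", "firebrick", "navy"),
                     bty = "n")
  } else {
    graphics::plot(days, df$theta, type = "l", xlab = "time (days)",
                   ylab = expression(theta == B / A), ...)
  }
  invisible(x)
}

#' Write a trajectory as delimited text
#'
#' CSV columns: `t_hours, A, B, N_AA, N_BB, C, theta, N_total`.
#'
#' @param trajectory A `pheno_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df <- df[, c("t_hours", "A", "B", "N_AA", "N_BB", "C", "theta", "N_total")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Time-averaged tumour burden
#'
#' `Burden = (1 / (w2 - w1)) * int_{w1}^{w2} N(tau) / K dtau`, the average
#' total population as a fraction of carrying capacity over a window,
#' evaluated by trapezoidal quadrature on the trajectory's output grid.
#'
#' @param trajectory A `pheno_trajectory`.
#' @param K Carrying capacity; defaults to the trajectory's growth-law `K`.
#' @param window `c(w1, w2)` in hours; defaults to the full trajectory.
#' @return Dimensionless burden, >= 0.
#' @export
burden <- function(trajectory, K = NULL, window = NULL) {
  if (is.null(K)) {
    K <- trajectory$params$growth$K
    if (!is.finite(K)) stop("no carrying capacity available; supply K")
  }
  tt <- trajectory$times
  N <- trajectory$states[, "A"] + trajectory$states[, "B"]
  if (is.null(window)) window <- range(tt)
  if (window[1] < tt[1] - 1e-9 || window[2] > tt[length(tt)] + 1e-9)
    stop("window outside trajectory")
  f <- stats::approxfun(tt, N)
  sub <- tt[tt > window[1] & tt < window[2]]
  xs <- c(window[1], sub, window[2])
  ys <- f(xs) / K
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2) /
    (window[2] - window[1])
}
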