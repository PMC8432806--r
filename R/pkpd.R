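#' One-compartment pharmacokinetic parameters
#'
#' The drug is infused intravenously over `t_admin` hours and cleared
#' linearly with elimination rate `k_elim = log(2) / t_half`.  Only the
#' ratio of concentration to the half-effect concentration `c_half` enters
#' the pharmacodynamics, so doses are conveniently expressed in units of
#' `c_half * vol`.
#'
#' @param t_half Elimination half-life, hours.
#' @param vol Distribution volume (arbitrary volume unit).
#' @param c_half Half-effect concentration (same unit as concentration).
#' @param t_admin Infusion duration per administration, hours.
#' @return An object of class `pk_params` with derived `k_elim`.
#' @export
pk_params <- function(t_half = 6, vol = 1, c_half = 1, t_admin = 1) {
  vals <- c(t_half, vol, c_half, t_admin)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all PK parameters must be strictly positive")
  structure(list(t_half = t_half, vol = vol, c_half = c_half,
                 t_admin = t_admin, k_elim = log(2) / t_half),
            class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "one-compartment PK: t_1/2 = %g h (k_elim = %.4g /h), vol = %g, C_1/2 = %g, T_admin = %g h\n",
    x$t_half, x$k_elim, x$vol, x$c_half, x$t_admin))
  invisible(x)
}

#' Dosing schedule
#'
#' @param times Administration start times, hours, strictly increasing.
#' @param doses Per-administration amounts (units of `c_half * vol`);
#'   recycled to the length of `times`.
#' @param t_admin Infusion duration, hours; successive administrations must
#'   not overlap.
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(times, doses, t_admin = 1) {
  if (length(times) == 0L)
    return(structure(list(times = numeric(0), doses = numeric(0),
                          t_admin = t_admin), class = "dose_schedule"))
  if (is.unsorted(times, strictly = TRUE))
    stop("administration times must be strictly increasing")
  doses <- rep_len(doses, length(times))
  if (any(doses < 0)) stop("doses must be nonnegative")
  if (length(times) > 1L && any(diff(times) < t_admin - 1e-9))
    stop("administrations overlap: need times[i+1] >= times[i] + t_admin")
  structure(list(times = as.numeric(times), doses = as.numeric(doses),
                 t_admin = t_admin), class = "dose_schedule")
}

#' Periodic dosing schedule helper
#'
#' @param start,end Window of administration, hours (doses at
#'   `start, start + period, ...` up to `end`).
#' @param period Dosing interval, hours.
#' @param dose Per-administration amount (units of `c_half * vol`).
#' @param t_admin Infusion duration, hours.
#' @return A [dose_schedule()].
#' @export
periodic_schedule <- function(start, end, period, dose, t_admin = 1) {
  dose_schedule(seq(start, end, by = period), dose, t_admin = t_admin)
}

#' Drug infusion rate I(t)
#'
#' `Dose / (vol * t_admin)` while an infusion window `(t_i, t_i + t_admin)`
#' is open, zero otherwise.
#'
#' @param schedule A [dose_schedule()].
#' @param pk A [pk_params()].
#' @param t Time(s), hours.
#' @return Concentration input rate(s), per hour.
#' @export
infusion_rate <- function(schedule, pk, t) {
  out <- numeric(length(t))
  for (i in seq_along(schedule$times)) {
    on <- t > schedule$times[i] & t <= schedule$times[i] + schedule$t_admin
    out[on] <- out[on] + schedule$doses[i] / (pk$vol * schedule$t_admin)
  }
  out
}

# Exact one-segment propagation of dC/dt = rate_in - k*C.
.pk_segment <- function(c0, rate_in, k, dt) {
  c0 * exp(-k * dt) + (rate_in / k) * (1 - exp(-k * dt))
}

#' Closed-form drug concentration trajectory
#'
#' Solves `dC/dt = I(t) - k_elim C` exactly by piecewise exponential
#' propagation within and between infusion windows (no numerical
#' integration, so dose events need no solver event handling).
#'
#' @param pk A [pk_params()].
#' @param schedule A [dose_schedule()].
#' @param t_grid Increasing times, hours.
#' @param c0 Initial concentration at `t_grid[1]` (default 0).
#' @return Concentrations at `t_grid`.
#' @export
concentration <- function(pk, schedule, t_grid, c0 = 0) {
  if (is.unsorted(t_grid)) stop("t_grid must be increasing")
  brk <- sort(unique(c(schedule$times, schedule$times + schedule$t_admin)))
  pts <- sort(unique(c(t_grid, brk[brk > t_grid[1] & brk < t_grid[length(t_grid)]])))
  cc <- numeric(length(pts))
  cc[1] <- c0
  if (length(pts) > 1) {
    for (i in 2:length(pts)) {
      mid <- (pts[i - 1] + pts[i]) / 2
      cc[i] <- .pk_segment(cc[i - 1], infusion_rate(schedule, pk, mid),
                           pk$k_elim, pts[i] - pts[i - 1])
    }
  }
  cc[match(t_grid, pts)]
}

#' Periodic steady-state concentration under repeated equal dosing
#'
#' Concentration profile of the T-periodic limit of an infinite train of
#' identical doses given every `period` hours (geometric-series
#' superposition of the piecewise closed form; reduces to
#' `(Dose/vol) exp(-k tau) / (1 - exp(-k T))` as `t_admin -> 0`).
#'
#' @param pk A [pk_params()].
#' @param dose Per-administration amount (units of `c_half * vol`).
#' @param period Dosing period T, hours; must be >= `pk$t_admin`.
#' @param phase Phase(s) tau within the period, hours, in `[0, period)`;
#'   the infusion starts at phase 0.
#' @return Steady-state concentration(s) at the given phases.
#' @export
periodic_steady_concentration <- function(pk, dose, period, phase) {
  if (period <= 0) stop("period must be positive")
  if (period < pk$t_admin) stop("period shorter than infusion time")
  if (any(phase < 0 | phase >= period)) stop("phase must lie in [0, period)")
  k <- pk$k_elim
  ta <- pk$t_admin
  rate <- dose / (pk$vol * ta)
  # trough just before an infusion starts: C0 = C(period) under one dose/period
  peak_gain <- (rate / k) * (1 - exp(-k * ta))      # added at end of infusion
  c0 <- peak_gain * exp(-k * (period - ta)) / (1 - exp(-k * period))
  within <- phase <= ta
  out <- numeric(length(phase))
  out[within] <- .pk_segment(c0, rate, k, phase[within])
  c_end <- .pk_segment(c0, rate, k, ta)
  out[!within] <- c_end * exp(-k * (phase[!within] - ta))
  out
}

#' Drug-dependent sensitive death rate
#'
#' Saturating (Emax) pharmacodynamics:
#' `d_A + (d_A_max - d_A) * c / (c + c_half)`, bounded in
#' `[d_A, d_A_max]`.  Only the ratio `c / c_half` matters.
#'
#' @param d_A Baseline sensitive death rate, per hour.
#' @param d_A_max Maximal sensitive death rate, per hour.
#' @param c Drug concentration(s), >= 0.
#' @param c_half Half-effect concentration.
#' @return Death rate(s), per hour.
#' @export
treated_death_rate <- function(d_A, d_A_max, c, c_half) {
  if (any(c < 0)) stop("concentration must be nonnegative")
  d_A + (d_A_max - d_A) * c / (c + c_half)
}
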