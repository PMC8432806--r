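#' Frequency-dependent cooperation factor of drug-tolerant cells
#'
#' Tolerant cells gain fitness as they become more common relative to the
#' sensitive population (an Allee-type effect mediated by cooperation).
#' With theta = Bbar/Abar the factor is the Hill-type interpolation
#'
#'   f_n(theta) = (r_B + r_A * theta^n) / (r_B * (1 + theta^n)),
#'
#' so the effective tolerant division rate r_B * f_n(theta) rises from r_B
#' when tolerant cells are rare to r_A when they dominate.  This is the
#' unique Hill-in-theta interpolation for which the two analytic thresholds
#' [theta_epsilon_star()] and [theta_star()] hold identically:
#' r_B f_n(theta) < eps * r_A iff theta < theta_eps_star, and (with
#' d_A = d_B) r_B f_n(theta) - d_B < 0 iff theta < theta_star.
#'
#' @param theta Ratio of tolerant to sensitive cells, `Bbar/Abar`, >= 0.
#'   `Inf` is allowed and returns the saturated value `r_A / r_B`.
#' @param n Hill coefficient, >= 1.
#' @param r_A,r_B Division rates, per hour, with `0 < r_B <= r_A`.
#' @return Multiplier(s) in `[1, r_A/r_B]`.
#' @export
cooperation_factor <- function(theta, n, r_A, r_B) {
  if (any(theta < 0, na.rm = TRUE)) stop("theta must be nonnegative")
  stopifnot(n >= 1, r_B > 0, r_B <= r_A)
  h <- theta^n
  out <- ifelse(is.infinite(h), r_A / r_B, (r_B + r_A * h) / (r_B * (1 + h)))
  out
}

#' Phenotype-specific reproduction rate under the chosen growth law
#'
#' Malthusian: constant `r_i`.  Logistic: `r_i * max(0, 1 - N/K)` (clamped at
#' zero so overshoot past carrying capacity never yields a negative rate).
#' The `allee` modes additionally multiply the tolerant (B) rate by
#' [cooperation_factor()] evaluated at `theta = bbar/abar`; when `abar = 0`
#' theta is taken as `+Inf` and the saturated rate is returned, so
#' trajectories that drive the sensitive population extinct remain
#' integrable.
#'
#' @param phenotype `"A"` or `"B"`.
#' @param abar,bbar Current sensitive and tolerant population sizes, cells.
#' @param params A [model_params()] object.
#' @return Nonnegative reproduction rate, per hour.
#' @export
reproduction_rate <- function(phenotype = c("A", "B"), abar, bbar, params) {
  phenotype <- match.arg(phenotype)
  if (abar < 0 || bbar < 0) stop("populations must be nonnegative")
  g <- params$growth
  base <- if (phenotype == "A") params$r_A else params$r_B
  rate <- base
  if (g$logistic) rate <- base * max(0, 1 - (abar + bbar) / g$K)
  if (g$allee && phenotype == "B") {
    theta <- if (abar == 0) Inf else bbar / abar
    rate <- rate * cooperation_factor(theta, g$n, params$r_A, params$r_B)
  }
  rate
}

#' Self-sustainability threshold ratio theta*
#'
#' The cooperation-adjusted tolerant growth rate is
#' `lambda_B(theta) = r_B f_n(theta) - d_B`.  When the tolerant population
#' decays on its own (`lambda_B < 0`) while the sensitive one grows
#' (`lambda_A > 0`), there is a critical tolerant-to-sensitive ratio
#'
#'   theta* = (-lambda_B / lambda_A)^(1/n)
#'
#' below which the tolerant population cannot sustain itself through
#' cooperation (exactly so under the fitted convention `d_A = d_B`).
#' Keeping `theta(t) < theta*` during therapy avoids competitive release.
#'
#' @param params A [model_params()] object with `lambda_B < 0 < lambda_A`.
#' @param n Hill coefficient; defaults to the growth law's `n`.
#' @return The threshold ratio, a positive scalar.
#' @export
theta_star <- function(params, n = params$growth$n) {
  lam <- lambda_rates(params)
  if (!(lam["lambda_B"] < 0 && lam["lambda_A"] > 0))
    stop("theta* requires lambda_B < 0 < lambda_A")
  unname((-lam["lambda_B"] / lam["lambda_A"])^(1 / n))
}

#' Cooperation-limiting threshold ratio
#'
#' The largest tolerant-to-sensitive ratio for which the cooperation-boosted
#' tolerant division rate stays below a fraction `epsilon` of the sensitive
#' rate: `r_B f_n(theta) < epsilon * r_A` iff `theta` is below
#'
#'   theta_eps* = ((epsilon r_A - r_B) / (r_A (1 - epsilon)))^(1/n).
#'
#' @param params A [model_params()] object.
#' @param epsilon Permissible fitness fraction, in `(r_B/r_A, 1)`.
#' @param n Hill coefficient; defaults to the growth law's `n`.
#' @return The threshold ratio, a positive scalar.
#' @export
theta_epsilon_star <- function(params, epsilon, n = params$growth$n) {
  lo <- params$r_B / params$r_A
  if (!(epsilon > lo && epsilon < 1))
    stop("epsilon must lie in (r_B/r_A, 1)")
  ((epsilon * params$r_A - params$r_B) /
     (params$r_A * (1 - epsilon)))^(1 / n)
}
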