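test_that("Malthusian parameter obeys the bounds and no-switching rule", {
  set.seed(41)
  for (i in 1:100) {
    p <- draw_params()
    lam <- lambda_rates(p)
    lamP <- malthusian_parameter(p)
    expect_true(lamP >= min(lam[1:2]) - 1e-10 &&
                  lamP <= max(lam[1:2]) + 1e-10)
    # no switching: maximum of the constituent rates
    pn <- model_params(p$r_A, p$r_B, p$d_A, p$d_B, p$d_A_max,
                       strategy_A = switching_strategy(1, 1, 0.01),
                       strategy_B = switching_strategy(1, 1, 0.01),
                       growth = p$growth)
    expect_equal(malthusian_parameter(pn), max(lam[1:2]), tolerance = 1e-10)
  }
  # identical phenotypes: symmetry pins lambda_P at lambda_A
  ps <- model_params(0.04, 0.04, 0.01, 0.01,
                     strategy_A = switching_strategy(0.7, 0.9, 0.02),
                     strategy_B = switching_strategy(0.7, 0.9, 0.02))
  expect_equal(malthusian_parameter(ps), 0.03, tolerance = 1e-10)
})

test_that("plastic populations sit strictly between the constituent rates", {
  p <- model_params(0.05, 0.02, 0.01, 0.015,
                    strategy_A = switching_strategy(0.9, 0.95, 0.01),
                    strategy_B = switching_strategy(0, 0.9, 0.01))
  lamP <- malthusian_parameter(p)
  expect_gt(lamP, 0.005)
  expect_lt(lamP, 0.04)
})

test_that("R0 matches the scalar next-generation ratio without switching", {
  p <- model_params(0.05, 0.01, 0.02, 0.03,
                    strategy_A = switching_strategy(1, 1, 0.01),
                    strategy_B = switching_strategy(1, 1, 0.01))
  # fitter type is A: R0 = 2 r_A / (r_A + d_A)
  expect_equal(basic_reproduction_number(p), 2 * 0.05 / (0.05 + 0.02),
               tolerance = 1e-8)
  # boundary case lambda_A = 0 gives exactly R0 = 1
  p0 <- model_params(0.03, 0.01, 0.03, 0.03,
                     strategy_A = switching_strategy(1, 1, 0.01),
                     strategy_B = switching_strategy(1, 1, 0.01))
  expect_equal(basic_reproduction_number(p0), 1, tolerance = 1e-10)
})

test_that("sign of lambda_P equals sign of R0 - 1 across random draws", {
  set.seed(42)
  for (i in 1:300) {
    p <- draw_params()
    lamP <- malthusian_parameter(p)
    r0 <- basic_reproduction_number(p)
    if (abs(lamP) > 1e-12)
      expect_equal(sign(lamP), sign(r0 - 1))
  }
})

test_that("cooperation eigenproblem is self-consistent and matches simulation", {
  p <- model_params(0.05, 0.02, 0.03, 0.03, 0.05,
                    strategy_A = switching_strategy(0, 0.95, 0.01),
                    strategy_B = switching_strategy(0.5, 0.9, 0.01),
                    growth = growth_law("malthusian_allee", n = 2))
  fp <- malthusian_parameter_allee(p)
  # re-evaluating the generator at the fixed point reproduces it
  f <- cooperation_factor(fp$theta, 2, p$r_A, p$r_B)
  ev <- dominant_eigen(linear_generator(p, f_B = f))
  v <- pmax(ev$vector, 0)
  expect_equal(v[2] / v[1], fp$theta, tolerance = 1e-8)
  expect_equal(ev$value, fp$lambda, tolerance = 1e-10)
  # long-run simulated growth matches the nonlinear eigenvalue
  st <- initial_state(model_params(p$r_A, p$r_B, p$d_A, p$d_B, p$d_A_max,
                                   strategy_A = p$strategy_A,
                                   strategy_B = p$strategy_B), 1000)
  tr <- simulate_population(p, t_span = c(0, 3000), init = st, dt_out = 20)
  N <- rowSums(tr$states[, 1:2])
  sel <- tr$times > 1500
  slope <- unname(coef(lm(log(N[sel]) ~ tr$times[sel]))[2])
  expect_lt(abs(slope - fp$lambda), 1e-3)
  # large n with sub-threshold theta reduces to the plain eigenvalue
  p10 <- model_params(0.05, 0.02, 0.03, 0.03, 0.05,
                      strategy_A = p$strategy_A, strategy_B = p$strategy_B,
                      growth = growth_law("malthusian_allee", n = 50))
  fp10 <- malthusian_parameter_allee(p10)
  if (fp10$theta < 0.9)
    expect_equal(fp10$lambda,
                 malthusian_parameter(
                   model_params(p$r_A, p$r_B, p$d_A, p$d_B, p$d_A_max,
                                strategy_A = p$strategy_A,
                                strategy_B = p$strategy_B)),
                 tolerance = 1e-4)
})

test_that("stable sensitive fraction behaves under symmetry and decline", {
  ps <- model_params(0.04, 0.04, 0.01, 0.01,
                     strategy_A = switching_strategy(0.7, 0.9, 0.02),
                     strategy_B = switching_strategy(0.7, 0.9, 0.02))
  expect_equal(sensitive_fraction_stable(ps), 0.5, tolerance = 1e-10)
  pn <- model_params(0.05, 0.01, 0.005, 0.005,
                     strategy_A = switching_strategy(1, 1, 0.01),
                     strategy_B = switching_strategy(1, 1, 0.01))
  expect_equal(sensitive_fraction_stable(pn), 1, tolerance = 1e-8)
  # strictly decreasing in d_A during exponential growth
  fr <- vapply(seq(0.002, 0.03, length.out = 8), function(dA)
    sensitive_fraction_stable(
      model_params(0.04, 0.02, dA, 0.01,
                   strategy_A = switching_strategy(0.9, 0.95, 0.01),
                   strategy_B = switching_strategy(0.3, 0.9, 0.01))),
    numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("resource limitation plateaus the sensitive fraction", {
  mk <- function(dA) model_params(0.04, 0.02, dA, 0.01,
    strategy_A = switching_strategy(0.9, 0.95, 0.01),
    strategy_B = switching_strategy(0, 0.37, 0.01),
    growth = growth_law("logistic", K = 1e5))
  dAs <- c(0.02, 0.03, 0.0375)
  lim <- vapply(dAs, function(dA)
    sensitive_fraction_limited(mk(dA), horizon_days = 500), numeric(1))
  mal <- vapply(dAs, function(dA) sensitive_fraction_stable(mk(dA)),
                numeric(1))
  # at high sensitive death the limited-resource fraction flattens out
  # while the exponential-stage fraction keeps falling
  expect_lt(abs(lim[3] - lim[2]), abs(mal[3] - mal[2]))
  expect_lt(abs(lim[3] - lim[2]), abs(lim[2] - lim[1]))
})

test_that("Floquet multiplier reduces to exp(lambda_P T) without dosing", {
  p <- model_params(0.05, 0.02, 0.01, 0.015,
                    strategy_A = switching_strategy(0.9, 0.95, 0.01),
                    strategy_B = switching_strategy(0.3, 0.9, 0.01))
  Tper <- 72
  expect_equal(treated_period_multiplier(p, pk_params(), 0, Tper),
               exp(malthusian_parameter(p) * Tper), tolerance = 1e-10)
  # saturating drug approaches the fully-treated autonomous limit
  pt <- model_params(0.05, 0.02, 0.01, 0.015, 0.12,
                     strategy_A = p$strategy_A, strategy_B = p$strategy_B)
  pk_sat <- pk_params(t_half = 1000, c_half = 1e-9)
  rho <- treated_period_multiplier(pt, pk_sat, 50, Tper)
  lam_star <- dominant_eigen(linear_generator(pt, delta_A = 0.12))$value
  expect_equal(log(rho) / Tper, lam_star, tolerance = 1e-4)
})

test_that("Floquet multiplier decreases with dose", {
  set.seed(43)
  pk <- pk_params(t_half = 8)
  for (i in 1:25) {
    p <- draw_params(treated_gap = TRUE)
    doses <- c(0.5, 2, 8)
    rho <- vapply(doses, function(D)
      treated_period_multiplier(p, pk, D, 96), numeric(1))
    expect_true(all(diff(rho) < 0))
  }
})

test_that("minimal-dose bisection hits the decay threshold", {
  pk <- pk_params(t_half = 8)
  p <- model_params(0.05, 0.02, 0.02, 0.025, 0.15,
                    strategy_A = switching_strategy(0.9, 0.95, 0.01),
                    strategy_B = switching_strategy(0.3, 0.9, 0.01))
  md <- min_effective_dose(p, pk, 96, cap = 100)
  expect_true(md$feasible)
  expect_lt(abs(md$rho - 1), 1e-4)
  expect_lt(treated_period_multiplier(p, pk, 1.01 * md$dose, 96), 1)
  # an ineffective drug is infeasible
  p_flat <- model_params(0.05, 0.02, 0.02, 0.025,
                         strategy_A = p$strategy_A, strategy_B = p$strategy_B)
  expect_false(min_effective_dose(p_flat, pk, 96, cap = 100)$feasible)
  # an already-decaying population needs no drug
  p_dec <- model_params(0.02, 0.01, 0.04, 0.05, 0.1,
                        strategy_A = p$strategy_A, strategy_B = p$strategy_B)
  expect_equal(min_effective_dose(p_dec, pk, 96, cap = 100)$dose, 0)
})

test_that("sensitivity of lambda_P reflects the switching strategy", {
  # finite-difference sensitivities at a reference point lambda_A = lambda_B
  sens <- function(strategy_B) {
    d <- 0.01; lam <- 0.02; h <- 1e-4
    f <- function(la, lb) malthusian_parameter(
      model_params(la + d, lb + d, d, d,
                   strategy_A = switching_strategy(0.9, 0.95, 0.01),
                   strategy_B = strategy_B, check_cost = FALSE))
    c(dA = (f(lam + h, lam) - f(lam - h, lam)) / (2 * h),
      dB = (f(lam, lam + h) - f(lam, lam - h)) / (2 * h))
  }
  stay <- sens(switching_strategy(0.95, 1, 0.01))
  expect_gt(stay["dB"], stay["dA"])
  sw <- sens(switching_strategy(0, 0.9, 0.01))
  expect_gt(sw["dA"], sw["dB"])
})

test_that("symmetric strategies give a symmetric growth-rate grid", {
  s <- switching_strategy(0.9, 0.95, 0.01)
  lam <- seq(-0.01, 0.03, by = 0.01)
  g <- malthusian_grid(lam, lam, s, s, d = 0.01)
  for (i in seq_along(lam)) for (j in seq_len(i)) {
    expect_equal(g[i, j], g[j, i], tolerance = 1e-10)
  }
})
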