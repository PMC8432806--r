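test_that("the rhs vanishes for a closed system and obeys the birth identity", {
  p <- model_params(0, 0, 0, 0, 0,
                    strategy_A = switching_strategy(0.5, 0.9, 0.01),
                    strategy_B = switching_strategy(0.5, 0.9, 0.01))
  st <- c(100, 50, 70, 30, 0)
  d0 <- population_rhs(st, 0, p)
  # populations and drug are static; the retention moments still relax by
  # memory decay as the (unobserved) age distribution shifts
  expect_equal(d0[c(1, 2, 5)], rep(0, 3))
  expect_equal(d0[3], 0.01 * (0.5 * 100 - 70))
  expect_equal(d0[4], 0.01 * (0.5 * 50 - 30))

  p2 <- draw_params()
  st2 <- c(120, 80, 110, 70, 0)
  d <- population_rhs(st2, 0, p2)
  # total birth flux: gains in dA + dB beyond losses equal 2 R_A A + 2 R_B B
  RA <- reproduction_rate("A", st2[1], st2[2], p2)
  RB <- reproduction_rate("B", st2[1], st2[2], p2)
  births <- (d[1] + (RA + p2$d_A) * st2[1]) + (d[2] + (RB + p2$d_B) * st2[2])
  expect_equal(births, 2 * RA * st2[1] + 2 * RB * st2[2], tolerance = 1e-12)
})

test_that("no-switching limit reduces to independent exponential growth", {
  p <- model_params(0.05, 0.02, 0.01, 0.015,
                    strategy_A = switching_strategy(1, 1, 0.01),
                    strategy_B = switching_strategy(1, 1, 0.01))
  st <- c(200, 100, 200, 100, 0)  # N_AA = A, N_BB = B
  d <- population_rhs(st, 0, p)
  expect_equal(d[1], (0.05 - 0.01) * 200, tolerance = 1e-12)
  expect_equal(d[2], (0.02 - 0.015) * 100, tolerance = 1e-12)
})

test_that("eigen initial state matches the stable composition and bounds", {
  set.seed(21)
  for (i in 1:20) {
    p <- draw_params()
    st <- initial_state(p, 1000)
    expect_equal(unname(st["A"] + st["B"]), 1000, tolerance = 1e-9)
    expect_equal(unname(st["A"]) / 1000, sensitive_fraction_stable(p),
                 tolerance = 1e-9)
    sA <- p$strategy_A; sB <- p$strategy_B
    expect_true(st["N_AA"] >= sA$p_min * st["A"] - 1e-9 &&
                  st["N_AA"] <= sA$p_max * st["A"] + 1e-9)
    expect_true(st["N_BB"] >= sB$p_min * st["B"] - 1e-9 &&
                  st["N_BB"] <= sB$p_max * st["B"] + 1e-9)
  }
  # no switching concentrates the state on the fitter phenotype
  pn <- model_params(0.05, 0.01, 0.005, 0.005,
                     strategy_A = switching_strategy(1, 1, 0.01),
                     strategy_B = switching_strategy(1, 1, 0.01))
  stn <- initial_state(pn, 500)
  expect_equal(unname(stn["B"]), 0, tolerance = 1e-8)
  # explicit mode: midpoint retention moments
  se <- initial_state(scenario("symmetric"), 300, mode = "explicit",
                      abar = 200, bbar = 100)
  expect_equal(unname(se["N_AA"]), 0.925 * 200)
  expect_equal(unname(se["N_BB"]), 0.925 * 100)
})

test_that("untreated Malthusian growth follows the Malthusian parameter", {
  set.seed(22)
  for (i in 1:5) {
    p <- draw_params()
    lamP <- malthusian_parameter(p)
    tr <- simulate_population(p, t_span = c(0, 400), n0 = 1000, dt_out = 10)
    N <- rowSums(tr$states[, 1:2])
    sel <- tr$times >= 200
    slope <- unname(coef(lm(log(N[sel]) ~ tr$times[sel]))[2])
    expect_lt(abs(slope - lamP), 1e-3)
  }
})

test_that("zero initial population stays zero", {
  p <- scenario("symmetric")
  tr <- simulate_population(p, t_span = c(0, 100),
                            init = c(0, 0, 0, 0, 0), dt_out = 10)
  expect_true(all(abs(tr$states) < 1e-8))
})

test_that("logistic growth approaches its equilibrium", {
  # without death the reduced system saturates exactly at K
  p <- model_params(0.04, 0.03, 0, 0,
                    growth = growth_law("logistic", K = 1e5))
  tr <- simulate_population(p, t_span = c(0, 24 * 400), n0 = 100, dt_out = 240)
  N_end <- sum(tr$states[nrow(tr$states), 1:2])
  expect_lt(abs(N_end - 1e5) / 1e5, 1e-3)
  # with death the population settles strictly below carrying capacity
  pd <- model_params(0.04, 0.03, 0.002, 0.002,
                     growth = growth_law("logistic", K = 1e5))
  trd <- simulate_population(pd, t_span = c(0, 24 * 400), n0 = 100,
                             dt_out = 240)
  expect_lt(sum(trd$states[nrow(trd$states), 1:2]), 1e5)
})

test_that("trajectories stay nonnegative and respect the moment sandwich", {
  set.seed(23)
  for (i in 1:10) {
    p <- draw_params(treated_gap = TRUE)
    pk <- pk_params(t_half = 6)
    sch <- periodic_schedule(100, 400, 100, 3)
    tr <- simulate_population(p, pk, sch, t_span = c(0, 500), n0 = 1000,
                              dt_out = 5, atol = 1e-9)
    expect_true(all(tr$states > -1e-9 * 1000))
    A <- tr$states[, "A"]; B <- tr$states[, "B"]
    slack <- 1e-6 * (A + B) + 1e-4   # absolute floor where populations crash
    expect_true(all(tr$states[, "N_AA"] >= p$strategy_A$p_min * A - slack))
    expect_true(all(tr$states[, "N_AA"] <= p$strategy_A$p_max * A + slack))
    expect_true(all(tr$states[, "N_BB"] >= p$strategy_B$p_min * B - slack))
    expect_true(all(tr$states[, "N_BB"] <= p$strategy_B$p_max * B + slack))
  }
})

test_that("burden integrates N/K over the window", {
  # synthetic trajectory with a known profile N = K exp(-t / T)
  Tend <- 100
  tt <- seq(0, Tend, by = 0.1)
  K <- 1e4
  tr <- structure(list(times = tt,
                       states = cbind(A = K * exp(-tt / Tend),
                                      B = rep(0, length(tt)),
                                      N_AA = 0, N_BB = 0, C = 0),
                       params = scenario("symmetric")),
                  class = "pheno_trajectory")
  expect_equal(burden(tr, K = K), 1 - exp(-1), tolerance = 1e-5)
  tr$states[, "A"] <- K
  expect_equal(burden(tr, K = K), 1, tolerance = 1e-12)
  tr$states[, "A"] <- 0
  expect_equal(burden(tr, K = K), 0)
  expect_error(burden(tr, K = K, window = c(-5, 50)), "window")
})

test_that("halving solver tolerances leaves the burden unchanged", {
  p <- scenario("switch")
  pk <- pk_params(t_half = 6)
  sch <- periodic_schedule(24 * 50, 24 * 120, 24 * 21, 15)
  b <- vapply(c(1e-8, 5e-9), function(rt) {
    tr <- simulate_population(p, pk, sch, t_span = c(0, 24 * 150), n0 = 1000,
                              dt_out = 12, rtol = rt)
    burden(tr)
  }, numeric(1))
  expect_lt(abs(b[1] - b[2]) / b[2], 1e-4)
})

test_that("trajectory round-trips through its CSV writer", {
  p <- scenario("symmetric")
  tr <- simulate_population(p, t_span = c(0, 48), n0 = 100, dt_out = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  df <- read.csv(path)
  expect_equal(names(df),
               c("t_hours", "A", "B", "N_AA", "N_BB", "C", "theta", "N_total"))
  expect_equal(df$N_total, df$A + df$B, tolerance = 1e-12)
  expect_equal(nrow(df), length(tr$times))
})
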