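# Malthusian variant of a scenario (fitting operates in the
# exponential-growth regime).
.malth <- function(p) model_params(p$r_A, p$r_B, p$d_A, p$d_B, p$d_A_max,
                                   strategy_A = p$strategy_A,
                                   strategy_B = p$strategy_B)

test_that("predicted totals follow closed forms in simple limits", {
  # no switching, untreated: plain exponential growth at lambda_A
  p <- model_params(0.03, 0.01, 0.01, 0.01, 0.08,
                    strategy_A = switching_strategy(1, 1, 0.01),
                    strategy_B = switching_strategy(1, 1, 0.01))
  d <- data.frame(time_hours = c(24, 72, 120), count = 500,
                  condition = "untreated", t_treat_hours = 72)
  pred <- predicted_total(p, d)
  expect_equal(pred, 500 * exp(0.02 * (c(24, 72, 120) - 24)),
               tolerance = 1e-8)
  # drug condition identical to untreated before t_treat
  dd <- data.frame(time_hours = c(24, 48, 71.9), count = 500,
                   condition = "drug", t_treat_hours = 72)
  du <- dd; du$condition <- "untreated"
  expect_equal(predicted_total(p, dd), predicted_total(p, du),
               tolerance = 1e-10)
  # after t_treat the sensitive population decays at lambda_A_star
  d2 <- data.frame(time_hours = c(72, 96, 144), count = 500,
                   condition = "drug", t_treat_hours = 72)
  pred2 <- predicted_total(p, d2)
  expect_equal(pred2, 500 * exp(-0.05 * (c(72, 96, 144) - 72)),
               tolerance = 1e-8)
})

test_that("treated counts fall then rebound when the tolerant pool expands", {
  p <- model_params(0.03, 0.012, 0.005, 0.01, 0.3,
                    strategy_A = switching_strategy(0, 0.95, 0.01),
                    strategy_B = switching_strategy(0.9, 0.99, 0.01))
  d <- data.frame(time_hours = c(24, 72, 96, 360, 720), count = 2000,
                  condition = "drug", t_treat_hours = 72)
  pred <- predicted_total(p, d)
  expect_lt(pred[3], pred[2])           # fall after treatment starts
  expect_gt(pred[5], pred[4])           # tolerant-driven rebound
})

test_that("the SSE objective sums squared residuals over datasets", {
  p <- .malth(scenario("wt_like"))
  des <- assay_design(noise = "none")
  dat <- generate_assays(p, des, n0 = 1000)
  expect_equal(sse_growth(p, dat), 0, tolerance = 1e-10)
  d1 <- dat[[1]]
  d1$count <- d1$count + c(0, 2, -2, 0)   # leave the anchor point untouched
  expect_equal(sse_growth(p, list(d1)), 8, tolerance = 1e-6)
  # invariant under dataset reordering; never decreases with more data
  expect_equal(sse_growth(p, list(d1, dat[[2]])),
               sse_growth(p, list(dat[[2]], d1)))
  expect_gte(sse_growth(p, list(d1, dat[[2]])), sse_growth(p, list(d1)))
})

test_that("noiseless joint data are fit nearly exactly", {
  truth <- .malth(scenario("wt_like"))
  dat <- generate_assays(truth, assay_design(noise = "none"), n0 = 1000)
  fit <- fit_growth_model(dat, n_starts = 8, seed = 4)
  expect_lt(fit$sse, 1e-6 * sum(unlist(lapply(dat, `[[`, "count"))^2))
  # the population growth rate (the untreated log-slope) is identified
  expect_lt(abs(malthusian_parameter(fit$params) -
                  malthusian_parameter(truth)) /
              malthusian_parameter(truth), 0.01)
})

test_that("strategy classification needs the treated condition", {
  sigma <- 0.01
  truth_sw <- model_params(0.05, 0.02, 0.03, 0.03, 0.09,
                           strategy_A = switching_strategy(0, 0.95, sigma),
                           strategy_B = switching_strategy(0, 0.9, sigma))
  des <- assay_design(noise = "none")
  dat <- generate_assays(truth_sw, des, n0 = 1000)
  cl <- classify_strategy(dat, n_starts = 6, seed = 5)
  expect_equal(cl$strategy, "switch")
  # untreated-only: both strategies fit equally well (non-identifiable)
  dat_u <- dat[vapply(dat, function(d) d$condition[1] == "untreated",
                      logical(1))]
  cl_u <- classify_strategy(dat_u, n_starts = 6, seed = 5)
  expect_lt(abs(cl_u$sse_switch - cl_u$sse_stay),
            0.01 * max(cl_u$sse_switch, cl_u$sse_stay, 1e-9))
})

test_that("drug refits freeze the growth parameters bit-identically", {
  truth <- .malth(scenario("wt_like"))
  dat <- generate_assays(truth, assay_design(noise = "none"), n0 = 1000)
  base <- fit_growth_model(dat, n_starts = 6, seed = 6)
  # second drug: larger maximal kill, different tolerant retention
  truth2 <- model_params(truth$r_A, truth$r_B, truth$d_A, truth$d_B, 0.15,
                         strategy_A = truth$strategy_A,
                         strategy_B = switching_strategy(0.7, 0.95, 0.01))
  dat2 <- generate_assays(truth2, assay_design(noise = "none", seed = 2),
                          n0 = 1000, drug_name = "drug2")
  re <- refit_drug(dat2, base, n_starts = 6, seed = 6)
  expect_identical(re$estimates[["r_A"]], base$estimates[["r_A"]])
  expect_identical(re$estimates[["r_B"]], base$estimates[["r_B"]])
  expect_identical(re$estimates[["d_A"]], base$estimates[["d_A"]])
  # recovered kill ordering across drugs
  expect_gt(re$estimates[["d_A_max"]], base$estimates[["d_A_max"]])
  # same-drug refit reproduces the base optimum
  re_same <- refit_drug(dat, base, n_starts = 6, seed = 6)
  expect_lt(abs(re_same$estimates[["d_A_max"]] -
                  base$estimates[["d_A_max"]]), 0.005)
})

test_that("fit objects expose the standard modelling interface", {
  truth <- .malth(scenario("wt_like"))
  dat <- generate_assays(truth, assay_design(cv = 0.05, seed = 7), n0 = 1000)
  fit <- fit_growth_model(dat, n_starts = 4, seed = 7, maxit = 100)
  expect_s3_class(fit, "growth_fit")
  expect_named(coef(fit), c("r_A", "r_B", "d_A", "d_B", "d_A_max",
                            "p_min_BB", "p_max_BB"))
  pred <- predict(fit)
  expect_length(pred, 2)
  res <- residuals(fit)
  expect_equal(res[[1]], dat[[1]]$count - pred[[1]], tolerance = 1e-12)
  expect_output(print(fit), "SSE")
  sims <- simulate(fit, seed = 1)
  expect_true(all(vapply(sims, is.data.frame, logical(1))))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$estimates$r_A, unname(coef(fit)["r_A"]), tolerance = 1e-12)
  expect_equal(j$seed, 7)
})
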