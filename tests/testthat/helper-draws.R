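# Random but biologically-shaped parameter draws used by the property tests.

draw_strategy <- function() {
  p_min <- runif(1, 0, 0.9)
  switching_strategy(p_min, runif(1, p_min, 1), runif(1, 0.001, 0.5))
}

# Generic plastic population draw (Malthusian analytics).
draw_params <- function(treated_gap = FALSE) {
  r_A <- runif(1, 0.01, 0.1)
  r_B <- runif(1, 0.1, 1) * r_A
  d_A <- runif(1, 0.001, 0.08)
  d_B <- runif(1, 0.001, 0.08)
  d_A_max <- if (treated_gap) d_A + runif(1, 0.01, 0.2) else d_A
  model_params(r_A, r_B, d_A, d_B, d_A_max,
               strategy_A = draw_strategy(),
               strategy_B = draw_strategy())
}

# Draw satisfying the fitted therapy regime lambda_B < 0 < lambda_A and
# lambda_A_star < 0.
draw_params_therapy <- function() {
  r_A <- runif(1, 0.02, 0.08)
  d <- runif(1, 0.3, 0.8) * r_A
  r_B <- runif(1, 0.1, 0.9) * d
  model_params(r_A, r_B, d, d, r_A + runif(1, 0.01, 0.1),
               strategy_A = draw_strategy(),
               strategy_B = draw_strategy())
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-300), tol)
}
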