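# Propagate x' = M x over dt via eigendecomposition (4x4), falling back to
# Matrix::expm when the eigenbasis is ill-conditioned.
.propagate_linear <- function(m, x0, dt) {
  out <- tryCatch({
    e <- eigen(m)
    co <- solve(e$vectors, x0)
    Re(e$vectors %*% (exp(e$values * dt) * co))
  }, error = function(err) NULL)
  if (!is.null(out) && all(is.finite(out))) return(as.numeric(out))
  as.numeric(as.matrix(Matrix::expm(m * dt)) %*% x0)
}

#' Model-predicted total cell counts for a growth assay
#'
#' Simulates the population from an eigen (exponential-growth) initial state
#' anchored at the dataset's first observation, and returns the predicted
#' total `N(t_i) = A(t_i) + B(t_i)` at the observation times.  For the
#' `drug` condition the sensitive death rate steps from `d_A` to `d_A_max`
#' at `t_treat` (constant lethal bath).  Under Malthusian growth the
#' two-phase linear system is propagated in closed form (matrix
#' exponentials); logistic growth falls back to the ODE integrator.
#'
#' @param params A [model_params()].
#' @param dataset A growth-assay data frame with columns `time_hours`,
#'   `count`, `condition` (`"untreated"` or `"drug"`), and
#'   `t_treat_hours` for the drug condition.
#' @return Predicted counts at `dataset$time_hours`.
#' @export
predicted_total <- function(params, dataset) {
  tt <- dataset$time_hours
  if (is.unsorted(tt)) stop("dataset times must be increasing")
  treated <- dataset$condition[1] == "drug"
  t_treat <- if (treated) dataset$t_treat_hours[1] else Inf
  n0 <- dataset$count[1]
  x <- initial_state(params, n0)[1:4]

  if (!params$growth$logistic && !params$growth$allee) {
    m_u <- linear_generator(params)
    m_t <- linear_generator(params, delta_A = params$d_A_max)
    out <- numeric(length(tt))
    out[1] <- n0
    cur_t <- tt[1]
    for (i in seq_along(tt)[-1]) {
      a <- cur_t; b <- tt[i]
      if (treated && a < t_treat && b > t_treat) {
        x <- .propagate_linear(m_u, x, t_treat - a)
        x <- .propagate_linear(m_t, x, b - t_treat)
      } else {
        m <- if (treated && a >= t_treat) m_t else m_u
        x <- .propagate_linear(m, x, b - a)
      }
      out[i] <- x[1] + x[2]
      cur_t <- b
    }
    return(out)
  }
  tr <- simulate_population(params, t_span = c(tt[1], tt[length(tt)]),
                            init = c(x, 0), dt_out = max(diff(tt)),
                            lethal_from = if (treated) t_treat else NULL,
                            rtol = 1e-8)
  f <- stats::approxfun(tr$times, tr$states[, "A"] + tr$states[, "B"])
  f(tt)
}

#' Sum-of-squares fitting objective
#'
#' `sum_i (N(t_i) - Data_i)^2` jointly over all supplied datasets
#' (untreated and treated conditions are fit simultaneously).
#'
#' @param params A [model_params()].
#' @param datasets A growth-assay data frame or list of them.
#' @return Squared count units, >= 0.
#' @export
sse_growth <- function(params, datasets) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  sum(vapply(datasets, function(d) {
    pred <- predicted_total(params, d)
    sum((pred - d$count)^2)
  }, numeric(1)))
}

# Transformed parameterization: every coordinate lives in [0, 1]-ish boxes
# and the ordering constraints (r_B <= r_A, d_A_max >= d_A,
# p_min_BB <= p_max_BB) hold by construction.
.build_params <- function(x, fixed, growth) {
  r_A <- x[["r_A"]]
  r_B <- x[["q_rB"]] * r_A
  d <- x[["d"]]
  d_A_max <- d + x[["gap_dmax"]]
  p_min <- if ("p_min_BB" %in% names(x)) x[["p_min_BB"]] else fixed$p_min_BB
  gap_p <- if ("gap_pBB" %in% names(x)) x[["gap_pBB"]] else NULL
  p_max <- if (is.null(gap_p)) fixed$p_max_BB else p_min + gap_p * (1 - p_min)
  model_params(
    r_A = r_A, r_B = r_B, d_A = d, d_B = d, d_A_max = d_A_max,
    strategy_A = switching_strategy(fixed$p_min_AA, fixed$p_max_AA,
                                    fixed$sigma),
    strategy_B = switching_strategy(p_min, p_max, fixed$sigma),
    growth = growth)
}

.default_fixed <- list(p_min_AA = 0, p_max_AA = 0.95, sigma = 0.01)

# Quasi-Newton (PORT) polished with simplex cycles: the SSE surface has a
# narrow curved valley that line searches alone tend to stall in.
.hybrid_min <- function(obj, par0, lo, hi, maxit) {
  obj_box <- function(x) if (any(x < lo) || any(x > hi)) 1e3 else obj(x)
  r <- tryCatch(
    stats::nlminb(par0, obj, lower = lo, upper = hi,
                  control = list(iter.max = maxit, eval.max = 2 * maxit)),
    error = function(e) list(par = par0, objective = Inf, convergence = -1L))
  for (k in 1:2) {
    nm <- tryCatch(
      stats::optim(r$par, obj_box, method = "Nelder-Mead",
                   control = list(maxit = 10 * maxit, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(nm)) break
    r2 <- tryCatch(
      stats::nlminb(nm$par, obj, lower = lo, upper = hi,
                    control = list(iter.max = maxit, eval.max = 2 * maxit)),
      error = function(e) NULL)
    if (is.null(r2)) break
    if (r2$objective >= r$objective - 1e-12) { r <- r2; break }
    r <- r2
  }
  r
}


#' Fit the switching model to growth-assay data
#'
#' Joint bound-constrained least-squares estimation of
#' `{r_A, r_B, d_A = d_B, d_A_max, p_min_BB, p_max_BB}` from untreated and
#' drug-treated growth assays, minimizing [sse_growth()] by multi-start
#' `L-BFGS-B` from Latin-hypercube seeds.  Conventions fixed a priori:
#' `p_min_AA = 0`, `p_max_AA = 0.95`, `sigma_A = sigma_B = 0.01` per hour,
#' `d_A = d_B`, and the cost of tolerance `r_B <= r_A` (enforced by
#' reparameterization).  Supplying `strategy_B` freezes the tolerant
#' switching strategy and fits only the four growth parameters, which is
#' how switch-vs-stay model selection is done (see [classify_strategy()]).
#'
#' @param datasets A growth-assay data frame or list of them; joint
#'   identifiability of the switching strategy requires both conditions.
#' @param strategy_B Optional fixed [switching_strategy()] for the tolerant
#'   phenotype.
#' @param growth A [growth_law()]; default Malthusian (the assays cover
#'   exponential-phase growth).
#' @param fixed Overrides for the fixed conventions (`p_min_AA`,
#'   `p_max_AA`, `sigma`).
#' @param bounds Named list of `c(lo, hi)` for the transformed coordinates
#'   `r_A, q_rB, d, gap_dmax, p_min_BB, gap_pBB`.
#' @param n_starts Number of Latin-hypercube starting points.
#' @param seed RNG seed for the start design.
#' @param maxit `optim` iteration cap per start.
#' @return An object of class `growth_fit` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `simulate` and `plot`
#'   methods.
#' @export
fit_growth_model <- function(datasets, strategy_B = NULL,
                             growth = growth_law("malthusian"),
                             fixed = list(), bounds = list(),
                             n_starts = 15, seed = 1, maxit = 200) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  fixed <- utils::modifyList(.default_fixed, fixed)
  if (!is.null(strategy_B)) {
    fixed$p_min_BB <- strategy_B$p_min
    fixed$p_max_BB <- strategy_B$p_max
  }
  free <- c("r_A", "q_rB", "d", "gap_dmax")
  if (is.null(strategy_B)) free <- c(free, "p_min_BB", "gap_pBB")
  default_bounds <- list(r_A = c(1e-5, 1), q_rB = c(0, 1), d = c(0, 1),
                         gap_dmax = c(0, 1), p_min_BB = c(0, 1),
                         gap_pBB = c(0, 1))
  bounds <- utils::modifyList(default_bounds, bounds)
  lo <- vapply(free, function(k) bounds[[k]][1], numeric(1))
  hi <- vapply(free, function(k) bounds[[k]][2], numeric(1))
  # start design confined to a plausible sub-box for the rates
  start_hi <- hi
  start_hi[free %in% c("r_A", "d", "gap_dmax")] <- 0.3

  sse_of <- function(x) {
    names(x) <- free
    p <- tryCatch(.build_params(x, fixed, growth), error = function(e) NULL)
    if (is.null(p)) return(Inf)
    v <- tryCatch(sse_growth(p, datasets), error = function(e) NA_real_)
    if (!is.finite(v)) Inf else v
  }
  # optimize on the log scale: same minimizer, far better conditioning
  floor_ <- 1e-14 * sum(unlist(lapply(datasets, `[[`, "count"))^2)
  obj <- function(x) {
    v <- sse_of(x)
    if (!is.finite(v)) 1e3 else log(v + floor_)
  }
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, length(free))
  starts <- sweep(sweep(design, 2, start_hi - lo, "*"), 2, lo, "+")
  runs <- lapply(seq_len(n_starts), function(s)
    .hybrid_min(obj, starts[s, ], lo, hi, maxit))
  vals <- vapply(runs, function(r) exp(r$objective) - floor_, numeric(1))
  if (all(!is.finite(vals))) stop("all optimization starts failed")
  best <- which.min(vals)
  par <- stats::setNames(runs[[best]]$par, free)
  params <- .build_params(par, fixed, growth)
  est <- c(r_A = params$r_A, r_B = params$r_B, d_A = params$d_A,
           d_B = params$d_B, d_A_max = params$d_A_max,
           p_min_BB = params$strategy_B$p_min,
           p_max_BB = params$strategy_B$p_max)
  structure(list(params = params, estimates = est, sse = sse_growth(params, datasets),
                 par = par, free = free, fixed = fixed,
                 strategy_fixed = !is.null(strategy_B),
                 starts = data.frame(value = vals,
                                     convergence = vapply(runs, function(r)
                                       as.integer(r$convergence %||% -1L),
                                       integer(1))),
                 best_start = best, n_starts = n_starts, seed = seed,
                 growth = growth, datasets = datasets,
                 bounds = bounds[free]),
            class = "growth_fit")
}

#' Refit only the drug-response parameters for a second drug
#'
#' Freezes the tumour growth parameters `r_A, r_B, d_A = d_B` at the values
#' of a base fit (cross-resistance: the tolerant growth rate is not refit)
#' and re-estimates only `{d_A_max, p_min_BB, p_max_BB}` from the new
#' drug's assays.
#'
#' @param datasets Growth-assay data for the new drug (both conditions).
#' @param base A converged `growth_fit`.
#' @param n_starts,seed,maxit As in [fit_growth_model()].
#' @return A `growth_fit`; the frozen parameters are copied bit-identically
#'   from `base` and recorded in `$fixed`.
#' @export
refit_drug <- function(datasets, base, n_starts = 15, seed = 1, maxit = 200) {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  stopifnot(inherits(base, "growth_fit"))
  bp <- base$params
  fixed <- base$fixed
  free <- c("gap_dmax", "p_min_BB", "gap_pBB")
  lo <- c(0, 0, 0); hi <- c(1, 1, 1)
  obj <- function(x) {
    names(x) <- free
    full <- c(r_A = unname(bp$r_A),
              q_rB = unname(bp$r_B / bp$r_A),
              d = unname(bp$d_A), x)
    p <- tryCatch(.build_params(full, fixed, base$growth),
                  error = function(e) NULL)
    if (is.null(p)) return(1e3)
    v <- tryCatch(sse_growth(p, datasets), error = function(e) NA_real_)
    if (!is.finite(v)) 1e3 else log(v + 1e-12)
  }
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, length(free))
  start_hi <- c(0.3, 1, 1)
  starts <- sweep(sweep(design, 2, start_hi - lo, "*"), 2, lo, "+")
  runs <- lapply(seq_len(n_starts), function(s)
    .hybrid_min(obj, starts[s, ], lo, hi, maxit))
  vals <- vapply(runs, function(r) exp(r$objective), numeric(1))
  best <- which.min(vals)
  par <- stats::setNames(runs[[best]]$par, free)
  full <- c(r_A = unname(bp$r_A), q_rB = unname(bp$r_B / bp$r_A),
            d = unname(bp$d_A), par)
  params <- .build_params(full, fixed, base$growth)
  est <- c(r_A = params$r_A, r_B = params$r_B, d_A = params$d_A,
           d_B = params$d_B, d_A_max = params$d_A_max,
           p_min_BB = params$strategy_B$p_min,
           p_max_BB = params$strategy_B$p_max)
  structure(list(params = params, estimates = est,
                 sse = sse_growth(params, datasets),
                 par = par, free = free,
                 fixed = c(fixed, list(r_A = bp$r_A, r_B = bp$r_B,
                                       d_A = bp$d_A)),
                 strategy_fixed = FALSE,
                 starts = data.frame(value = vals,
                                     convergence = vapply(runs, function(r)
                                       as.integer(r$convergence %||% -1L),
                                       integer(1))),
                 best_start = best, n_starts = n_starts, seed = seed,
                 growth = base$growth, datasets = datasets,
                 bounds = NULL),
            class = "growth_fit")
}

#' Classify the tolerant switching strategy from data
#'
#' Fits the model twice with the tolerant strategy frozen at the two
#' contrasting reference strategies -- `switch` `(0, 0.9)` and `stay`
#' `(0.95, 1)` -- and selects the one with the lower joint SSE.  With
#' treated and untreated data together the treatment response separates
#' the strategies; untreated data alone leaves them practically
#' indistinguishable.
#'
#' @param datasets Growth-assay data (data frame or list).
#' @param sigma Memory decay rate used for both candidate strategies.
#' @param ... Passed to [fit_growth_model()].
#' @return List with `strategy` (`"switch"` or `"stay"`), `sse_switch`,
#'   `sse_stay`, and both fits.
#' @export
classify_strategy <- function(datasets, sigma = 0.01, ...) {
  f_sw <- fit_growth_model(datasets,
                           strategy_B = switching_strategy(0, 0.9, sigma), ...)
  f_st <- fit_growth_model(datasets,
                           strategy_B = switching_strategy(0.95, 1, sigma), ...)
  list(strategy = if (f_sw$sse <= f_st$sse) "switch" else "stay",
       sse_switch = f_sw$sse, sse_stay = f_st$sse,
       fit_switch = f_sw, fit_stay = f_st)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("phenotype-switching growth model fit\n")
  cat(sprintf("  SSE = %.6g (best of %d starts, start %d)\n",
              x$sse, x$n_starts, x$best_start))
  print(signif(x$estimates, 5))
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  lam <- lambda_rates(object$params)
  cat("phenotype-switching growth model fit\n")
  cat(sprintf("  datasets: %d (%s)\n", length(object$datasets),
              paste(vapply(object$datasets, function(d)
                as.character(d$condition[1]), character(1)), collapse = ", ")))
  cat(sprintf("  SSE = %.6g; converged starts: %d / %d\n", object$sse,
              sum(object$starts$convergence == 0), object$n_starts))
  cat("  estimates (per hour / probabilities):\n")
  print(signif(object$estimates, 5))
  cat(sprintf("  derived: lambda_A = %.4g, lambda_B = %.4g, lambda_A* = %.4g\n",
              lam["lambda_A"], lam["lambda_B"], lam["lambda_A_star"]))
  if (lam["lambda_B"] < 0 && lam["lambda_A"] > 0)
    cat(sprintf("  theta* = %.4g\n", theta_star(object$params)))
  invisible(object)
}

#' @export
coef.growth_fit <- function(object, ...) object$estimates

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$datasets
          else if (is.data.frame(newdata)) list(newdata) else newdata
  out <- lapply(data, function(d) predicted_total(object$params, d))
  if (length(out) == 1L) out[[1]] else out
}

#' @export
fitted.growth_fit <- function(object, ...) predict(object)

#' @export
residuals.growth_fit <- function(object, ...) {
  pred <- predict(object)
  if (!is.list(pred)) pred <- list(pred)
  res <- Map(function(d, p) d$count - p, object$datasets, pred)
  if (length(res) == 1L) res[[1]] else res
}

#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL,
                                design = NULL, ...) {
  if (is.null(design)) {
    if (is.null(seed)) seed <- 1
    design <- assay_design(seed = seed, n_replicates = nsim)
  }
  generate_assays(object$params, design,
                  n0 = object$datasets[[1]]$count[1])
}

#' @export
plot.growth_fit <- function(x, ...) {
  cols <- c(untreated = "navy", drug = "firebrick")
  all_t <- unlist(lapply(x$datasets, `[[`, "time_hours"))
  all_c <- unlist(lapply(x$datasets, `[[`, "count"))
  graphics::plot(range(all_t) / 24, range(all_c), type = "n",
                 xlab = "time (days)", ylab = "cells", log = "y", ...)
  for (d in x$datasets) {
    col <- cols[[as.character(d$condition[1])]]
    graphics::points(d$time_hours / 24, d$count, col = col, pch = 16)
    tt <- seq(min(d$time_hours), max(d$time_hours), length.out = 100)
    nd <- data.frame(time_hours = tt, count = d$count[1],
                     condition = d$condition[1],
                     t_treat_hours = d$t_treat_hours[1])
    nd$count[1] <- d$count[1]
    graphics::lines(tt / 24, predicted_total(x$params, nd), col = col)
  }
  graphics::legend("topleft", names(cols), col = cols, pch = 16, bty = "n")
  invisible(x)
}

#' Write a fit result as JSON
#' @param fit A `growth_fit`.
#' @param path Output file.
#' @export
write_fit <- function(fit, path) {
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates), sse = fit$sse,
         fixed = fit$fixed, n_starts = fit$n_starts,
         best_start = fit$best_start, seed = fit$seed,
         start_values = fit$starts$value,
         growth_mode = fit$growth$mode),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
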