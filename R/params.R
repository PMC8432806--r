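#' Phenotype-retention (switching) strategy
#'
#' A switching strategy describes how the probability that a dividing cell of
#' phenotype i produces daughters of the same phenotype depends on the age of
#' the mother cell.  Young mothers retain their phenotype with probability
#' close to `p_max`; as intracellular signalling factors decay (rate `sigma`,
#' per hour) the retention probability relaxes towards `p_min`:
#' beta_ii(a) = p_min + (p_max - p_min) * exp(-sigma * a).
#'
#' @param p_min Minimal retention probability (the large-age limit).
#' @param p_max Maximal retention probability (at age 0).
#' @param sigma Memory decay rate of the intracellular signal, per hour.
#' @return An object of class `switching_strategy`.
#' @examples
#' s <- switching_strategy(0.9, 0.95, 0.01)
#' switching_probability(s, age = c(0, 100, 1000))
#' @export
switching_strategy <- function(p_min, p_max, sigma = 0.01) {
  stopifnot(is.numeric(p_min), is.numeric(p_max), is.numeric(sigma),
            length(p_min) == 1L, length(p_max) == 1L, length(sigma) == 1L)
  if (p_min < 0 || p_max > 1 || p_min > p_max)
    stop("need 0 <= p_min <= p_max <= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(p_min = p_min, p_max = p_max, sigma = sigma),
            class = "switching_strategy")
}

#' @export
print.switching_strategy <- function(x, ...) {
  cat(sprintf("switching strategy: (P* = %g, Pmax = %g), sigma = %g /h\n",
              x$p_min, x$p_max, x$sigma))
  invisible(x)
}

#' Age-dependent phenotype retention probability
#'
#' Evaluates beta_ii(a) = p_min + (p_max - p_min) exp(-sigma a).  The
#' probability that a daughter switches phenotype is `1 - switching_probability`.
#'
#' @param strategy A [switching_strategy()].
#' @param age Mother-cell age(s) at division, hours; must be nonnegative.
#' @return Retention probabilities, same length as `age`, in `[p_min, p_max]`.
#' @export
switching_probability <- function(strategy, age) {
  stopifnot(inherits(strategy, "switching_strategy"))
  if (any(age < 0)) stop("age must be nonnegative")
  strategy$p_min + (strategy$p_max - strategy$p_min) * exp(-strategy$sigma * age)
}

#' Growth-law selection
#'
#' @param mode One of `"malthusian"`, `"logistic"`, `"malthusian_allee"`,
#'   `"logistic_allee"`.  The `allee` modes multiply the drug-tolerant
#'   division rate by the cooperation factor [cooperation_factor()].
#' @param K Carrying capacity, cells (logistic modes).
#' @param n Hill coefficient of the cooperation factor, >= 1 (allee modes).
#' @return An object of class `growth_law`.
#' @export
growth_law <- function(mode = c("malthusian", "logistic",
                                "malthusian_allee", "logistic_allee"),
                       K = NA_real_, n = 1) {
  mode <- match.arg(mode)
  logistic <- mode %in% c("logistic", "logistic_allee")
  allee <- mode %in% c("malthusian_allee", "logistic_allee")
  if (logistic && (!is.finite(K) || K <= 0)) stop("logistic modes need K > 0")
  if (allee && n < 1) stop("allee modes need Hill coefficient n >= 1")
  structure(list(mode = mode, K = K, n = n,
                 logistic = logistic, allee = allee),
            class = "growth_law")
}

#' Full model parameter set
#'
#' Collects division and death rates of the drug-sensitive (A) and
#' drug-tolerant (B) phenotypes, the maximal drug-induced sensitive death
#' rate, both switching strategies and the growth law.  All rates are per
#' hour.  The cost of tolerance is enforced as `r_B <= r_A`.
#'
#' @param r_A,r_B Division rates, per hour.
#' @param d_A,d_B Death rates, per hour.
#' @param d_A_max Maximal sensitive death rate under saturating drug, >= d_A.
#' @param strategy_A,strategy_B [switching_strategy()] for each phenotype.
#' @param growth A [growth_law()].
#' @param check_cost Enforce the cost-of-tolerance assumption `r_B <= r_A`
#'   (default). Fitness analytics that sweep both net growth rates (e.g.
#'   [malthusian_grid()]) disable the check; the cooperation factor is only
#'   defined under the cost assumption.
#' @return An object of class `pheno_params`, carrying derived net rates
#'   `lambda_A = r_A - d_A`, `lambda_B = r_B - d_B`,
#'   `lambda_A_star = r_A - d_A_max` as attributes of convenience via
#'   [lambda_rates()].
#' @export
model_params <- function(r_A, r_B, d_A, d_B = d_A, d_A_max = d_A,
                         strategy_A = switching_strategy(0.9, 0.95, 0.01),
                         strategy_B = switching_strategy(0.9, 0.95, 0.01),
                         growth = growth_law("malthusian"),
                         check_cost = TRUE) {
  rates <- c(r_A = r_A, r_B = r_B, d_A = d_A, d_B = d_B, d_A_max = d_A_max)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and nonnegative")
  if (check_cost && r_B > r_A + 1e-12)
    stop("cost of tolerance requires r_B <= r_A")
  if (d_A_max < d_A) stop("d_A_max must be >= d_A")
  stopifnot(inherits(strategy_A, "switching_strategy"),
            inherits(strategy_B, "switching_strategy"),
            inherits(growth, "growth_law"))
  structure(list(r_A = r_A, r_B = r_B, d_A = d_A, d_B = d_B,
                 d_A_max = d_A_max, strategy_A = strategy_A,
                 strategy_B = strategy_B, growth = growth),
            class = "pheno_params")
}

#' Net intrinsic growth rates
#'
#' @param params A [model_params()] object.
#' @return Named vector with `lambda_A = r_A - d_A` (untreated sensitive),
#'   `lambda_B = r_B - d_B` (tolerant) and
#'   `lambda_A_star = r_A - d_A_max` (treated sensitive at saturating drug).
#' @export
lambda_rates <- function(params) {
  c(lambda_A = params$r_A - params$d_A,
    lambda_B = params$r_B - params$d_B,
    lambda_A_star = params$r_A - params$d_A_max)
}

#' @export
print.pheno_params <- function(x, ...) {
  lam <- lambda_rates(x)
  cat("phenotype-switching model parameters (per hour)\n")
  cat(sprintf("  sensitive: r_A = %g, d_A = %g, d_A_max = %g  (lambda_A = %g, lambda_A* = %g)\n",
              x$r_A, x$d_A, x$d_A_max, lam["lambda_A"], lam["lambda_A_star"]))
  cat(sprintf("  tolerant:  r_B = %g, d_B = %g  (lambda_B = %g)\n",
              x$r_B, x$d_B, lam["lambda_B"]))
  cat(sprintf("  strategy A: (%g, %g, sigma %g); strategy B: (%g, %g, sigma %g)\n",
              x$strategy_A$p_min, x$strategy_A$p_max, x$strategy_A$sigma,
              x$strategy_B$p_min, x$strategy_B$p_max, x$strategy_B$sigma))
  cat(sprintf("  growth: %s", x$growth$mode))
  if (x$growth$logistic) cat(sprintf(", K = %g", x$growth$K))
  if (x$growth$allee) cat(sprintf(", n = %g", x$growth$n))
  cat("\n")
  invisible(x)
}

#' Serialize / deserialize model parameters
#'
#' Flat key-value JSON representation with keys `r_A, r_B, d_A, d_B, d_A_max,
#' p_min_AA, p_max_AA, sigma_A, p_min_BB, p_max_BB, sigma_B, growth_mode, K, n`.
#' All rates are per hour; `K` in cells.
#'
#' @param params A [model_params()] object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` a
#'   [model_params()] object.
#' @export
write_params <- function(params, path) {
  flat <- list(
    r_A = params$r_A, r_B = params$r_B, d_A = params$d_A, d_B = params$d_B,
    d_A_max = params$d_A_max,
    p_min_AA = params$strategy_A$p_min, p_max_AA = params$strategy_A$p_max,
    sigma_A = params$strategy_A$sigma,
    p_min_BB = params$strategy_B$p_min, p_max_BB = params$strategy_B$p_max,
    sigma_B = params$strategy_B$sigma,
    growth_mode = params$growth$mode, K = params$growth$K, n = params$growth$n)
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_params(
    r_A = x$r_A, r_B = x$r_B, d_A = x$d_A, d_B = x$d_B, d_A_max = x$d_A_max,
    strategy_A = switching_strategy(x$p_min_AA, x$p_max_AA, x$sigma_A),
    strategy_B = switching_strategy(x$p_min_BB, x$p_max_BB, x$sigma_B),
    growth = growth_law(x$growth_mode,
                        K = if (is.null(x$K)) NA_real_ else x$K,
                        n = if (is.null(x$n)) 1 else x$n))
}
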