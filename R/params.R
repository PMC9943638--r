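#' Model parameters
#'
#' Container for all exogenous parameters of the desperation-threshold
#' violence model, plus the decision horizon and the resource-grid
#' discretization used by the dynamic-programming solver.
#'
#' The resource state of an agent follows a stationary AR(1) process with
#' mean \code{mu}, standard deviation \code{sigma} and autocorrelation
#' \code{r}. The desperation threshold is fixed at 0: agents whose resources
#' fall below it pay a multiplicative fitness cost \code{omega} per period.
#' Exploitation attempts to take \code{beta} resources from a target and is
#' sanctioned with probability \code{gamma} at a cost of \code{pi_cost}
#' resources; the parameters must satisfy
#' \code{(1 - gamma) * beta - gamma * pi_cost <= 0} so that stealing is on
#' average unprofitable. Exploiters pick their target among
#' \code{n_targets} randomly drawn candidates, preferring submissive ones,
#' which is what makes the violent strategy a protective "toughness signal".
#' Violent agents enter a mistaken fight with probability \code{m} per round
#' and each lost fight costs a fraction \code{lam} of terminal fitness.
#'
#' @param mu mean resource level (resource units).
#' @param sigma standard deviation of resource levels (resource units).
#' @param r AR(1) autocorrelation of the resource state, in [0, 1).
#' @param N_pop population size for agent-based simulations.
#' @param n_targets number of candidate targets an exploiter samples (>= 1).
#' @param beta exploitation stake (resource units).
#' @param pi_cost punishment cost (resource units).
#' @param gamma punishment probability.
#' @param m probability that a violent agent attacks a non-exploiter by
#'   mistake in a given round.
#' @param omega per-period multiplicative fitness penalty for being below
#'   the desperation threshold.
#' @param lam multiplicative fitness penalty per lost fight.
#' @param T_horizon decision horizon (number of periods) of the
#'   backward-induction solver.
#' @param threshold desperation threshold (fixed at 0 in the model; kept as
#'   a field so alternative threshold rules can be hooked in).
#' @param grid_lo,grid_hi lower/upper bound of the resource grid. Defaults
#'   (\code{NULL}) cover \code{mu +/- 5 sigma} and always include
#'   \code{[-3 sigma, sigma]} around the threshold.
#' @param grid_n number of grid points.
#'
#' @return An object of class \code{violence_params}: a validated list of
#'   parameters.
#' @examples
#' p <- model_params()
#' p
#' model_params(mu = 5, sigma = 4, n_targets = 10)
#' @export
model_params <- function(mu = 25, sigma = 10, r = 0.99, N_pop = 1e5,
                         n_targets = 50, beta = 10, pi_cost = 20,
                         gamma = 1/3, m = 0.035, omega = 0.10, lam = 0.30,
                         T_horizon = 50, threshold = 0,
                         grid_lo = NULL, grid_hi = NULL, grid_n = 301) {
  p <- list(mu = mu, sigma = sigma, r = r, N_pop = N_pop,
            n_targets = n_targets, beta = beta, pi_cost = pi_cost,
            gamma = gamma, m = m, omega = omega, lam = lam,
            T_horizon = T_horizon, threshold = threshold,
            grid_lo = grid_lo, grid_hi = grid_hi, grid_n = grid_n)
  if (is.null(p$grid_lo)) p$grid_lo <- min(mu - 5 * sigma, -3 * sigma)
  if (is.null(p$grid_hi)) p$grid_hi <- max(mu + 5 * sigma, sigma)
  validate_params(p)
  class(p) <- "violence_params"
  p
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("mu", "sigma", "r", "N_pop", "n_targets", "beta", "pi_cost",
              "gamma", "m", "omega", "lam", "T_horizon", "threshold",
              "grid_lo", "grid_hi", "grid_n"))
    if (!num1(p[[f]])) stop("parameter '", f, "' must be a finite number")
  if (p$sigma <= 0) stop("sigma must be positive")
  if (p$r < 0 || p$r >= 1) stop("r must be in [0, 1)")
  for (f in c("gamma", "m", "omega", "lam"))
    if (p[[f]] < 0 || p[[f]] > 1) stop("'", f, "' must be a probability in [0, 1]")
  if (p$beta < 0 || p$pi_cost < 0) stop("beta and pi_cost must be >= 0")
  if (p$n_targets < 1 || p$n_targets != round(p$n_targets))
    stop("n_targets must be an integer >= 1")
  if (p$N_pop < 1 || p$N_pop != round(p$N_pop))
    stop("N_pop must be an integer >= 1")
  if (p$T_horizon < 1 || p$T_horizon != round(p$T_horizon))
    stop("T_horizon must be an integer >= 1")
  if (p$threshold != 0)
    warning("the model is formulated for threshold = 0; other values are an unanalysed hook")
  if (!(p$grid_lo < p$threshold && p$threshold < p$grid_hi))
    stop("resource grid must bracket the desperation threshold")
  if (p$grid_n < 2 || p$grid_n != round(p$grid_n))
    stop("grid_n must be an integer >= 2")
  # Stealing must be on average a bad decision, even against an undefended
  # target: (1 - gamma) * beta <= gamma * pi_cost.
  if ((1 - p$gamma) * p$beta - p$gamma * p$pi_cost > 1e-9)
    stop("invalid parameters: expected exploitation payoff ",
         "(1-gamma)*beta - gamma*pi_cost = ",
         format((1 - p$gamma) * p$beta - p$gamma * p$pi_cost),
         " must be <= 0")
  invisible(p)
}

#' @export
print.violence_params <- function(x, ...) {
  cat("Desperation-threshold violence model parameters\n")
  cat(sprintf("  resources: mu = %g, sigma = %g, r = %g (threshold at %g)\n",
              x$mu, x$sigma, x$r, x$threshold))
  cat(sprintf("  exploitation: beta = %g, pi = %g, gamma = %g, n_targets = %d\n",
              x$beta, x$pi_cost, x$gamma, as.integer(x$n_targets)))
  cat(sprintf("  fitness: omega = %g, lam = %g, mistake rate m = %g, horizon T = %d\n",
              x$omega, x$lam, x$m, as.integer(x$T_horizon)))
  cat(sprintf("  population: N = %d; grid: %d points on [%g, %g]\n",
              as.integer(x$N_pop), as.integer(x$grid_n), x$grid_lo, x$grid_hi))
  invisible(x)
}

#' Population strategy frequencies
#'
#' @param e fraction of exploiters.
#' @param v fraction of violent (non-exploiting) agents.
#' @param s fraction of submissive agents; defaults to \code{1 - e - v}.
#' @return An object of class \code{strategy_freqs} with fields
#'   \code{e}, \code{v}, \code{s} summing to one.
#' @examples
#' strategy_freqs(e = 0.1, v = 0.3)
#' @export
strategy_freqs <- function(e, v, s = 1 - e - v) {
  if (any(c(e, v, s) < -1e-12) || any(c(e, v, s) > 1 + 1e-12))
    stop("strategy frequencies must lie in [0, 1]")
  if (abs(e + v + s - 1) > 1e-9)
    stop("strategy frequencies must sum to 1 (got ", format(e + v + s), ")")
  out <- list(e = min(max(e, 0), 1), v = min(max(v, 0), 1),
              s = min(max(s, 0), 1))
  class(out) <- "strategy_freqs"
  out
}

#' @export
print.strategy_freqs <- function(x, ...) {
  cat(sprintf("strategy frequencies: exploit %.4f, violent %.4f, submissive %.4f\n",
              x$e, x$v, x$s))
  invisible(x)
}

# canonical strategy labels, in tie-break order (least risky first)
STRATEGIES <- c("submissive", "violent", "exploit")
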