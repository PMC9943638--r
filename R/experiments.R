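#' Mean resource level for a target desperation rate
#'
#' Inverts the Gaussian tail: with resources \eqn{N(\mu, \sigma^2)} and the
#' threshold at 0, the expected desperation rate equals
#' \eqn{\Phi(-\mu/\sigma)}, so \eqn{\mu = -\sigma \Phi^{-1}(rate)}. This is
#' how the experiment drivers vary deprivation at fixed inequality.
#'
#' @param desperation_rate target fraction below the threshold, in (0, 1).
#' @param sigma resource standard deviation.
#' @return Mean resource level \code{mu}.
#' @examples
#' rate_to_mu(0.5, 10)          # 0
#' rate_to_mu(pnorm(-2.5), 10)  # 25
#' @export
rate_to_mu <- function(desperation_rate, sigma) {
  if (any(desperation_rate <= 0) || any(desperation_rate >= 1))
    stop("desperation_rate must lie strictly inside (0, 1)")
  if (sigma <= 0) stop("sigma must be positive")
  -sigma * stats::qnorm(desperation_rate)
}

# params with mu set for a desperation rate (grid re-derived from mu)
params_at_rate <- function(params, rate) {
  model_params(mu = rate_to_mu(rate, params$sigma), sigma = params$sigma,
               r = params$r, N_pop = params$N_pop,
               n_targets = params$n_targets, beta = params$beta,
               pi_cost = params$pi_cost, gamma = params$gamma, m = params$m,
               omega = params$omega, lam = params$lam,
               T_horizon = params$T_horizon, threshold = params$threshold,
               grid_n = params$grid_n)
}

#' Equilibrium violence across desperation rates and initial conditions
#'
#' For each target desperation rate, sets \code{mu} via [rate_to_mu], builds
#' a population under each initial strategy configuration and iterates to
#' equilibrium. Running both the all-submissive and the all-violent
#' initialization exposes the bistable window, where the two arrive at
#' different equilibria, and hence the hysteresis loop: a population keeps
#' the violent equilibrium it inherited even at desperation rates where a
#' peaceful population would stay peaceful.
#'
#' @param params a [model_params] object (its \code{mu} is overridden per
#'   rate).
#' @param rates numeric vector of target desperation rates in (0, 1).
#' @param inits character vector among \code{"all_submissive"},
#'   \code{"all_violent"}.
#' @param seed integer seed; each (rate, init) run gets a distinct stream
#'   derived from it.
#' @param protocol \code{"fresh"} builds a new population from its
#'   initialization at every rate. \code{"continuation"} reproduces the
#'   hysteresis loop itself: the \code{all_submissive} branch walks the
#'   rates upward and the \code{all_violent} branch walks them downward,
#'   each rate starting from the previous rate's converged strategies (only
#'   the resources are redrawn to hit the new desperation rate, preserving
#'   each agent's rank). The continuation protocol is the one that can
#'   actually reach the high-violence equilibrium at low desperation rates:
#'   its basin is so small (strategies must be near-saturated \emph{and}
#'   exploiters already present) that a fresh all-violent population, whose
#'   exploiters only accumulate while its violence drains, falls out of it.
#' @param ... further arguments passed to [run_to_equilibrium]
#'   (\code{tol}, \code{window}, \code{max_steps}, \code{fraction}).
#' @return An object of class \code{violence_sweep}: data.frame with columns
#'   \code{desperation_rate_target}, \code{mu_used}, \code{init},
#'   \code{equilibrium_e}, \code{equilibrium_v}, \code{equilibrium_s},
#'   \code{desperation_rate}, \code{converged}, \code{steps}.
#' @export
hysteresis_sweep <- function(params, rates,
                             inits = c("all_submissive", "all_violent"),
                             seed = 1, protocol = c("fresh", "continuation"),
                             ...) {
  inits <- match.arg(inits, several.ok = TRUE)
  protocol <- match.arg(protocol)
  rates <- sort(rates)
  rows <- list()
  for (j in seq_along(inits)) {
    rate_order <- if (protocol == "continuation" && inits[j] == "all_violent")
      rev(seq_along(rates)) else seq_along(rates)
    carried_by_rank <- NULL
    for (i in rate_order) {
      p <- params_at_rate(params, rates[i])
      run_seed <- (seed * 1000L + i * 10L + j) %% .Machine$integer.max
      pop <- init_population(p, seed = run_seed, init = inits[j])
      if (protocol == "continuation" && !is.null(carried_by_rank)) {
        # inherit strategies by resource rank: the population keeps its
        # behavioural state while the economic conditions shift
        pop$strategies[order(pop$resources)] <- carried_by_rank
      }
      eq <- run_to_equilibrium(pop, p, seed = run_seed + 1L, ...)
      carried_by_rank <-
        eq$population$strategies[order(eq$population$resources)]
      rows[[length(rows) + 1L]] <- data.frame(
        desperation_rate_target = rates[i], mu_used = p$mu, init = inits[j],
        equilibrium_e = eq$final_freqs$e, equilibrium_v = eq$final_freqs$v,
        equilibrium_s = eq$final_freqs$s,
        desperation_rate = eq$desperation_rate,
        converged = eq$converged, steps = eq$steps)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$desperation_rate_target, out$init), ]
  rownames(out) <- NULL
  class(out) <- c("violence_sweep", "data.frame")
  out
}

#' @export
plot.violence_sweep <- function(x, ...) {
  graphics::plot(NULL, xlim = range(x$desperation_rate_target),
                 ylim = c(0, 1), xlab = "desperation rate",
                 ylab = "equilibrium violent fraction", ...)
  for (init in unique(x$init)) {
    sub <- x[x$init == init, ]
    pch <- if (init == "all_violent") 1 else 4  # circles vs crosses
    graphics::points(sub$desperation_rate_target, sub$equilibrium_v, pch = pch)
    graphics::lines(sub$desperation_rate_target, sub$equilibrium_v, lty = 3)
  }
  graphics::legend("bottomright", legend = unique(x$init),
                   pch = ifelse(unique(x$init) == "all_violent", 1, 4),
                   bty = "n")
  invisible(x)
}

#' Short-run drift of the violent fraction (vector field)
#'
#' Over a grid of (desperation rate, initial violent fraction), runs a fixed
#' small number of update steps and records the change in the violent
#' fraction. The sign pattern of the drift maps the basins of attraction of
#' the low- and high-violence equilibria.
#'
#' @param params a [model_params] object.
#' @param rates desperation rates in (0, 1).
#' @param v0_values initial violent fractions in [0, 1] (remainder
#'   submissive; exploiters emerge endogenously at the first update).
#' @param k_steps number of update steps per arrow (default 10).
#' @param seed integer seed.
#' @return An object of class \code{violence_vector_field}: data.frame with
#'   columns \code{desperation_rate}, \code{v_initial}, \code{v_final},
#'   \code{delta_v}.
#' @export
vector_field <- function(params, rates, v0_values, k_steps = 10, seed = 1) {
  stopifnot(length(rates) > 0, length(v0_values) > 0, k_steps >= 1)
  rows <- list()
  for (i in seq_along(rates)) for (j in seq_along(v0_values)) {
    p <- params_at_rate(params, rates[i])
    run_seed <- (seed * 1000L + i * 40L + j) %% .Machine$integer.max
    pop <- init_population(p, seed = run_seed, init = v0_values[j])
    v0 <- measure(pop, p)$freqs$v
    rng <- local_rng(run_seed + 1L)
    cache <- new.env(parent = emptyenv())
    for (k in seq_len(k_steps)) pop <- update_step(pop, p, cache = cache)
    rng$restore()
    v1 <- measure(pop, p)$freqs$v
    rows[[length(rows) + 1L]] <- data.frame(
      desperation_rate = rates[i], v_initial = v0, v_final = v1,
      delta_v = v1 - v0)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("violence_vector_field", "data.frame")
  out
}

#' @export
plot.violence_vector_field <- function(x, scale = 1, ...) {
  graphics::plot(NULL, xlim = range(x$desperation_rate), ylim = c(0, 1),
                 xlab = "desperation rate", ylab = "violent fraction", ...)
  ok <- abs(x$delta_v) > 1e-9
  graphics::arrows(x$desperation_rate[ok], x$v_initial[ok],
                   x$desperation_rate[ok], x$v_initial[ok] + scale * x$delta_v[ok],
                   length = 0.05)
  graphics::points(x$desperation_rate[!ok], x$v_initial[!ok], pch = 16, cex = 0.4)
  invisible(x)
}

#' Incentive for violence as a function of its prevalence
#'
#' Mean fitness advantage of the violent over the submissive strategy at a
#' fixed desperation rate, as the prevalence of violence varies. For each
#' \code{v}, the exploiter fraction is pinned to the desperation rate
#' (below-threshold agents exploit at equilibrium), the first-period
#' strategy is forced to violent or to submissive with optimal play
#' afterwards, and the fitness difference is averaged over the stationary
#' Gaussian resource distribution. The curve first falls with \code{v}
#' (hawk-dove-style fight costs) and then rises steeply as \code{v} nears
#' its maximum, when the rare submissive agents concentrate all
#' exploitation: the frequency-dependence reversal that creates
#' bistability.
#'
#' @param params a [model_params] object.
#' @param rate desperation rate fixing \code{mu} and the exploiter
#'   fraction.
#' @param v_values violent fractions, each in \code{[0, 1 - rate]}.
#' @return An object of class \code{violence_incentive}: data.frame with
#'   columns \code{v} and \code{incentive} (mean fitness difference,
#'   violent minus submissive).
#' @export
violence_incentive_curve <- function(params, rate, v_values) {
  p <- params_at_rate(params, rate)
  e <- rate
  if (any(v_values < 0) || any(v_values > 1 - e + 1e-12))
    stop("v_values must lie in [0, 1 - rate]")
  grid <- resource_grid(p)
  # stationary Gaussian weights on the grid (midpoint bins)
  n <- length(grid)
  edges <- c(-Inf, (grid[-n] + grid[-1L]) / 2, Inf)
  wts <- diff(stats::pnorm(edges, p$mu, p$sigma))
  rows <- lapply(v_values, function(v) {
    fr <- strategy_freqs(e, min(v, 1 - e))
    d <- pinned_value_difference(fr, p, grid)
    data.frame(v = v, incentive = sum(wts * d))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("violence_incentive", "data.frame")
  out
}

# V0(first period violent) - V0(first period submissive), optimal play after
pinned_value_difference <- function(freqs, params, grid = resource_grid(params)) {
  ops <- lapply(STRATEGIES, strategy_operator,
                freqs = freqs, params = params, grid = grid)
  names(ops) <- STRATEGIES
  pen <- ifelse(grid < params$threshold, 1 - params$omega, 1)
  V <- pmax(grid, 0)
  for (t in seq_len(params$T_horizon - 1L))
    V <- pen * pmax(ops$submissive %*% V, ops$violent %*% V, ops$exploit %*% V)
  as.numeric(pen * (ops$violent %*% V) - pen * (ops$submissive %*% V))
}

#' @export
plot.violence_incentive <- function(x, ...) {
  graphics::plot(x$v, x$incentive, type = "b", pch = 16,
                 xlab = "prevalence of violence",
                 ylab = "incentive for violence (fitness difference)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Policy-map figure driver
#'
#' Computes [policy_map] over panels of exploitation prevalence and
#' optionally writes the tidy table (CSV) and a figure (PNG) to disk.
#'
#' @param params a [model_params] object.
#' @param e_panels exploiter fractions, one panel each.
#' @param v_grid violent fractions.
#' @param csv,png optional output file paths.
#' @return The \code{violence_policy_map}, invisibly when written to disk.
#' @export
policy_figure <- function(params, e_panels, v_grid, csv = NULL, png = NULL) {
  if (length(v_grid) == 0 || length(e_panels) == 0)
    stop("e_panels and v_grid must be non-empty")
  pm <- policy_map(params, e_panels, v_grid)
  if (!is.null(csv)) utils::write.csv(pm, csv, row.names = FALSE)
  if (!is.null(png)) {
    grDevices::png(png, width = 480 * length(e_panels), height = 480)
    on.exit(grDevices::dev.off())
    plot(pm)
  }
  if (is.null(csv) && is.null(png)) pm else invisible(pm)
}
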