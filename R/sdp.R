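#' Resource grid
#'
#' Evenly spaced discretization of the resource state used by the
#' backward-induction solver. The grid spans \code{[grid_lo, grid_hi]} with
#' \code{grid_n} points; by construction of [model_params] it brackets the
#' desperation threshold and covers at least \code{mu +/- 4 sigma}.
#'
#' @param params a [model_params] object.
#' @return Numeric vector of strictly increasing grid points.
#' @export
resource_grid <- function(params) {
  stopifnot(inherits(params, "violence_params"))
  seq(params$grid_lo, params$grid_hi, length.out = params$grid_n)
}

# index of nearest grid point for each x (grid is sorted, evenly spaced)
nearest_index <- function(grid, x) {
  mids <- (grid[-length(grid)] + grid[-1L]) / 2
  findInterval(x, mids) + 1L
}

#' AR(1) resource transition, discretized
#'
#' One period of the resource process: from level \eqn{x}, next-period
#' resources are \eqn{\mu + r (x - \mu) + \epsilon} with Gaussian
#' innovation of standard deviation \eqn{\sigma\sqrt{1-r^2}}, so that
#' \eqn{N(\mu, \sigma^2)} is the stationary distribution. Probability mass
#' is binned onto the resource grid (midpoint bins, tails absorbed into the
#' end bins), keeping the dynamic program an exact Markov chain on the grid.
#'
#' @param x numeric vector of current resource levels (need not lie on the
#'   grid: action outcomes are applied before the shock).
#' @param params a [model_params] object.
#' @param grid optional precomputed [resource_grid].
#' @return A \code{length(x) x grid_n} matrix of transition probabilities;
#'   each row sums to one.
#' @examples
#' p <- model_params(grid_n = 51)
#' rowSums(ar1_transition(c(0, 25), p))
#' @export
ar1_transition <- function(x, params, grid = resource_grid(params)) {
  stopifnot(all(is.finite(x)))
  mu <- params$mu
  sd_inn <- params$sigma * sqrt(1 - params$r^2)
  means <- mu + params$r * (x - mu)
  n <- length(grid)
  edges <- c(-Inf, (grid[-n] + grid[-1L]) / 2, Inf)
  # cdf at every interior edge for every mean; outer columns are 0 / 1
  P <- vapply(edges, function(ed) stats::pnorm(ed, mean = means, sd = sd_inn),
              numeric(length(means)))
  P <- matrix(P, nrow = length(means))
  M <- P[, -1L, drop = FALSE] - P[, -(n + 1L), drop = FALSE]
  M
}

# one-period expected-value operator for a strategy: matrix M such that
# (M %*% V_next)[i] = E[ (1-lam)^fights * V_next(x_i + delta + shock) ]
strategy_operator <- function(strategy, freqs, params, grid) {
  dist <- round_outcome_distribution(strategy, freqs, params)
  w <- dist$prob * (1 - params$lam)^dist$fights_lost
  # outcomes sharing a delta share a transition matrix
  agg <- rowsum(w, dist$delta)
  deltas <- as.numeric(rownames(agg))
  M <- 0
  for (k in seq_along(deltas))
    M <- M + agg[k, 1L] * ar1_transition(grid + deltas[k], params, grid)
  M
}

#' Solve the individual decision problem by backward induction
#'
#' Computes expected fitness and the optimal strategy on the resource grid,
#' for a fixed population composition. Fitness is the resource level
#' attained after \code{T_horizon} periods, floored at zero, discounted
#' multiplicatively by \code{(1 - omega)} for every period started below the
#' desperation threshold and by \code{(1 - lam)} for every lost fight:
#' \deqn{V_T(x) = \max(x, 0)}
#' \deqn{V_t(x) = pen(x) \max_a \sum_o p^a_o (1-\lambda)^{f_o}
#'       E[V_{t+1}(x + \delta^a_o + \epsilon)]}
#' with \eqn{pen(x) = 1-\omega} below the threshold and 1 above, and the
#' expectation taken over the AR(1) shock. Exact ties between strategies are
#' broken towards the less risky one (submissive over violent over exploit),
#' which makes the degenerate \eqn{\omega = \lambda = 0} case deterministic.
#'
#' @param freqs a [strategy_freqs] object (the social environment).
#' @param params a [model_params] object.
#' @return An object of class \code{violence_policy}: list with \code{grid},
#'   \code{value} (expected fitness at t = 0 on the grid), \code{policy}
#'   (factor of optimal strategies at t = 0), \code{freqs}, \code{params}.
#' @examples
#' pol <- solve_policy(strategy_freqs(e = 0.05, v = 0.2), model_params(grid_n = 101))
#' pol
#' @export
solve_policy <- function(freqs, params) {
  stopifnot(inherits(freqs, "strategy_freqs"), inherits(params, "violence_params"))
  grid <- resource_grid(params)
  ops <- lapply(STRATEGIES, strategy_operator,
                freqs = freqs, params = params, grid = grid)
  names(ops) <- STRATEGIES
  pen <- ifelse(grid < params$threshold, 1 - params$omega, 1)
  V <- pmax(grid, 0)
  EV <- matrix(0, nrow = length(grid), ncol = length(STRATEGIES),
               dimnames = list(NULL, STRATEGIES))
  for (t in seq_len(params$T_horizon)) {
    for (a in STRATEGIES) EV[, a] <- ops[[a]] %*% V
    V <- pen * do.call(pmax, as.data.frame(EV))
    if (any(!is.finite(V)))
      stop("backward induction produced non-finite values at t = ",
           params$T_horizon - t)
  }
  # argmax at t = 0; STRATEGIES is ordered least-risky-first and the first
  # within-tolerance maximiser wins, so ties resolve to the least risky
  # strategy. The tolerance absorbs the probability-binning ripple (relative
  # error ~1e-7 per period), which would otherwise break exact strategic
  # ties pseudo-randomly; genuine payoff differences are orders larger.
  pol_idx <- apply(EV, 1L, function(row)
    which(row >= max(row) - 1e-5 * max(1, abs(max(row))))[1L])
  structure(list(grid = grid, value = V,
                 policy = factor(STRATEGIES[pol_idx], levels = STRATEGIES),
                 strategy_values = EV, freqs = freqs, params = params),
            class = "violence_policy")
}

#' @export
print.violence_policy <- function(x, ...) {
  cat(sprintf("Optimal-strategy policy (T = %d, %d grid points) at e = %.4f, v = %.4f\n",
              as.integer(x$params$T_horizon), length(x$grid), x$freqs$e, x$freqs$v))
  tab <- table(x$policy)
  cat("  policy composition:",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  if (any(x$policy == "exploit")) {
    reg <- range(x$grid[x$policy == "exploit"])
    cat(sprintf("  exploit region: [%.2f, %.2f]\n", reg[1], reg[2]))
  }
  invisible(x)
}

#' @export
plot.violence_policy <- function(x, ...) {
  cols <- c(submissive = "#4477AA", violent = "#EE6677", exploit = "#222222")
  graphics::plot(x$grid, x$value, type = "l", xlab = "resources",
                 ylab = "expected fitness", ...)
  graphics::points(x$grid, x$value, col = cols[as.character(x$policy)],
                   pch = 16, cex = 0.5)
  graphics::abline(v = x$params$threshold, lty = 2)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Optimal strategy at a resource level
#'
#' Nearest-grid-point lookup into the time-zero policy of [solve_policy].
#' Levels outside the grid are clipped to its ends with a warning.
#'
#' @param x numeric vector of resource levels.
#' @param freqs a [strategy_freqs] object, or a precomputed
#'   \code{violence_policy} (avoids re-solving).
#' @param params a [model_params] object (ignored when \code{freqs} is a
#'   policy).
#' @return Character vector of strategy labels.
#' @export
optimal_strategy <- function(x, freqs, params) {
  pol <- if (inherits(freqs, "violence_policy")) freqs
         else solve_policy(freqs, params)
  rng <- range(pol$grid)
  if (any(x < rng[1] | x > rng[2])) {
    warning("resource levels outside the grid were clipped to its range")
    x <- pmin(pmax(x, rng[1]), rng[2])
  }
  as.character(pol$policy[nearest_index(pol$grid, x)])
}

#' Policy map over population compositions
#'
#' Tabulates the time-zero optimal strategy over the resource grid for every
#' combination of exploitation prevalence (panels) and violence prevalence,
#' the model's analogue of a phase diagram of individual decisions.
#'
#' @param params a [model_params] object.
#' @param e_values numeric vector of exploiter fractions (one per panel).
#' @param v_grid numeric vector of violent fractions.
#' @return An object of class \code{violence_policy_map}: a data.frame with
#'   columns \code{x}, \code{e}, \code{v}, \code{strategy}, one row per
#'   combination.
#' @examples
#' pm <- policy_map(model_params(grid_n = 61, T_horizon = 20),
#'                  e_values = 0.05, v_grid = c(0, 0.5, 0.99))
#' head(pm)
#' @export
policy_map <- function(params, e_values, v_grid) {
  if (length(e_values) == 0 || length(v_grid) == 0)
    stop("e_values and v_grid must be non-empty")
  if (any(e_values < 0) || any(v_grid < 0) || any(e_values + max(v_grid) > 1 + 1e-12))
    stop("e_values and v_grid must be admissible frequencies (e + v <= 1)")
  grid <- resource_grid(params)
  rows <- list()
  for (e in e_values) for (v in v_grid) {
    pol <- solve_policy(strategy_freqs(e, v), params)
    rows[[length(rows) + 1L]] <- data.frame(
      x = grid, e = e, v = v, strategy = as.character(pol$policy))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("violence_policy_map", "data.frame")
  out
}

#' @export
plot.violence_policy_map <- function(x, ...) {
  cols <- c(submissive = "#4477AA", violent = "#EE6677", exploit = "#222222")
  panels <- sort(unique(x$e))
  op <- graphics::par(mfrow = c(1, length(panels)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (e in panels) {
    sub <- x[x$e == e, ]
    xs <- sort(unique(sub$x)); vs <- sort(unique(sub$v))
    z <- matrix(match(sub$strategy, names(cols)),
                nrow = length(xs), ncol = length(vs))
    graphics::image(xs, vs, z, col = cols, zlim = c(1, 3),
                    xlab = "resources", ylab = "prevalence of violence",
                    main = sprintf("e = %g", e), ...)
    graphics::abline(v = 0, lty = 2, col = "white")
  }
  invisible(x)
}
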