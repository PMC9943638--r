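#' Initialize an agent population
#'
#' Draws agent resources from the stationary Gaussian resource distribution
#' \eqn{N(\mu, \sigma^2)} and assigns initial strategies.
#'
#' @param params a [model_params] object (\code{N_pop}, \code{mu},
#'   \code{sigma} are used).
#' @param seed integer RNG seed; identical seeds give identical populations.
#' @param init initial strategy configuration: \code{"all_submissive"},
#'   \code{"all_violent"}, or a single numeric in [0, 1] giving the fraction
#'   of (randomly chosen) violent agents, the remainder submissive.
#' @return An object of class \code{violence_population}: list with
#'   \code{resources}, \code{strategies} (character vector) and \code{seed}.
#' @examples
#' pop <- init_population(model_params(N_pop = 1000), seed = 1)
#' measure(pop, model_params(N_pop = 1000))
#' @export
init_population <- function(params, seed, init = "all_submissive") {
  stopifnot(inherits(params, "violence_params"))
  n <- as.integer(params$N_pop)
  rng <- local_rng(seed)
  resources <- stats::rnorm(n, params$mu, params$sigma)
  if (is.numeric(init)) {
    if (length(init) != 1 || init < 0 || init > 1)
      stop("numeric 'init' must be a single fraction in [0, 1]")
    strategies <- rep("submissive", n)
    k <- round(init * n)
    if (k > 0) strategies[sample.int(n, k)] <- "violent"
  } else {
    init <- match.arg(init, c("all_submissive", "all_violent"))
    strategies <- rep(if (init == "all_violent") "violent" else "submissive", n)
  }
  rng$restore()
  structure(list(resources = resources, strategies = strategies, seed = seed),
            class = "violence_population")
}

# scoped RNG: set seed, return a restorer for the caller's RNG state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  list(restore = function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
}

#' @export
print.violence_population <- function(x, ...) {
  m <- measure(x)
  cat(sprintf("population of %d agents (seed %s)\n", length(x$resources),
              format(x$seed)))
  cat(sprintf("  exploit %.4f, violent %.4f, submissive %.4f; desperation rate %.4f\n",
              m$freqs$e, m$freqs$v, m$freqs$s, m$desperation_rate))
  invisible(x)
}

#' Measure strategy frequencies and the desperation rate
#'
#' @param pop a \code{violence_population}.
#' @param params a [model_params] object; only the threshold is used
#'   (defaults to threshold 0 if omitted).
#' @return List with \code{freqs} (a [strategy_freqs]) and
#'   \code{desperation_rate}, the fraction of agents with resources below
#'   the threshold.
#' @export
measure <- function(pop, params = NULL) {
  stopifnot(inherits(pop, "violence_population"))
  thr <- if (is.null(params)) 0 else params$threshold
  n <- length(pop$resources)
  e <- sum(pop$strategies == "exploit") / n
  v <- sum(pop$strategies == "violent") / n
  s <- sum(pop$strategies == "submissive") / n
  list(freqs = strategy_freqs(e, v, s),
       desperation_rate = mean(pop$resources < thr))
}

#' One asynchronous strategy-update step
#'
#' A randomly chosen fraction of agents replaces its strategy with the
#' optimal strategy for its own resource level, given the strategy
#' frequencies measured at the start of the step (agents are assumed to
#' know the current composition of the population exactly). Resources are
#' held fixed, so the desperation rate is an exogenous constant of the run.
#'
#' @param pop a \code{violence_population}.
#' @param params a [model_params] object.
#' @param fraction fraction of agents updated per step (default 0.1).
#' @param cache optional environment caching solved policies by frequency;
#'   pass the same environment across steps to avoid re-solving at a fixed
#'   point.
#' @return The updated \code{violence_population}.
#' @export
update_step <- function(pop, params, fraction = 0.1, cache = NULL) {
  stopifnot(inherits(pop, "violence_population"),
            fraction > 0, fraction <= 1)
  freqs <- measure(pop, params)$freqs
  pol <- cached_policy(freqs, params, cache)
  n <- length(pop$resources)
  k <- max(1L, round(fraction * n))
  idx <- sample.int(n, k)
  pop$strategies[idx] <- optimal_strategy(pop$resources[idx], pol)
  pop
}

cached_policy <- function(freqs, params, cache = NULL) {
  if (is.null(cache)) return(solve_policy(freqs, params))
  key <- sprintf("%.17g_%.17g", freqs$e, freqs$v)
  if (is.null(cache[[key]])) cache[[key]] <- solve_policy(freqs, params)
  cache[[key]]
}

#' Iterate strategy updating to equilibrium
#'
#' Repeats [update_step] until the strategy composition stabilizes: the run
#' is declared converged when the ranges of both the exploiter and the
#' violent fraction over the trailing \code{window} steps fall below
#' \code{tol}. Non-convergence within \code{max_steps} is reported through
#' the \code{converged} flag, not an error.
#'
#' @param pop a \code{violence_population} (see [init_population]).
#' @param params a [model_params] object.
#' @param fraction fraction of agents updated per step.
#' @param tol absolute stability tolerance on \code{e} and \code{v}.
#' @param window number of trailing steps over which stability is required.
#' @param max_steps iteration cap.
#' @param seed optional integer seed controlling the update draws (so a run
#'   is reproducible independently of the caller's RNG state).
#' @return An object of class \code{violence_equilibrium}: list with
#'   \code{final_freqs}, \code{desperation_rate}, \code{trajectory} (a
#'   data.frame step/e/v/s/desperation_rate), \code{converged},
#'   \code{steps}, and the final \code{population}.
#' @examples
#' p <- model_params(N_pop = 500, grid_n = 61, T_horizon = 10)
#' pop <- init_population(p, seed = 1)
#' eq <- run_to_equilibrium(pop, p, max_steps = 30, seed = 2)
#' eq
#' @export
run_to_equilibrium <- function(pop, params, fraction = 0.1, tol = 1e-3,
                               window = 50, max_steps = 2000, seed = NULL) {
  stopifnot(inherits(pop, "violence_population"))
  rng <- if (!is.null(seed)) local_rng(seed) else NULL
  cache <- new.env(parent = emptyenv())
  m0 <- measure(pop, params)
  traj <- matrix(NA_real_, nrow = max_steps + 1L, ncol = 4L,
                 dimnames = list(NULL, c("e", "v", "s", "desperation_rate")))
  traj[1L, ] <- c(m0$freqs$e, m0$freqs$v, m0$freqs$s, m0$desperation_rate)
  converged <- is.infinite(tol)
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    pop <- update_step(pop, params, fraction, cache)
    m <- measure(pop, params)
    traj[step + 1L, ] <- c(m$freqs$e, m$freqs$v, m$freqs$s, m$desperation_rate)
    if (step + 1L >= window) {
      win <- traj[(step + 2L - window):(step + 1L), , drop = FALSE]
      if (diff(range(win[, "e"])) < tol && diff(range(win[, "v"])) < tol) {
        converged <- TRUE
        break
      }
    }
    if (is.infinite(tol)) { converged <- TRUE; break }
  }
  if (!is.null(rng)) rng$restore()
  traj <- as.data.frame(traj[seq_len(step + 1L), , drop = FALSE])
  traj <- cbind(step = 0:step, traj)
  m <- measure(pop, params)
  structure(list(final_freqs = m$freqs,
                 desperation_rate = m$desperation_rate,
                 trajectory = traj, converged = converged, steps = step,
                 population = pop, params = params),
            class = "violence_equilibrium")
}

#' @export
print.violence_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium after %d steps (%s)\n", x$steps,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  exploit %.4f, violent %.4f, submissive %.4f\n",
              x$final_freqs$e, x$final_freqs$v, x$final_freqs$s))
  cat(sprintf("  desperation rate %.4f\n", x$desperation_rate))
  invisible(x)
}

#' @export
summary.violence_equilibrium <- function(object, ...) {
  print(object)
  cat("trajectory tail:\n")
  print(utils::tail(object$trajectory, 5L), row.names = FALSE)
  invisible(object)
}

#' @export
plot.violence_equilibrium <- function(x, ...) {
  tr <- x$trajectory
  graphics::matplot(tr$step, tr[, c("e", "v", "s")], type = "l", lty = 1,
                    col = c("#222222", "#EE6677", "#4477AA"),
                    xlab = "update step", ylab = "strategy frequency",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = c("exploit", "violent", "submissive"),
                   col = c("#222222", "#EE6677", "#4477AA"), lty = 1, bty = "n")
  invisible(x)
}
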