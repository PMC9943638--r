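# small parameter sets used across the suite; coarse grids and short
# horizons keep the dynamic program cheap without changing its structure
toy_params <- function(...) {
  args <- list(...)
  defaults <- list(mu = 25, sigma = 10, N_pop = 1000, grid_n = 101,
                   T_horizon = 20)
  do.call(model_params, utils::modifyList(defaults, args))
}

# agent-level Monte-Carlo of the target-sampling scheme: each exploiter
# draws n candidates (with replacement) and attacks a random non-violent
# candidate if there is one, else a random violent candidate; returns
# expected attacks per agent per round for the unprotected (submissive or
# exploiting) and the violent class, with standard errors
mc_victimization <- function(e, v, n_targets, N = 2000, rounds = 400,
                             seed = 42) {
  set.seed(seed)
  n_e <- round(e * N); n_v <- round(v * N)
  violent <- c(rep(FALSE, n_e), rep(TRUE, n_v), rep(FALSE, N - n_e - n_v))
  hits_unprot <- numeric(rounds); hits_viol <- numeric(rounds)
  n_unprot <- N - n_v
  for (r in seq_len(rounds)) {
    h_u <- 0L; h_v <- 0L
    if (n_e > 0) {
      cand <- matrix(sample.int(N, n_e * n_targets, replace = TRUE),
                     nrow = n_e)
      for (i in seq_len(n_e)) {
        cv <- violent[cand[i, ]]
        if (all(cv)) h_v <- h_v + 1L else h_u <- h_u + 1L
      }
    }
    hits_unprot[r] <- if (n_unprot > 0) h_u / n_unprot else 0
    hits_viol[r] <- if (n_v > 0) h_v / n_v else 0
  }
  list(rate_unprotected = mean(hits_unprot),
       se_unprotected = stats::sd(hits_unprot) / sqrt(rounds),
       rate_violent = mean(hits_viol),
       se_violent = stats::sd(hits_viol) / sqrt(rounds))
}

# expected value of a fixed Markov policy by backward evaluation with no
# maximization; taking the pointwise max over all enumerated policies gives
# an oracle for the dynamic program on tiny instances
evaluate_fixed_policy <- function(policy_matrix, freqs, params) {
  grid <- resource_grid(params)
  n <- length(grid)
  stopifnot(nrow(policy_matrix) == params$T_horizon, ncol(policy_matrix) == n)
  dists <- lapply(STRATS, function(a)
    round_outcome_distribution(a, freqs, params))
  names(dists) <- STRATS
  pen <- ifelse(grid < params$threshold, 1 - params$omega, 1)
  V <- pmax(grid, 0)
  for (t in params$T_horizon:1) {
    Vnew <- numeric(n)
    for (i in seq_len(n)) {
      d <- dists[[policy_matrix[t, i]]]
      acc <- 0
      for (o in seq_len(nrow(d))) {
        trans <- ar1_transition(grid[i] + d$delta[o], params, grid)
        acc <- acc + d$prob[o] * (1 - params$lam)^d$fights_lost[o] *
          sum(trans * V)
      }
      Vnew[i] <- pen[i] * acc
    }
    V <- Vnew
  }
  V
}

oracle_dp_value <- function(freqs, params) {
  grid <- resource_grid(params)
  n <- length(grid)
  Tn <- params$T_horizon
  cells <- Tn * n
  combos <- expand.grid(rep(list(seq_along(STRATS)), cells))
  best <- rep(-Inf, n)
  for (k in seq_len(nrow(combos))) {
    pm <- matrix(STRATS[as.integer(combos[k, ])], nrow = Tn, ncol = n)
    best <- pmax(best, evaluate_fixed_policy(pm, freqs, params))
  }
  best
}

STRATS <- c("submissive", "violent", "exploit")
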