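test_that("mean-field victimization rates match their closed forms and limits", {
  # n = 1: the toughness signal is inert and every class is victimized at
  # the exploiter rate
  r <- victimization_rates(strategy_freqs(0.1, 0.3), n_targets = 1)
  expect_equal(r$rate_submissive, 0.1, tolerance = 1e-12)
  expect_equal(r$rate_tough, 0.1, tolerance = 1e-12)

  # no exploiters, no attacks
  expect_equal(victimization_rates(strategy_freqs(0, 0.5), 10),
               list(rate_submissive = 0, rate_tough = 0))

  # n large: violent agents are effectively never victimized while any
  # unprotected agent remains
  r50 <- victimization_rates(strategy_freqs(0.02, 0.5), n_targets = 50)
  expect_equal(r50$rate_tough, 0.02 * 0.5^49, tolerance = 1e-12)
  expect_lt(r50$rate_tough, 1e-15)
  expect_equal(r50$rate_submissive, 0.02 * (1 - 0.5^50) / 0.5, tolerance = 1e-12)

  # v -> 1 limit: the last unprotected agents absorb e * n attacks
  rlim <- victimization_rates(strategy_freqs(0.02, 0.98, 0), n_targets = 4)
  expect_equal(rlim$rate_submissive, 0.02 * (1 - 0.98^4) / 0.02, tolerance = 1e-9)
  rdeg <- victimization_rates(strategy_freqs(1e-13, 1 - 1e-13, 0), n_targets = 7)
  expect_true(is.finite(rdeg$rate_submissive))
})

test_that("victimization rates conserve attacks and are monotone in n", {
  set.seed(42)
  for (k in 1:30) {
    f <- as.numeric(stats::rmultinom(1, 1000, runif(3))) / 1000
    fr <- strategy_freqs(f[1], f[2], f[3])
    n <- sample(1:60, 1)
    r <- victimization_rates(fr, n)
    # every exploiter makes exactly one attempt per round
    expect_equal((fr$s + fr$e) * r$rate_submissive + fr$v * r$rate_tough,
                 fr$e, tolerance = 1e-12)
    # equal rates when the signal is inert
    r1 <- victimization_rates(fr, 1)
    expect_equal(r1$rate_submissive, r1$rate_tough, tolerance = 1e-12)
  }
  # deflection strengthens with the candidate-sample size
  fr <- strategy_freqs(0.05, 0.4)
  rates_t <- sapply(1:20, function(n) victimization_rates(fr, n)$rate_tough)
  rates_s <- sapply(1:20, function(n) victimization_rates(fr, n)$rate_submissive)
  expect_true(all(diff(rates_t) <= 1e-12))
  expect_true(all(diff(rates_s) >= -1e-12))
})

test_that("mean-field rates agree with an agent-level Monte-Carlo oracle", {
  set.seed(7)
  for (k in 1:8) {
    e <- runif(1, 0.02, 0.3); v <- runif(1, 0.1, min(0.85, 1 - e - 0.05))
    n <- sample(c(1, 2, 5, 10), 1)
    e_eff <- round(e * 2000) / 2000; v_eff <- round(v * 2000) / 2000
    mc <- mc_victimization(e, v, n, N = 2000, rounds = 200, seed = 100 + k)
    an <- victimization_rates(strategy_freqs(e_eff, v_eff), n)
    expect_lt(abs(mc$rate_unprotected - an$rate_submissive),
              3 * mc$se_unprotected + 1e-3)
    expect_lt(abs(mc$rate_violent - an$rate_tough),
              3 * mc$se_violent + 1e-3)
  }
})

test_that("round outcome distributions are exact, exhaustive probability models", {
  p <- model_params()

  # nothing can happen to a submissive agent in a peaceful population
  d0 <- round_outcome_distribution("submissive", strategy_freqs(0, 0, 1), p)
  expect_equal(d0, data.frame(prob = 1, delta = 0, fights_lost = 0))

  # exploiting an all-submissive population: default stakes, sanction
  # forfeits the loot
  de <- round_outcome_distribution("exploit", strategy_freqs(0, 0, 1), p)
  expect_equal(de$prob, c(1/3, 2/3), tolerance = 1e-12)
  expect_equal(de$delta, c(-20, 10))
  expect_equal(de$fights_lost, c(0, 0))

  # a violent agent with no mistakes: victimization mass is split by the
  # coin toss, with the Poisson-thinned attack probability 1 - exp(-0.1)
  pv <- model_params(m = 0)
  dv <- round_outcome_distribution("violent", strategy_freqs(0.1, 0.3), pv)
  p_att <- 1 - exp(-victimization_rates(strategy_freqs(0.1, 0.3), 50)$rate_tough)
  expect_equal(dv$prob[dv$delta == -10], p_att / 2, tolerance = 1e-12)
  expect_equal(dv$fights_lost[dv$delta == -10], 1)
  expect_equal(sum(dv$prob[dv$delta == 0]), 1 - p_att / 2, tolerance = 1e-12)

  # probability conservation across random compositions and strategies
  set.seed(11)
  for (k in 1:20) {
    f <- as.numeric(stats::rmultinom(1, 100, runif(3))) / 100
    fr <- strategy_freqs(f[1], f[2], f[3])
    for (strat in c("submissive", "violent", "exploit")) {
      d <- round_outcome_distribution(strat, fr, p)
      expect_equal(sum(d$prob), 1, tolerance = 1e-12)
      expect_true(all(d$fights_lost >= 0))
      expect_true(all(d$prob > 0))
    }
  }
  expect_error(round_outcome_distribution("flee", strategy_freqs(0, 0, 1), p))
})

test_that("exploitation is never profitable in expectation at the default stakes", {
  p <- model_params()
  # exact equality against an undefended population at the default-stakes boundary
  expect_equal(expected_exploitation_payoff(p, strategy_freqs(0, 0, 1)), 0,
               tolerance = 1e-12)
  # fighting for every theft halves the success rate: strictly negative
  expect_equal(expected_exploitation_payoff(p, strategy_freqs(0, 1, 0)),
               (1/2) * (2/3) * 10 - (1/3) * 20, tolerance = 1e-12)
  expect_lt(expected_exploitation_payoff(p, strategy_freqs(0, 1, 0)), 0)
  # no stake, no possible gain
  p0 <- model_params(beta = 0)
  expect_lte(expected_exploitation_payoff(p0, strategy_freqs(0.2, 0.3)), 0)
  # non-positive across random compositions
  set.seed(3)
  for (k in 1:25) {
    f <- as.numeric(stats::rmultinom(1, 100, runif(3))) / 100
    fr <- strategy_freqs(f[1], f[2], f[3])
    expect_lte(expected_exploitation_payoff(p, fr), 1e-12)
  }
})
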