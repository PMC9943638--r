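test_that("AR(1) transition has the right moments and stationary behaviour", {
  p <- toy_params(mu = 25, sigma = 10, r = 0.99, grid_n = 601,
                  grid_lo = -80, grid_hi = 130)
  g <- resource_grid(p)
  M <- ar1_transition(c(35, 0), p, g)
  expect_equal(rowSums(M), c(1, 1), tolerance = 1e-12)
  # E[next | x = mu + 10] = mu + r * 10;  sd = sigma * sqrt(1 - r^2)
  mean1 <- sum(M[1, ] * g)
  sd1 <- sqrt(sum(M[1, ] * g^2) - mean1^2)
  expect_equal(mean1, 25 + 0.99 * 10, tolerance = 1e-3)
  expect_equal(sd1, 10 * sqrt(1 - 0.99^2), tolerance = 1e-2)

  # r = 0: next-period distribution is the stationary Gaussian regardless of x
  p0 <- toy_params(r = 0, grid_n = 301)
  g0 <- resource_grid(p0)
  M0 <- ar1_transition(c(-20, 25, 60), p0, g0)
  expect_equal(M0[1, ], M0[2, ], tolerance = 1e-12)
  expect_equal(M0[2, ], M0[3, ], tolerance = 1e-12)
  expect_equal(sum(M0[1, ] * g0), 25, tolerance = 1e-6)

  # r -> 1: mass concentrates at the current level
  p1 <- toy_params(r = 0.999999, grid_n = 301)
  g1 <- resource_grid(p1)
  M1 <- ar1_transition(10, p1, g1)
  expect_equal(sum(M1 * g1), 10, tolerance = 0.5)
})

test_that("backward induction matches exhaustive policy enumeration on a toy", {
  # 3-point grid, 2 periods: all 3^(2*3) = 729 Markov policies are evaluated
  # without any maximization, and their pointwise-best value must equal the
  # dynamic program exactly
  p <- model_params(mu = 5, sigma = 4, r = 0.5, n_targets = 2,
                    T_horizon = 2, grid_lo = -6, grid_hi = 14, grid_n = 3,
                    m = 0.1, omega = 0.2, lam = 0.2)
  freqs <- strategy_freqs(e = 0.2, v = 0.3)
  dp <- solve_policy(freqs, p)
  oracle <- oracle_dp_value(freqs, p)
  expect_equal(dp$value, oracle, tolerance = 1e-12)

  # and on a second parameter point with different penalties
  p2 <- model_params(mu = 2, sigma = 5, r = 0.9, n_targets = 3,
                     T_horizon = 2, grid_lo = -9, grid_hi = 11, grid_n = 3,
                     m = 0.3, omega = 0.05, lam = 0.3)
  freqs2 <- strategy_freqs(e = 0.05, v = 0.6)
  expect_equal(solve_policy(freqs2, p2)$value, oracle_dp_value(freqs2, p2),
               tolerance = 1e-12)
})

test_that("terminal condition and degenerate penalties behave as specified", {
  # T = 1 with everything switched off: value is the expected floored
  # terminal resource level, identical across strategies, and the tie
  # breaks to submissive everywhere
  p <- toy_params(T_horizon = 1, m = 0, omega = 0, lam = 0, grid_n = 61)
  pol <- solve_policy(strategy_freqs(0, 0, 1), p)
  g <- resource_grid(p)
  expected <- sapply(g, function(x) {
    tr <- ar1_transition(x, p, g)
    sum(tr * pmax(g, 0))
  })
  expect_equal(unname(pol$strategy_values[, "submissive"]), expected,
               tolerance = 1e-10)
  expect_true(all(pol$value >= expected - 1e-10))
  # violence offers nothing here and ties break to submission
  expect_equal(unname(pol$strategy_values[, "violent"]),
               unname(pol$strategy_values[, "submissive"]), tolerance = 1e-12)
  expect_true(all(pol$policy != "violent"))
  # far above the threshold the zero-mean stealing lottery is value-neutral
  # and the tie breaks to submission; below the threshold its upside makes
  # the agent risk-prone
  expect_true(all(pol$policy[g > 30] == "submissive"))
  expect_true(all(pol$strategy_values[g < -10, "exploit"] >=
                    pol$strategy_values[g < -10, "submissive"]))
})

test_that("value functions are monotone in resources and in penalties", {
  p <- toy_params(grid_n = 101, T_horizon = 15)
  for (fr in list(strategy_freqs(0.05, 0.2), strategy_freqs(0.2, 0.6),
                  strategy_freqs(0, 0.9), strategy_freqs(0.01, 0))) {
    v <- solve_policy(fr, p)$value
    expect_true(all(diff(v) > -1e-9))
  }
  # higher omega / lam weakly decrease expected fitness pointwise
  fr <- strategy_freqs(0.05, 0.3)
  v_base <- solve_policy(fr, p)$value
  v_om <- solve_policy(fr, toy_params(grid_n = 101, T_horizon = 15,
                                      omega = 0.3))$value
  v_lam <- solve_policy(fr, toy_params(grid_n = 101, T_horizon = 15,
                                       lam = 0.4))$value
  expect_true(all(v_om <= v_base + 1e-9))
  expect_true(all(v_lam <= v_base + 1e-9))
})

test_that("policy lookups and maps are consistent and deterministic", {
  p <- toy_params(grid_n = 81, T_horizon = 10)
  fr <- strategy_freqs(0.05, 0.2)
  pol <- solve_policy(fr, p)
  g <- resource_grid(p)
  # nearest-grid-point lookup agrees with the policy column
  expect_identical(optimal_strategy(g[c(1, 40, 81)], pol),
                   as.character(pol$policy[c(1, 40, 81)]))
  expect_warning(optimal_strategy(min(g) - 50, pol), "clipped")

  pm <- policy_map(p, e_values = c(0.02, 0.2), v_grid = c(0, 0.5, 0.75))
  expect_equal(nrow(pm), 2 * 3 * length(g))
  pm2 <- policy_map(p, e_values = c(0.02, 0.2), v_grid = c(0, 0.5, 0.75))
  expect_identical(pm, pm2)
  # single-point map agrees with optimal_strategy
  pm1 <- policy_map(p, e_values = 0.05, v_grid = 0.2)
  expect_identical(pm1$strategy[pm1$x == g[40]],
                   optimal_strategy(g[40], fr, p))
  expect_error(policy_map(p, e_values = numeric(0), v_grid = 0.1), "non-empty|admissible")
})
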