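test_that("epsilon-greedy selection is greedy, uniform, and tie-symmetric", {
  set.seed(1)
  # pure greedy
  expect_equal(epsilon_greedy(c(0.1, 0.9), 0), 2L)
  expect_error(epsilon_greedy(numeric(0), 0.5), "at least one")
  expect_error(epsilon_greedy(c(1, 2), 1.5), "\\[0,1\\]")

  # epsilon = 1: empirical frequencies uniform within 3-sigma binomial bounds
  n <- 1e5
  draws <- replicate(n, epsilon_greedy(c(0, 0, 0, 1), 1))
  p <- tabulate(draws, 4) / n
  tol <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(p - 0.25) < tol))

  # exact ties split evenly under pure greedy
  ties <- replicate(n / 10, epsilon_greedy(c(0.5, 0.5), 0))
  expect_lt(abs(mean(ties == 1) - 0.5), 3 * sqrt(0.25 / (n / 10)))

  # a numerically broken value landscape falls back to the first action
  expect_equal(epsilon_greedy(c(NaN, NaN), 0), 1L)
  expect_equal(epsilon_greedy(c(NaN, 0.2), 0), 2L)
})

test_that("the epsilon schedule decays geometrically to its floor", {
  p <- agent_params()
  expect_equal(decay_epsilon(1.0, p), 0.99)
  expect_equal(decay_epsilon(0.01, p), 0.01)
  expect_equal(decay_epsilon(0.012, p), 0.01188)

  # iterate the schedule across episodes
  eps <- numeric(600)
  eps[1] <- p$epsilon0
  for (k in 2:600) eps[k] <- decay_epsilon(eps[k - 1], p)
  expect_true(all(diff(eps) <= 0))
  expect_equal(min(eps), 0.01)
  first_floor <- which(eps == p$epsilon_floor)[1]
  # closed form: first k with 0.99^(k-1) <= 0.01
  expect_equal(first_floor, ceiling(log(0.01) / log(0.99)) + 1)
})

test_that("the one-step Q update moves only the taken action's weights", {
  spec <- grid_spec("chain_1d")
  p <- agent_params()
  W <- matrix(0, 2, 20)

  # terminal reward of 1 writes alpha at the visited coordinate
  W1 <- q_update(W, one_hot(19, 20), 2, 1, one_hot(20, 20), p, terminal = TRUE)
  expect_equal(W1[2, 19], 0.1)
  expect_equal(sum(W1 != 0), 1L)

  # zero reward and zero values: no change
  expect_equal(q_update(W, one_hot(3, 20), 1, 0, one_hot(2, 20), p), W)

  # bootstrap from max next value: delta = 0 + gamma * 1 - 0
  W2 <- W
  W2[1, 5] <- 1
  W3 <- q_update(W2, one_hot(4, 20), 2, 0, one_hot(5, 20), p)
  expect_equal(W3[2, 4], 0.1 * 0.95 * 1)
  expect_error(q_update(W, one_hot(3, 10), 1, 0, one_hot(2, 20), p),
               "does not match")
})

test_that("Q(lambda) reduces to Q at lambda 0 and decays credit by gamma*lambda", {
  p0 <- agent_params(lambda = 0)
  W <- matrix(0, 2, 20); E <- matrix(0, 2, 20)
  o <- one_hot(19, 20); on <- one_hot(20, 20)
  upd <- q_lambda_update(W, E, o, 2, 1, on, p0, terminal = TRUE)
  expect_identical(upd$weights, q_update(W, o, 2, 1, on, p0, terminal = TRUE))
  expect_equal(upd$trace, matrix(0, 2, 20)) # gamma*lambda = 0 wipes the trace

  # trace entries decay by (gamma*lambda)^k over k further steps
  p <- agent_params(lambda = 0.8)
  E2 <- matrix(0, 2, 20)
  upd <- q_lambda_update(W, E2, one_hot(3, 20), 1, 0, one_hot(4, 20), p)
  e0 <- upd$trace[1, 3]
  expect_equal(e0, 0.95 * 0.8) # accumulated 1, then decayed once
  tr <- upd$trace
  for (k in 1:3) tr <- q_lambda_update(upd$weights, tr, one_hot(10, 20), 2, 0,
                                       one_hot(11, 20), p)$trace
  expect_equal(tr[1, 3], e0 * (0.95 * 0.8)^3)

  # two-step chain with terminal reward: the state visited two steps before
  # the goal is credited in the same update, proportional to gamma*lambda
  W <- matrix(0, 2, 20); E <- matrix(0, 2, 20)
  s1 <- q_lambda_update(W, E, one_hot(18, 20), 2, 0, one_hot(19, 20), p)
  s2 <- q_lambda_update(s1$weights, s1$trace, one_hot(19, 20), 2, 1,
                        one_hot(20, 20), p, terminal = TRUE)
  expect_equal(s2$weights[2, 19], 0.1)           # delta * e[19] = 1
  expect_equal(s2$weights[2, 18], 0.1 * 0.95 * 0.8) # delta * e[18]
})

test_that("single SF steps match hand-traced updates", {
  p <- agent_params()
  d <- 20
  W <- replicate(2, matrix(0, d, d), simplify = FALSE)
  w_r <- numeric(d)

  # zero init: delta_sf = phi(s), so W_a gains alpha_w at (s, s)
  upd <- sf_step(W, w_r, one_hot(3, d), 2, 0, one_hot(4, d), p)
  expect_equal(upd$W[[2]][3, 3], 0.1)
  expect_equal(sum(upd$W[[2]] != 0), 1L)
  expect_equal(upd$w_r, numeric(d))

  # reward of 1 writes alpha_r at the successor state's coordinate
  upd2 <- sf_step(W, w_r, one_hot(19, d), 2, 1, one_hot(20, d), p,
                  terminal = TRUE)
  expect_equal(upd2$w_r[20], 0.1)
  # terminal target includes the goal's own (discounted) feature
  expect_equal(upd2$W[[2]][20, 19], 0.1 * 0.95)
  expect_equal(upd2$W[[2]][19, 19], 0.1)

  expect_error(sf_step(W, w_r, one_hot(3, 10), 1, 0, one_hot(4, d), p),
               "does not match")
})

test_that("PF reduces to SF at lambda 0 and spreads credit along the trace", {
  d <- 20
  p0 <- agent_params(lambda = 0)
  W <- replicate(2, matrix(0, d, d), simplify = FALSE)
  w_r <- numeric(d)
  tr <- numeric(d)

  a <- pf_step(W, w_r, tr, one_hot(3, d), 2, 0, one_hot(4, d), p0)
  b <- sf_step(W, w_r, one_hot(3, d), 2, 0, one_hot(4, d), p0)
  expect_identical(a$W, b$W)
  expect_identical(a$w_r, b$w_r)
  expect_equal(a$trace, numeric(d))

  # visiting s0 then s1: the update at s1 touches column s0 with weight
  # gamma*lambda relative to column s1
  p <- agent_params(lambda = 0.8)
  st1 <- pf_step(W, w_r, numeric(d), one_hot(3, d), 2, 0, one_hot(4, d), p)
  st2 <- pf_step(st1$W, st1$w_r, st1$trace, one_hot(4, d), 2, 0,
                 one_hot(5, d), p)
  delta_col4 <- st2$W[[2]][, 4] - st1$W[[2]][, 4]
  delta_col3 <- st2$W[[2]][, 3] - st1$W[[2]][, 3]
  expect_equal(delta_col3, 0.95 * 0.8 * delta_col4)

  # trace norm after k unrewarded steps is bounded by the geometric sum
  tr <- numeric(d)
  k <- 12
  for (i in seq_len(k)) {
    st <- pf_step(W, w_r, tr, one_hot(1 + (i %% 5), d), 1, 0,
                  one_hot(2 + (i %% 5), d), p)
    tr <- st$trace
  }
  expect_lte(sum(tr), sum((0.95 * 0.8)^(1:k)))
})

test_that("action values compose weights and observations correctly", {
  spec <- grid_spec("chain_1d")
  p <- agent_params()
  sf <- make_agent("sf", spec, p)
  expect_equal(action_values(sf, one_hot(5, 20)), c(0, 0))

  # W = identity per action, w_r = one_hot(goal): value is o[goal]
  sf$W <- replicate(2, diag(20), simplify = FALSE)
  sf$w_r <- one_hot(20, 20)
  o <- one_hot(12, 20) + 0.1
  expect_equal(action_values(sf, o), rep(o[20], 2))

  q <- make_agent("q", spec, p)
  expect_equal(action_values(q, one_hot(5, 20)), c(0, 0))
  expect_error(action_values(q, numeric(10)), "does not match")
})

test_that("frozen-policy SF learning converges to the analytic occupancy", {
  # continuing 20-state chain under the deterministic policy "always right",
  # with the last state absorbing via the boundary clamp
  d <- 20
  p <- agent_params()
  P <- matrix(0, d, d)
  for (s in 1:(d - 1)) P[s, s + 1] <- 1
  P[d, d] <- 1
  M <- analytic_successor(P, p$gamma)

  W <- replicate(2, matrix(0, d, d), simplify = FALSE)
  w_r <- numeric(d)
  for (sweep in 1:2000) {
    for (s in 1:d) {
      s_next <- min(s + 1, d)
      upd <- sf_step(W, w_r, one_hot(s, d), 2, 0, one_hot(s_next, d), p,
                     terminal = FALSE, next_action = 2)
      W <- upd$W
      w_r <- upd$w_r
    }
  }
  # psi(s) = W[, s] should match the occupancy row M[s, ]
  learned <- t(W[[2]])
  expect_lt(max(abs(learned - M)), 0.05)
})

test_that("reward weights recover the true reward vector without noise", {
  tr <- train_agent("sf", sigma = 0, n_episodes = 600, seed = 3)
  w_r <- tr$agent$w_r
  expect_lt(abs(w_r[20] - 1), 0.01)
  expect_equal(w_r[1:19], numeric(19)) # never rewarded, tagged cleanly
})

test_that("trained agents can be rebuilt from stored weights", {
  cfg <- tiny_config("sf", sigma = 0, n_episodes = 400, seed = 5)
  rec <- run_trial(cfg, 1, keep_weights = TRUE)
  ag <- agent_from_weights("sf", grid_spec("chain_1d"), rec$weights)
  expect_equal(greedy_path_length(ag, grid_spec("chain_1d")), 19L)
})
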