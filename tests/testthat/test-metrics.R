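test_that("the trailing moving average smooths with partial prefix windows", {
  expect_equal(moving_average(rep(3, 50)), rep(3, 50))
  expect_equal(moving_average(1:20)[20], 10.5)
  expect_equal(moving_average(c(2, 4, 9), window = 1), c(2, 4, 9))
  expect_equal(moving_average(c(2, 4, 6), window = 2), c(2, 3, 5))
  expect_error(moving_average(numeric(0)), "non-empty")
  expect_error(moving_average(1:5, window = 0), ">= 1")

  # smoothed values stay within the range of the raw series
  set.seed(2)
  x <- sample(100, 500, replace = TRUE)
  sm <- moving_average(x)
  expect_true(all(sm >= min(x) & sm <= max(x)))
  expect_length(sm, length(x))
})

test_that("per-trial summaries match hand-computed statistics", {
  row <- summarize_trials(c(1, 2, 3, 4))
  expect_equal(row$mean, 2.5)
  expect_equal(row$sem, sd(1:4) / 2, tolerance = 1e-12)
  expect_equal(round(row$sem, 4), 0.6455)
  expect_equal(row$q25, 1.75) # linear interpolation between order statistics
  expect_equal(row$q50, 2.5)
  expect_equal(row$q75, 3.25)
  expect_equal(row$mean_sem_ratio, 2.5 / (sd(1:4) / 2))

  # all values equal: SEM 0, ratio flagged as NA rather than infinite
  same <- summarize_trials(rep(7, 10))
  expect_equal(same$sem, 0)
  expect_true(is.na(same$mean_sem_ratio))

  # a single value: SEM unavailable
  one <- summarize_trials(5)
  expect_true(is.na(one$sem))
  expect_error(summarize_trials(numeric(0)), "no values")

  # ordering of the quartiles holds on arbitrary samples
  set.seed(3)
  for (i in 1:20) {
    r <- summarize_trials(rnorm(sample(5:50, 1)))
    expect_true(r$q25 <= r$q50 && r$q50 <= r$q75)
    expect_true(r$mean >= r$q25 - 10 && r$mean <= r$q75 + 10)
  }
})

test_that("final-window lengths average the last twenty episodes", {
  expect_equal(final_window_length(rep(19L, 40)), 19)
  expect_equal(final_window_length(rep(100L, 25)), 100)
  expect_equal(final_window_length(c(rep(1L, 30), rep(19L, 10), rep(21L, 10))),
               20)
  expect_error(final_window_length(1:10), "at least 20")
  # agrees with the moving average evaluated at the last episode
  set.seed(4)
  x <- sample(1:100, 60, replace = TRUE)
  expect_equal(final_window_length(x), moving_average(x)[60])
})

test_that("episode bins count short, intermediate and capped episodes", {
  expect_equal(count_episode_bins(rep(19L, 50), cap = 100),
               c(short = 50L, mid = 0L, maxed = 0L))
  expect_equal(count_episode_bins(rep(100L, 8), cap = 100),
               c(short = 0L, mid = 0L, maxed = 8L))
  expect_equal(count_episode_bins(c(10L, 50L, 100L), cap = 100),
               c(short = 1L, mid = 1L, maxed = 1L))
  expect_error(count_episode_bins(c(10L, 101L), cap = 100), "\\[1, cap\\]")

  # conservation: the three bins always partition the episodes
  set.seed(5)
  for (i in 1:20) {
    lens <- sample(1:200, 100, replace = TRUE)
    bins <- count_episode_bins(lens, cap = 200)
    expect_equal(sum(bins), 100L)
  }
})

test_that("threshold attainment is scanned from the front and censored", {
  expect_equal(as.integer(first_threshold_episode(c(100, 100, 18, 100), 20)), 3L)
  expect_false(attr(first_threshold_episode(c(100, 100, 18, 100), 20), "censored"))
  expect_equal(as.integer(first_threshold_episode(c(15, 80), 20)), 1L)
  never <- first_threshold_episode(rep(80, 3000), 20)
  expect_equal(as.integer(never), 3000L)
  expect_true(attr(never, "censored"))
  expect_error(first_threshold_episode(numeric(0), 20), "non-empty")
})

test_that("cumulative reward curves are running prefix sums", {
  cr <- cumulative_reward(c(1, 0, 1))
  expect_equal(cr$curve, c(1, 1, 2))
  expect_equal(cr$final, 2)
  expect_equal(cumulative_reward(rep(1, 3000))$final, 3000)
  expect_equal(cumulative_reward(rep(0, 10))$final, 0)
  expect_true(all(diff(cumulative_reward(rbinom(100, 1, 0.5))$curve) >= 0))
})

test_that("the analytic occupancy matrix matches closed forms and series", {
  gamma <- 0.95
  # absorbing self-loops: geometric series 1/(1-gamma) on the diagonal
  M <- analytic_successor(diag(4), gamma)
  expect_equal(M, 20 * diag(4))

  # two-state chain 1 -> 2 -> 2
  P2 <- matrix(c(0, 0, 1, 1), 2, 2)
  M2 <- analytic_successor(P2, gamma)
  expect_equal(M2[1, ], c(1, 19))

  # every row sums to 1/(1-gamma) for row-stochastic P
  set.seed(6)
  P <- matrix(rexp(25), 5, 5)
  P <- P / rowSums(P)
  M5 <- analytic_successor(P, gamma)
  expect_equal(unname(rowSums(M5)), rep(20, 5), tolerance = 1e-10)

  # agreement with the truncated power series within gamma^(K+1)/(1-gamma)
  K <- 200
  S <- diag(5)
  Pk <- diag(5)
  for (k in 1:K) {
    Pk <- Pk %*% P
    S <- S + gamma^k * Pk
  }
  expect_lt(max(abs(M5 - S)), gamma^(K + 1) / (1 - gamma))

  expect_error(analytic_successor(matrix(1, 2, 3), gamma), "square")
  expect_error(analytic_successor(diag(2), 1), "gamma")
})

test_that("summary tables aggregate per-trial metrics by condition", {
  res <- run_experiment(tiny_config("q", n_trials = 3, n_episodes = 40))
  tab <- summary_table(res, "cumulative_reward")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n, 3L)
  cums <- vapply(res$trials, `[[`, numeric(1), "cumulative_reward")
  expect_equal(tab$mean, mean(cums))
  expect_true(all(c("sem", "q25", "q50", "q75", "mean_sem_ratio") %in%
                    names(tab)))

  bins <- summary_table(res, "maxed_episodes")
  expect_equal(bins$mean,
               mean(vapply(res$trials,
                           function(t) sum(t$lengths == 100L), numeric(1))))
})
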