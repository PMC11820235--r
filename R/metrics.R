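#' Trailing moving average
#'
#' Element `i` is the mean of the trailing window of up to `window` values
#' ending at `i`; the first `window - 1` elements average the available
#' prefix, so the smoothed series has the same length as the input.
#'
#' @param series Numeric vector (e.g. per-episode lengths).
#' @param window Window size, `>= 1` (default 20 episodes).
#' @return Numeric vector the same length as `series`.
#' @export
#' @examples
#' moving_average(1:20)[20]  # 10.5
moving_average <- function(series, window = 20L) {
  n <- length(series)
  if (n == 0L) stop("series must be non-empty", call. = FALSE)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  cs <- cumsum(as.numeric(series))
  i <- seq_len(n)
  lag <- c(rep(0, min(window, n)), cs[seq_len(max(0L, n - window))])
  (cs - lag) / pmin(i, window)
}

#' Summary-table row for one condition
#'
#' Mean, SEM (sample SD over the square root of the number of trials),
#' quartiles (linear interpolation between order statistics, the R default
#' quantile type 7), and the mean/SEM stability ratio.  The ratio is `NA`
#' (flagged, not infinite) when the SEM is zero; the SEM itself is `NA` when
#' fewer than two values are supplied.
#'
#' @param values Numeric vector, one value per trial.
#' @return A one-row tibble with columns `n`, `mean`, `sem`, `q25`, `q50`,
#'   `q75`, `mean_sem_ratio`.
#' @export
summarize_trials <- function(values) {
  n <- length(values)
  if (n == 0L) stop("no values to summarise", call. = FALSE)
  m <- mean(values)
  sem <- if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  ratio <- if (is.na(sem) || sem == 0) NA_real_ else m / sem
  tibble::tibble(n = n, mean = m, sem = sem,
                 q25 = q[1], q50 = q[2], q75 = q[3],
                 mean_sem_ratio = ratio)
}

#' Moving-averaged episode length at the final episode
#'
#' The value of the 20-episode trailing moving average at the last episode,
#' i.e. the mean length of the final `window` episodes of a trial.
#'
#' @param lengths Integer vector of per-episode lengths (or a
#'   `trial_record`).
#' @param window Window size (default 20).
#' @return Mean length of the last `window` episodes.
#' @export
final_window_length <- function(lengths, window = 20L) {
  if (inherits(lengths, "trial_record")) lengths <- lengths$lengths
  if (length(lengths) < window)
    stop("need at least ", window, " episodes", call. = FALSE)
  mean(utils::tail(lengths, window))
}

#' Count short, intermediate, and cap-length episodes
#'
#' Episodes shorter than `short_threshold` steps count as efficient
#' navigation; episodes of exactly the cap length count as failures to reach
#' the goal; the remainder are intermediate.  The three counts always sum to
#' the number of episodes.
#'
#' @param lengths Integer vector of per-episode lengths.
#' @param cap The environment step cap.
#' @param short_threshold Upper bound (exclusive) for a "short" episode
#'   (default 30 steps).
#' @return Named integer vector `c(short, mid, maxed)`.
#' @export
count_episode_bins <- function(lengths, cap, short_threshold = 30L) {
  if (any(lengths < 1L | lengths > cap))
    stop("episode lengths must lie in [1, cap]", call. = FALSE)
  short <- sum(lengths < short_threshold)
  maxed <- sum(lengths == cap)
  c(short = short, mid = length(lengths) - short - maxed, maxed = maxed)
}

#' First episode attaining a length threshold
#'
#' 1-based index of the first episode whose length is at most `theta` steps.
#' Trials that never attain the threshold are censored at the number of
#' episodes, with attribute `censored = TRUE`.
#'
#' @param lengths Integer vector of per-episode lengths.
#' @param theta Length threshold in steps (the study uses 20, 40, 60).
#' @return Integer episode index, with a logical `censored` attribute.
#' @export
first_threshold_episode <- function(lengths, theta) {
  if (!length(lengths)) stop("lengths must be non-empty", call. = FALSE)
  hit <- which(lengths <= theta)
  if (length(hit)) {
    structure(hit[1L], censored = FALSE)
  } else {
    structure(length(lengths), censored = TRUE)
  }
}

#' Cumulative reward curve and final total
#'
#' @param rewards Numeric vector of per-episode rewards (or a
#'   `trial_record`).
#' @return List with `curve` (running sums) and `final` (total reward).
#' @export
cumulative_reward <- function(rewards) {
  if (inherits(rewards, "trial_record")) rewards <- rewards$rewards
  curve <- cumsum(rewards)
  list(curve = curve, final = if (length(curve)) curve[length(curve)] else 0)
}

#' Analytic discounted occupancy matrix
#'
#' The closed-form successor representation of a fixed policy with
#' row-stochastic state-transition matrix `P`:
#' `M = (I - gamma P)^{-1} = sum_k gamma^k P^k`.  Row `s` is the expected
#' discounted number of future visits to each state starting from `s`
#' (counting the current state), and every row sums to `1 / (1 - gamma)`.
#' Serves as the convergence oracle for SF/PF learning under a frozen
#' policy.
#'
#' @param P Square row-stochastic matrix.
#' @param gamma Discount factor in `[0, 1)`.
#' @return The occupancy matrix, same dimensions as `P`.
#' @export
analytic_successor <- function(P, gamma) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("P must be a square matrix", call. = FALSE)
  if (gamma < 0 || gamma >= 1) stop("gamma must be in [0, 1)", call. = FALSE)
  solve(diag(nrow(P)) - gamma * P)
}

#' Per-condition summary table
#'
#' Builds the study-style summary table (mean, SEM, quartiles, mean/SEM) for
#' one metric across a set of experiment results.
#'
#' @param results A list of `experiment_result` objects (or a single one).
#' @param metric `"cumulative_reward"` (per-trial total reward),
#'   `"final_window_length"` (20-episode moving average at the last
#'   episode), `"short_episodes"` (< 30 steps), or `"maxed_episodes"`
#'   (exactly the cap).
#' @return A tibble with one row per condition: `condition`, `agent`,
#'   `sigma`, `lambda`, then the [summarize_trials()] columns.
#' @export
summary_table <- function(results,
                          metric = c("cumulative_reward",
                                     "final_window_length",
                                     "short_episodes", "maxed_episodes")) {
  metric <- match.arg(metric)
  if (inherits(results, "experiment_result")) results <- list(results)
  if (!length(results)) {
    return(tibble::tibble(condition = character(), agent = character(),
                          sigma = numeric(), lambda = numeric(),
                          n = integer(), mean = numeric(), sem = numeric(),
                          q25 = numeric(), q50 = numeric(), q75 = numeric(),
                          mean_sem_ratio = numeric()))
  }
  rows <- lapply(results, function(res) {
    cap <- grid_spec(res$config$layout)$step_cap
    vals <- vapply(res$trials, function(tr) {
      switch(metric,
        cumulative_reward = tr$cumulative_reward,
        final_window_length = final_window_length(tr),
        short_episodes = unname(count_episode_bins(tr$lengths, cap)["short"]),
        maxed_episodes = unname(count_episode_bins(tr$lengths, cap)["maxed"])
      )
    }, numeric(1))
    cbind(
      tibble::tibble(condition = res$condition,
                     agent = res$config$agent,
                     sigma = res$config$sigma,
                     lambda = res$config$lambda),
      summarize_trials(vals)
    )
  })
  tibble::as_tibble(do.call(rbind, rows))
}
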