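#' Experiment configuration
#'
#' One condition of the simulation grid: an environment, an agent kind, an
#' observation-noise level, and the trial/episode counts.  Defaults mirror
#' the full study protocol (100 trials of 3000 episodes); the desk-scale
#' profile used by the acceptance checks runs 20 trials.
#'
#' @param layout `"chain_1d"` or `"grid_2d"`.
#' @param agent One of `"q"`, `"q_lambda"`, `"sf"`, `"pf"`.
#' @param sigma Observation-noise SD (`>= 0`).
#' @param lambda Trace decay for `"q_lambda"`/`"pf"`; ignored otherwise.
#' @param n_trials,n_episodes Number of independent trials and of episodes
#'   per trial.
#' @param master_seed Integer master seed; per-trial seeds are derived
#'   deterministically from it, the condition id, and the trial index.
#' @param params An [agent_params()]; its `lambda` is overridden by the
#'   `lambda` argument for trace-based agents.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(layout = c("chain_1d", "grid_2d"),
                              agent = c("q", "q_lambda", "sf", "pf"),
                              sigma = 0, lambda = NA_real_,
                              n_trials = 100L, n_episodes = 3000L,
                              master_seed = 1L,
                              params = agent_params()) {
  layout <- match.arg(layout)
  agent <- match.arg(agent)
  stopifnot(sigma >= 0, n_trials >= 1, n_episodes >= 1)
  if (agent %in% c("q_lambda", "pf")) {
    if (is.na(lambda)) stop(agent, " requires a lambda value", call. = FALSE)
    params$lambda <- lambda
  } else {
    lambda <- NA_real_
    params$lambda <- 0
  }
  structure(
    list(layout = layout, agent = agent, sigma = sigma, lambda = lambda,
         n_trials = as.integer(n_trials), n_episodes = as.integer(n_episodes),
         master_seed = as.integer(master_seed), params = params),
    class = "experiment_config"
  )
}

#' Condition identifier string
#'
#' @param config An [experiment_config()].
#' @return A short unique id, e.g. `"chain_1d.pf0.9.s0.5"`.
#' @export
condition_id <- function(config) {
  lam <- if (is.na(config$lambda)) "" else config$lambda
  paste0(config$layout, ".", config$agent, lam, ".s", config$sigma)
}

#' Derive a reproducible integer seed from components
#'
#' Folds an integer and a string context through a small LCG so that every
#' (master seed, condition, trial) triple maps to a distinct, reproducible
#' seed below 2^31.  Not cryptographic; just auditable stream separation.
#'
#' @param master_seed Integer.
#' @param context Character scalar (e.g. a condition id).
#' @param index Integer (e.g. trial number).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
mix_seed <- function(master_seed, context = "", index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master_seed) %% m
  for (x in c(utf8ToInt(as.character(context)), as.numeric(index))) {
    h <- (h * 69069 + x + 1) %% m
  }
  as.integer(h) + 1L
}

trial_seed <- function(config, trial) {
  mix_seed(config$master_seed, condition_id(config), trial)
}

#' Run a single episode (pure-R engine)
#'
#' Loops observe -> act -> step -> learn until the goal is entered or the
#' step cap is reached.  Epsilon is held constant within the episode.  One
#' fresh noisy percept is drawn per environment step; it is the input to
#' action selection for every agent.  What the learning update consumes
#' depends on the agent family (see [make_agent()]): the Q agents learn
#' directly from the noisy percepts, while the SF/PF agents learn their
#' successor and reward weights from the true state features, with noise
#' degrading only their value readout at decision time.  Only entering the
#' goal is treated as terminal for bootstrapping; hitting the cap truncates
#' the episode but keeps the bootstrap term.
#'
#' @param spec A [grid_spec()].
#' @param agent An `rl_agent` ([make_agent()]); mutated in place.
#' @param epsilon Exploration rate for this episode.
#' @param sigma Observation-noise SD.
#' @return A list with `length` (steps taken) and `reward` (0 or 1).
#' @export
run_episode <- function(spec, agent, epsilon, sigma) {
  agent_begin_episode(agent)
  st <- env_reset(spec)
  o <- observe(st$current, spec, sigma)
  state_learn <- agent$kind %in% c("sf", "pf")
  reward <- 0
  repeat {
    a <- agent_act(agent, o, epsilon)
    step <- env_step(spec, st, a)
    o_next <- observe(step$state$current, spec, sigma)
    terminal <- step$state$current == spec$goal
    if (state_learn) {
      agent_learn(agent, one_hot(st$current, spec$n_obs), a, step$reward,
                  one_hot(step$state$current, spec$n_obs), terminal)
    } else {
      agent_learn(agent, o, a, step$reward, o_next, terminal)
    }
    st <- step$state
    reward <- step$reward
    if (st$done) break
    o <- o_next
  }
  list(length = st$steps_taken, reward = reward)
}

#' Run one trial
#'
#' A trial is a fresh zero-initialised agent run for `n_episodes` episodes,
#' with epsilon starting at `epsilon0` and decayed once after each episode,
#' and eligibility traces reset at each episode start.  The default engine
#' is the compiled inner loop; `engine = "r"` runs the pure-R reference
#' implementation, which consumes the RNG stream in exactly the same order
#' and is cross-checked against the compiled path in the test suite.
#'
#' @param config An [experiment_config()].
#' @param trial Trial index (used to derive the seed).
#' @param engine `"cpp"` (default) or `"r"`.
#' @param keep_weights Return the final learned weights?
#' @return An object of class `trial_record`: list with `trial`, `seed`,
#'   `lengths` (integer per episode), `rewards` (0/1 per episode),
#'   `cumulative_reward`, and optionally `weights`.
#' @export
run_trial <- function(config, trial = 1L, engine = c("cpp", "r"),
                      keep_weights = FALSE) {
  engine <- match.arg(engine)
  seed <- trial_seed(config, trial)
  spec <- grid_spec(config$layout)
  p <- config$params
  set.seed(seed)
  if (engine == "cpp") {
    kind <- match(config$agent, c("q", "q_lambda", "sf", "pf")) - 1L
    res <- sim_trial_cpp(
      kind, spec$next_state, spec$start, spec$goal, spec$step_cap,
      config$sigma, config$n_episodes,
      p$alpha, p$alpha_w, p$alpha_r, p$gamma, p$lambda,
      p$epsilon0, p$epsilon_decay, p$epsilon_floor, keep_weights
    )
    lengths <- res$lengths
    rewards <- res$rewards
    weights <- if (keep_weights) res$weights else NULL
  } else {
    agent <- make_agent(config$agent, spec, p)
    eps <- p$epsilon0
    lengths <- integer(config$n_episodes)
    rewards <- numeric(config$n_episodes)
    for (k in seq_len(config$n_episodes)) {
      ep <- run_episode(spec, agent, eps, config$sigma)
      lengths[k] <- ep$length
      rewards[k] <- ep$reward
      eps <- decay_epsilon(eps, p)
    }
    weights <- if (keep_weights) {
      if (config$agent %in% c("q", "q_lambda")) {
        list(weights = agent$weights)
      } else {
        list(W = agent$W, w_r = agent$w_r)
      }
    }
  }
  structure(
    list(trial = as.integer(trial), seed = seed,
         lengths = as.integer(lengths), rewards = as.numeric(rewards),
         cumulative_reward = sum(rewards), weights = weights),
    class = "trial_record"
  )
}

#' Run all trials of a condition
#'
#' Trials are mutually independent: each gets its own derived seed, so
#' results do not depend on execution order and adding conditions never
#' perturbs another condition's trials.
#'
#' @param config An [experiment_config()].
#' @param engine `"cpp"` or `"r"`.
#' @param trials Which trial indices to run (default all).
#' @return An object of class `experiment_result`: list with `config`,
#'   `condition` (id string), and `trials` (list of `trial_record`s).
#' @export
run_experiment <- function(config, engine = c("cpp", "r"),
                           trials = seq_len(config$n_trials)) {
  engine <- match.arg(engine)
  recs <- lapply(trials, function(i) run_trial(config, i, engine))
  structure(
    list(config = config, condition = condition_id(config), trials = recs),
    class = "experiment_result"
  )
}

#' Tidy per-episode records of an experiment
#'
#' @param result An `experiment_result` from [run_experiment()].
#' @return A tibble with columns `condition`, `trial`, `episode`, `length`,
#'   `reward`.
#' @export
episode_records <- function(result) {
  n_ep <- result$config$n_episodes
  tibble::tibble(
    condition = result$condition,
    trial = rep(vapply(result$trials, `[[`, integer(1), "trial"), each = n_ep),
    episode = rep(seq_len(n_ep), length(result$trials)),
    length = unlist(lapply(result$trials, `[[`, "lengths")),
    reward = unlist(lapply(result$trials, `[[`, "rewards"))
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cum <- vapply(x$trials, `[[`, numeric(1), "cumulative_reward")
  cat("<experiment_result> ", x$condition, ": ", length(x$trials),
      " trials x ", x$config$n_episodes, " episodes; mean cumulative reward ",
      round(mean(cum), 2), "\n", sep = "")
  invisible(x)
}
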