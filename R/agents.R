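#' Learning hyperparameters
#'
#' Bundles every tunable rate the agents use.  Defaults are the study
#' conditions used throughout the package: all learning rates 0.1, discount
#' 0.95, and an epsilon-greedy exploration schedule that starts at 1.0 and
#' decays by factor 0.99 per episode down to a floor of 0.01.
#'
#' @param alpha Q/Q(lambda) learning rate.
#' @param alpha_w Successor/predecessor feature-weight learning rate.
#' @param alpha_r Reward-weight learning rate.
#' @param gamma Discount factor in `[0, 1)`.
#' @param lambda Eligibility-trace decay in `[0, 1]`; used by the Q(lambda)
#'   and PF agents only.
#' @param epsilon0 Initial exploration rate.
#' @param epsilon_decay Per-episode multiplicative decay of epsilon.
#' @param epsilon_floor Lower bound on epsilon.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha = 0.1, alpha_w = 0.1, alpha_r = 0.1,
                         gamma = 0.95, lambda = 0,
                         epsilon0 = 1, epsilon_decay = 0.99,
                         epsilon_floor = 0.01) {
  stopifnot(
    alpha > 0, alpha <= 1, alpha_w > 0, alpha_w <= 1,
    alpha_r > 0, alpha_r <= 1,
    gamma >= 0, gamma < 1, lambda >= 0, lambda <= 1,
    epsilon0 >= 0, epsilon0 <= 1,
    epsilon_decay > 0, epsilon_decay <= 1, epsilon_floor >= 0
  )
  structure(
    list(alpha = alpha, alpha_w = alpha_w, alpha_r = alpha_r,
         gamma = gamma, lambda = lambda, epsilon0 = epsilon0,
         epsilon_decay = epsilon_decay, epsilon_floor = epsilon_floor),
    class = "agent_params"
  )
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` picks a uniformly random action; otherwise
#' picks uniformly among the actions attaining the maximum value (ties are
#' broken at random so an all-zero value landscape carries no directional
#' bias).  Consumes one uniform draw, plus one more when exploring or when
#' the greedy argmax is tied.
#'
#' Non-finite values are excluded from the greedy comparison (runaway
#' Q(lambda) weights can overflow under heavy noise); if no value is finite
#' the first action is taken, so a numerically broken value landscape yields
#' a fixed degenerate policy rather than an error.
#'
#' @param values Numeric vector of per-action values.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return Action index (1-based).
#' @export
epsilon_greedy <- function(values, epsilon) {
  n <- length(values)
  if (n < 1L) stop("values must contain at least one action", call. = FALSE)
  if (epsilon < 0 || epsilon > 1) stop("epsilon must be in [0,1]", call. = FALSE)
  u <- stats::runif(1)
  if (u < epsilon) {
    a <- floor(stats::runif(1) * n) + 1
    return(as.integer(min(a, n)))
  }
  finite <- is.finite(values)
  if (!any(finite)) return(1L)
  mx <- max(values[finite])
  ties <- which(finite & values == mx)
  if (length(ties) == 1L) return(ties)
  j <- floor(stats::runif(1) * length(ties)) + 1
  ties[min(j, length(ties))]
}

#' Per-episode epsilon decay
#'
#' `epsilon_{k+1} = max(decay * epsilon_k, floor)`, applied once per episode.
#'
#' @param epsilon Current exploration rate.
#' @param params An [agent_params()].
#' @return The decayed rate.
#' @export
#' @examples
#' decay_epsilon(1.0, agent_params())   # 0.99
#' decay_epsilon(0.01, agent_params())  # 0.01 (floor)
decay_epsilon <- function(epsilon, params = agent_params()) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  max(params$epsilon_decay * epsilon, params$epsilon_floor)
}

# first index attaining the finite maximum; 1 when nothing is finite
first_argmax <- function(values) {
  finite <- is.finite(values)
  if (!any(finite)) return(1L)
  which(finite & values == max(values[finite]))[1L]
}

check_obs <- function(o, weights_dim) {
  if (length(o) != weights_dim)
    stop("observation length ", length(o), " does not match weight dimension ",
         weights_dim, call. = FALSE)
}

#' One-step Q-learning update on observation vectors
#'
#' Linear action values `Q(o, a) = w_a . o` with one weight vector per
#' action.  The TD error is
#' `delta = r + gamma * max_a' w_a' . o_next - w_a . o`
#' (bootstrap dropped when `o_next` is terminal) and only the row for the
#' taken action moves, in the direction of `o` scaled by `alpha * delta`.
#'
#' @param weights Numeric matrix, `n_actions x n_obs`.
#' @param o,o_next Observation vectors at t and t+1.
#' @param a Taken action index.
#' @param r Reward received.
#' @param params An [agent_params()].
#' @param terminal Is the transition into a terminal (goal) state?
#' @return The updated weight matrix.
#' @export
q_update <- function(weights, o, a, r, o_next, params, terminal = FALSE) {
  check_obs(o, ncol(weights)); check_obs(o_next, ncol(weights))
  target <- r + if (terminal) 0 else params$gamma * max(weights %*% o_next)
  delta <- target - drop(weights[a, , drop = FALSE] %*% o)
  weights[a, ] <- weights[a, ] + params$alpha * delta * o
  weights
}

#' Q(lambda) update with accumulating eligibility traces
#'
#' Naive Q(lambda): the trace (shaped like the weights) accumulates the
#' current observation at the taken action's row, every weight moves by
#' `alpha * delta * trace`, and the whole trace then decays by
#' `gamma * lambda`.  No trace cut is made on exploratory actions.  The
#' trace must be reset to zero at each episode start.
#'
#' @inheritParams q_update
#' @param trace Numeric matrix shaped like `weights`.
#' @return List with updated `weights` and `trace`.
#' @export
q_lambda_update <- function(weights, trace, o, a, r, o_next, params,
                            terminal = FALSE) {
  check_obs(o, ncol(weights)); check_obs(o_next, ncol(weights))
  trace[a, ] <- trace[a, ] + o
  target <- r + if (terminal) 0 else params$gamma * max(weights %*% o_next)
  delta <- target - drop(weights[a, , drop = FALSE] %*% o)
  weights <- weights + (params$alpha * delta) * trace
  trace <- (params$gamma * params$lambda) * trace
  list(weights = weights, trace = trace)
}

sf_delta <- function(W, w_r, o, a, o_next, gamma, terminal,
                     next_action = NULL) {
  psi_t <- drop(W[[a]] %*% o)
  # the terminal state's successor features are its own features, so the
  # goal's (discounted) occupancy still enters psi; without this the value
  # function psi . w_r is identically zero and no policy can be learned
  if (terminal) return(o + gamma * o_next - psi_t)
  if (is.null(next_action)) {
    vals <- vapply(W, function(Wa) sum(drop(Wa %*% o_next) * w_r), numeric(1))
    next_action <- first_argmax(vals)
  }
  o + gamma * drop(W[[next_action]] %*% o_next) - psi_t
}

#' Successor-feature (SF) learning step
#'
#' One successor matrix `W_a` per action with features
#' `psi(o, a) = W_a o`.  The feature TD error is
#' `delta_sf = o + gamma * psi(o_next, a*) - psi(o, a)` where `a*` is the
#' greedy next action (off-policy, Q-style; pass `next_action` to bootstrap
#' with a prescribed action instead, e.g. under a frozen policy).  `W_a` for
#' the taken action moves by `alpha_w * delta_sf %o% o`, and the reward
#' weights by `alpha_r * (r - o_next . w_r) * o_next`.  On a terminal
#' (goal-entering) transition the target is `o + gamma * o_next`: the
#' terminal state's successor features are its own features, so the goal's
#' discounted occupancy enters psi even though no further bootstrapping
#' happens.
#'
#' @param W List of `n_actions` successor matrices (`n_obs x n_obs`).
#' @param w_r Reward-weight vector of length `n_obs`.
#' @inheritParams q_update
#' @param next_action Optional action to bootstrap with (default: greedy).
#' @return List with updated `W` and `w_r`.
#' @export
sf_step <- function(W, w_r, o, a, r, o_next, params, terminal = FALSE,
                    next_action = NULL) {
  d <- length(w_r)
  check_obs(o, d); check_obs(o_next, d)
  delta <- sf_delta(W, w_r, o, a, o_next, params$gamma, terminal, next_action)
  W[[a]] <- W[[a]] + params$alpha_w * (delta %o% o)
  w_r <- w_r + params$alpha_r * (r - sum(o_next * w_r)) * o_next
  list(W = W, w_r = w_r)
}

#' Predecessor-feature (PF) learning step
#'
#' SF learning whose feature TD error is broadcast backwards through an
#' accumulating eligibility trace over observations: `e <- e + o`, then
#' `W_a <- W_a + alpha_w * delta_pf %o% e`, then `e <- gamma * lambda * e`.
#' The trace must be reset to zero at episode start.  With `lambda = 0` the
#' trace collapses to the current observation and PF coincides with SF.
#'
#' @inheritParams sf_step
#' @param trace Eligibility-trace vector of length `n_obs`.
#' @return List with updated `W`, `w_r`, and `trace`.
#' @export
pf_step <- function(W, w_r, trace, o, a, r, o_next, params, terminal = FALSE,
                    next_action = NULL) {
  d <- length(w_r)
  check_obs(o, d); check_obs(o_next, d)
  trace <- trace + o
  delta <- sf_delta(W, w_r, o, a, o_next, params$gamma, terminal, next_action)
  W[[a]] <- W[[a]] + params$alpha_w * (delta %o% trace)
  w_r <- w_r + params$alpha_r * (r - sum(o_next * w_r)) * o_next
  trace <- (params$gamma * params$lambda) * trace
  list(W = W, w_r = w_r, trace = trace)
}

#' Create a learning agent
#'
#' Builds a mutable agent object (an environment) holding zero-initialised
#' weights for one of the four algorithms.  Interact with it through
#' [agent_begin_episode()], [agent_act()] and [agent_learn()].
#'
#' The two families differ in how observation noise reaches them (the
#' `learn_input` field).  The Q agents (`"q"`, `"q_lambda"`) are linear
#' function approximators over the percept: both their action values and
#' their TD updates consume the noisy observation vector.  The SF/PF agents
#' decompose the value function into a predictive map (successor features)
#' and a reward vector, both learned from the resolved state sequence
#' (`learn_input = "state"`); the noisy percept enters only their value
#' readout `psi(o) . w_r` at decision time.  With `sigma = 0` the two
#' interfaces coincide.
#'
#' @param kind One of `"q"`, `"q_lambda"`, `"sf"`, `"pf"`.
#' @param spec A [grid_spec()] providing the observation dimension and
#'   action count.
#' @param params An [agent_params()].
#' @return An object of class `rl_agent`.
#' @export
make_agent <- function(kind = c("q", "q_lambda", "sf", "pf"), spec,
                       params = agent_params()) {
  kind <- match.arg(kind)
  d <- spec$n_obs
  nA <- spec$n_actions
  ag <- new.env(parent = emptyenv())
  ag$kind <- kind
  ag$params <- params
  ag$d <- d
  ag$n_actions <- nA
  ag$learn_input <- if (kind %in% c("q", "q_lambda")) "observation" else "state"
  if (kind %in% c("q", "q_lambda")) {
    ag$weights <- matrix(0, nA, d)
    if (kind == "q_lambda") ag$trace <- matrix(0, nA, d)
  } else {
    ag$W <- replicate(nA, matrix(0, d, d), simplify = FALSE)
    ag$w_r <- numeric(d)
    if (kind == "pf") ag$trace <- numeric(d)
  }
  class(ag) <- c("rl_agent", "environment")
  ag
}

#' @rdname make_agent
#' @param agent An `rl_agent`.
#' @export
agent_begin_episode <- function(agent) {
  if (agent$kind == "q_lambda") agent$trace <- matrix(0, agent$n_actions, agent$d)
  if (agent$kind == "pf") agent$trace <- numeric(agent$d)
  invisible(agent)
}

#' Per-action values of an agent at an observation
#'
#' Q/Q(lambda): `w_a . o` per action; SF/PF: `(W_a o) . w_r` per action.
#'
#' @param agent An `rl_agent` from [make_agent()].
#' @param o Observation vector.
#' @return Numeric vector of length `n_actions`.
#' @export
action_values <- function(agent, o) {
  check_obs(o, agent$d)
  if (agent$kind %in% c("q", "q_lambda")) {
    drop(agent$weights %*% o)
  } else {
    vapply(agent$W, function(Wa) sum(drop(Wa %*% o) * agent$w_r), numeric(1))
  }
}

#' @rdname make_agent
#' @param o Observation vector.
#' @param epsilon Exploration rate for this episode.
#' @export
agent_act <- function(agent, o, epsilon) {
  epsilon_greedy(action_values(agent, o), epsilon)
}

#' @rdname make_agent
#' @param o,o_next Observations at t and t+1.
#' @param a Taken action.
#' @param r Reward.
#' @param terminal Did this transition enter the goal?
#' @export
agent_learn <- function(agent, o, a, r, o_next, terminal = FALSE) {
  p <- agent$params
  switch(agent$kind,
    q = {
      agent$weights <- q_update(agent$weights, o, a, r, o_next, p, terminal)
    },
    q_lambda = {
      upd <- q_lambda_update(agent$weights, agent$trace, o, a, r, o_next, p,
                             terminal)
      agent$weights <- upd$weights
      agent$trace <- upd$trace
    },
    sf = {
      upd <- sf_step(agent$W, agent$w_r, o, a, r, o_next, p, terminal)
      agent$W <- upd$W
      agent$w_r <- upd$w_r
    },
    pf = {
      upd <- pf_step(agent$W, agent$w_r, agent$trace, o, a, r, o_next, p,
                     terminal)
      agent$W <- upd$W
      agent$w_r <- upd$w_r
      agent$trace <- upd$trace
    }
  )
  invisible(agent)
}

#' Rebuild an agent from stored weights
#'
#' Wraps weights returned by [run_trial()] (with `keep_weights = TRUE`) back
#' into an `rl_agent`, e.g. to evaluate the learned greedy policy.
#'
#' @inheritParams make_agent
#' @param weights For `"q"`/`"q_lambda"`: a list with element `weights`
#'   (matrix `n_actions x n_obs`); for `"sf"`/`"pf"`: a list with `W` (list
#'   of matrices) and `w_r`.
#' @return An `rl_agent`.
#' @export
agent_from_weights <- function(kind, spec, weights, params = agent_params()) {
  ag <- make_agent(kind, spec, params)
  if (kind %in% c("q", "q_lambda")) {
    stopifnot(all(dim(weights$weights) == dim(ag$weights)))
    ag$weights <- weights$weights
  } else {
    ag$W <- weights$W
    ag$w_r <- as.numeric(weights$w_r)
  }
  ag
}

#' Greedy rollout length from learned weights
#'
#' Rolls the noise-free environment forward from the start state, always
#' taking the first argmax action (no exploration, no learning, no noise),
#' and returns the number of steps taken to reach the goal, or the step cap
#' if it is not reached.  Used to check whether a trained agent's greedy
#' policy has converged to the shortest path.
#'
#' @param agent A trained `rl_agent`.
#' @param spec The [grid_spec()] it was trained on.
#' @return Integer path length.
#' @export
greedy_path_length <- function(agent, spec) {
  s <- spec$start
  for (step in seq_len(spec$step_cap)) {
    a <- first_argmax(action_values(agent, one_hot(s, spec$n_obs)))
    s <- spec$next_state[s, a]
    if (s == spec$goal) return(step)
  }
  spec$step_cap
}
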