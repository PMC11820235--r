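# Shared helpers: small training loops built from exported API only.

# Run n episodes of a fresh agent with the standard epsilon schedule,
# starting from a given RNG seed; returns lengths, rewards, and the agent.
train_agent <- function(kind, layout = "chain_1d", sigma = 0, n_episodes = 100,
                        seed = 1, lambda = 0) {
  set.seed(seed)
  spec <- grid_spec(layout)
  params <- agent_params(lambda = lambda)
  agent <- make_agent(kind, spec, params)
  eps <- params$epsilon0
  lengths <- integer(n_episodes)
  rewards <- numeric(n_episodes)
  for (k in seq_len(n_episodes)) {
    ep <- run_episode(spec, agent, eps, sigma)
    lengths[k] <- ep$length
    rewards[k] <- ep$reward
    eps <- decay_epsilon(eps, params)
  }
  list(lengths = lengths, rewards = rewards, agent = agent, spec = spec)
}

# Tiny experiment config for runner tests.
tiny_config <- function(agent = "q", layout = "chain_1d", sigma = 0.25,
                        lambda = NA, n_trials = 2, n_episodes = 30, seed = 42) {
  experiment_config(layout, agent, sigma = sigma, lambda = lambda,
                    n_trials = n_trials, n_episodes = n_episodes,
                    master_seed = seed)
}
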