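#' Grid-world environment specification
#'
#' Constructs an immutable description of one of the two deterministic
#' grid-world MDPs used throughout the package: a one-dimensional chain of
#' 20 states (start at state 1, goal at state 20, actions left/right) or a
#' two-dimensional 7x7 lattice whose border cells are walls, leaving a 5x5
#' navigable interior (start at the bottom-right navigable cell, goal at the
#' top-left navigable cell, actions up/down/left/right).  Observations are
#' one-hot over the full lattice, so the 2D world has 49 observable cells but
#' only 25 movable states.  Transitions are deterministic; moves into a wall
#' or off the grid leave the agent in place and still consume a step.
#'
#' @param layout `"chain_1d"` or `"grid_2d"`.
#' @param n_states Chain length for `"chain_1d"` (default 20). Ignored for
#'   `"grid_2d"`.
#' @param size Lattice side for `"grid_2d"` (default 7; border cells are
#'   walls). Ignored for `"chain_1d"`.
#' @param start,goal Optional state indices (1-based, over the observation
#'   lattice) overriding the default corner-to-corner task. Both must be
#'   navigable and distinct.
#' @param step_cap Maximum steps per episode; default 100 (1D) or 200 (2D).
#'
#' @return An object of class `grid_spec`: a list with elements `layout`,
#'   `n_obs` (observation dimension), `n_nav` (number of navigable states),
#'   `nav_states`, `wall` (logical per cell), `actions`, `n_actions`,
#'   `next_state` (integer matrix `n_obs x n_actions` of deterministic
#'   successors; wall rows are self-loops and never visited), `start`,
#'   `goal`, `step_cap`, and for 2D `nrow`/`ncol`.
#' @export
#' @examples
#' spec <- grid_spec("chain_1d")
#' spec$n_obs       # 20
#' spec$step_cap    # 100
grid_spec <- function(layout = c("chain_1d", "grid_2d"),
                      n_states = 20L, size = 7L,
                      start = NULL, goal = NULL, step_cap = NULL) {
  layout <- match.arg(layout)
  if (layout == "chain_1d") {
    n_obs <- as.integer(n_states)
    if (n_obs < 2L) stop("chain_1d needs at least 2 states", call. = FALSE)
    wall <- rep(FALSE, n_obs)
    actions <- c("left", "right")
    next_state <- cbind(
      left  = pmax(seq_len(n_obs) - 1L, 1L),
      right = pmin(seq_len(n_obs) + 1L, n_obs)
    )
    spec <- list(
      layout = layout, n_obs = n_obs, n_nav = n_obs,
      nav_states = seq_len(n_obs), wall = wall,
      actions = actions, n_actions = 2L,
      next_state = next_state,
      start = if (is.null(start)) 1L else as.integer(start),
      goal = if (is.null(goal)) n_obs else as.integer(goal),
      step_cap = if (is.null(step_cap)) 100L else as.integer(step_cap)
    )
  } else {
    size <- as.integer(size)
    if (size < 3L) stop("grid_2d needs size >= 3", call. = FALSE)
    n_obs <- size * size
    row_of <- function(s) (s - 1L) %/% size + 1L
    col_of <- function(s) (s - 1L) %% size + 1L
    wall <- row_of(seq_len(n_obs)) %in% c(1L, size) |
      col_of(seq_len(n_obs)) %in% c(1L, size)
    actions <- c("up", "down", "left", "right")
    drow <- c(up = -1L, down = 1L, left = 0L, right = 0L)
    dcol <- c(up = 0L, down = 0L, left = -1L, right = 1L)
    next_state <- matrix(0L, n_obs, 4L, dimnames = list(NULL, actions))
    for (s in seq_len(n_obs)) {
      for (a in seq_along(actions)) {
        r <- row_of(s) + drow[a]
        cc <- col_of(s) + dcol[a]
        tgt <- if (r < 1L || r > size || cc < 1L || cc > size) {
          s
        } else {
          (r - 1L) * size + cc
        }
        # moves into walls clamp back to the current cell
        next_state[s, a] <- if (wall[tgt]) s else tgt
      }
    }
    nav <- which(!wall)
    # bottom-right navigable cell -> top-left navigable cell (corner task)
    default_start <- (size - 2L) * size + (size - 1L)
    default_goal <- size + 2L
    spec <- list(
      layout = layout, n_obs = n_obs, n_nav = length(nav),
      nav_states = nav, wall = wall,
      actions = actions, n_actions = 4L,
      next_state = next_state,
      start = if (is.null(start)) default_start else as.integer(start),
      goal = if (is.null(goal)) default_goal else as.integer(goal),
      step_cap = if (is.null(step_cap)) 200L else as.integer(step_cap),
      nrow = size, ncol = size
    )
  }
  if (spec$wall[spec$start] || spec$wall[spec$goal])
    stop("start and goal must be navigable cells", call. = FALSE)
  if (spec$start == spec$goal)
    stop("start and goal must differ", call. = FALSE)
  structure(spec, class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$layout,
      ": ", x$n_nav, " navigable / ", x$n_obs, " observable states, ",
      x$n_actions, " actions, start ", x$start, " -> goal ", x$goal,
      ", step cap ", x$step_cap, "\n", sep = "")
  invisible(x)
}

#' Read a grid-world specification from a plain-text config
#'
#' Reads a YAML (or JSON, which YAML subsumes) file with keys `layout`,
#' and optionally `size`/`n_states`, `start`, `goal`, `step_cap`, `sigma`.
#'
#' @param path Path to the config file.
#' @return A list with elements `spec` (a [grid_spec()]) and `sigma`
#'   (observation-noise SD, 0 if absent).
#' @export
read_grid_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$layout)) stop("config must contain 'layout'", call. = FALSE)
  spec <- grid_spec(
    layout = cfg$layout,
    n_states = if (is.null(cfg$n_states)) 20L else cfg$n_states,
    size = if (is.null(cfg$size)) 7L else cfg$size,
    start = cfg$start, goal = cfg$goal, step_cap = cfg$step_cap
  )
  sigma <- if (is.null(cfg$sigma)) 0 else cfg$sigma
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  list(spec = spec, sigma = sigma)
}

#' One-hot state feature vector
#'
#' @param state State index, 1-based.
#' @param dim Feature dimension (number of observable cells).
#' @return Numeric vector of length `dim` with a single 1 at `state`.
#' @export
#' @examples
#' one_hot(1, 20)[1]  # 1
one_hot <- function(state, dim) {
  state <- as.integer(state)
  dim <- as.integer(dim)
  if (length(state) != 1L || is.na(state) || state < 1L || state > dim)
    stop("state out of range [1, ", dim, "]", call. = FALSE)
  v <- numeric(dim)
  v[state] <- 1
  v
}

#' Noisy observation of a state
#'
#' Returns the one-hot encoding of `state` perturbed by i.i.d. Gaussian
#' noise, `o = phi(s) + eps`, `eps ~ N(0, sigma^2 I)`.  Every call makes a
#' fresh draw from R's RNG; with `sigma = 0` the observation is exactly
#' one-hot and no random numbers are consumed.
#'
#' @param state State index, 1-based.
#' @param spec A [grid_spec()] (or anything with an `n_obs` element).
#' @param sigma Noise standard deviation, `>= 0`.
#' @return Numeric observation vector of length `spec$n_obs`.
#' @export
observe <- function(state, spec, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a non-negative scalar", call. = FALSE)
  phi <- one_hot(state, spec$n_obs)
  if (sigma > 0) phi <- phi + stats::rnorm(spec$n_obs, 0, sigma)
  phi
}

#' Reset an environment to the start of an episode
#'
#' @param spec A [grid_spec()].
#' @return An `env_state` list: `current` (state id), `steps_taken`, `done`.
#' @export
env_reset <- function(spec) {
  structure(
    list(current = spec$start, steps_taken = 0L, done = FALSE),
    class = "env_state"
  )
}

#' Advance the environment one step
#'
#' Applies the deterministic transition for `action`; invalid moves (off-grid
#' or into a wall) leave the position unchanged but still consume a step.
#' Reward is 1 iff the resulting position is the goal, else 0.  The episode
#' terminates when the goal is entered or when `steps_taken` reaches the step
#' cap; a goal entered exactly on the cap-th step still counts as success.
#'
#' @param spec A [grid_spec()].
#' @param state An `env_state` from [env_reset()] or a previous step.
#' @param action Action index (1-based into `spec$actions`) or action name.
#' @return A list with `state` (new `env_state`) and `reward` (0 or 1).
#' @export
env_step <- function(spec, state, action) {
  if (isTRUE(state$done))
    stop("cannot step a finished episode", call. = FALSE)
  if (is.character(action)) action <- match(action, spec$actions)
  action <- as.integer(action)
  if (is.na(action) || action < 1L || action > spec$n_actions)
    stop("invalid action", call. = FALSE)
  nxt <- unname(spec$next_state[state$current, action])
  steps <- state$steps_taken + 1L
  reward <- if (nxt == spec$goal) 1 else 0
  done <- reward == 1 || steps >= spec$step_cap
  list(
    state = structure(
      list(current = nxt, steps_taken = steps, done = done),
      class = "env_state"
    ),
    reward = reward
  )
}

#' Shortest path length between two states
#'
#' Breadth-first search over the deterministic transition table, counting
#' moves from `from` to `to`.
#'
#' @param spec A [grid_spec()].
#' @param from,to State indices; default the spec's start and goal.
#' @return Integer number of moves (0 when `from == to`).
#' @export
#' @examples
#' shortest_path_length(grid_spec("chain_1d"))  # 19
#' shortest_path_length(grid_spec("grid_2d"))   # 8
shortest_path_length <- function(spec, from = spec$start, to = spec$goal) {
  from <- as.integer(from); to <- as.integer(to)
  if (from == to) return(0L)
  dist <- rep(NA_integer_, spec$n_obs)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(as.integer(spec$next_state[frontier, ]))
    nxt <- nxt[is.na(dist[nxt])]
    if (!length(nxt)) break
    dist[nxt] <- dist[frontier[1L]] + 1L
    if (!is.na(dist[to])) return(dist[to])
    frontier <- nxt
  }
  stop("goal is unreachable from the given state", call. = FALSE)
}
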