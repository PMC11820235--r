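#' The full study condition grid for one environment
#'
#' Eight agent variants (Q; Q(lambda) and PF at lambda 0.7, 0.8, 0.9; SF)
#' crossed with the three observation-noise levels sigma = 0.05, 0.25, 0.5:
#' 24 conditions per environment.
#'
#' @param layout `"chain_1d"` or `"grid_2d"`.
#' @param sigmas Noise levels (default the study's three).
#' @param lambdas Trace decays for the trace-based agents.
#' @return A tibble with columns `layout`, `agent`, `sigma`, `lambda`.
#' @export
paper_conditions <- function(layout = c("chain_1d", "grid_2d"),
                             sigmas = c(0.05, 0.25, 0.5),
                             lambdas = c(0.7, 0.8, 0.9)) {
  layout <- match.arg(layout)
  agents <- rbind(
    data.frame(agent = "q", lambda = NA_real_),
    data.frame(agent = "q_lambda", lambda = lambdas),
    data.frame(agent = "sf", lambda = NA_real_),
    data.frame(agent = "pf", lambda = lambdas)
  )
  grid <- merge(agents, data.frame(sigma = sigmas))
  tibble::tibble(layout = layout, agent = grid$agent,
                 sigma = grid$sigma, lambda = grid$lambda)
}

#' Sweep manifest
#'
#' Bundles a set of conditions with the shared trial/episode counts, master
#' seed, and output directory.  The desk-scale profile (20 trials) is the
#' default; pass `n_trials = 100` for the full protocol.
#'
#' @param conditions A tibble as from [paper_conditions()] (columns
#'   `layout`, `agent`, `sigma`, `lambda`).
#' @param n_trials,n_episodes Counts shared by all conditions.
#' @param master_seed Integer master seed.
#' @param out_dir Output directory for CSV/JSON artifacts.
#' @return An object of class `sweep_manifest`.
#' @export
sweep_manifest <- function(conditions, n_trials = 20L, n_episodes = 3000L,
                           master_seed = 1L, out_dir = "results") {
  configs <- lapply(seq_len(nrow(conditions)), function(i) {
    experiment_config(
      layout = conditions$layout[i], agent = conditions$agent[i],
      sigma = conditions$sigma[i], lambda = conditions$lambda[i],
      n_trials = n_trials, n_episodes = n_episodes,
      master_seed = master_seed
    )
  })
  ids <- vapply(configs, condition_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate conditions in manifest", call. = FALSE)
  structure(
    list(configs = configs, ids = ids, out_dir = out_dir,
         n_trials = as.integer(n_trials), n_episodes = as.integer(n_episodes),
         master_seed = as.integer(master_seed)),
    class = "sweep_manifest"
  )
}

#' Run a sweep and write its artifacts
#'
#' Runs every condition in the manifest, writing per-episode records as tidy
#' CSV (one file per condition, columns condition/trial/episode/length/
#' reward), a JSON metadata echo (seeds, parameters), and the summary tables
#' (cumulative reward and final moving-averaged episode length).  All
#' randomness derives from the manifest's master seed, so rerunning a
#' manifest reproduces its outputs exactly.
#'
#' @param manifest A [sweep_manifest()].
#' @param engine `"cpp"` or `"r"`.
#' @param verbose Print per-condition progress to stderr?
#' @return Invisibly, a list of summary tibbles (`cumulative_reward`,
#'   `final_window_length`).
#' @export
run_sweep <- function(manifest, engine = "cpp", verbose = TRUE) {
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- vector("list", length(manifest$configs))
  meta <- list(
    master_seed = manifest$master_seed, n_trials = manifest$n_trials,
    n_episodes = manifest$n_episodes, conditions = list()
  )
  for (i in seq_along(manifest$configs)) {
    cfg <- manifest$configs[[i]]
    id <- manifest$ids[i]
    if (verbose) message("[", i, "/", length(manifest$configs), "] ", id)
    res <- run_experiment(cfg, engine = engine)
    results[[i]] <- res
    utils::write.csv(episode_records(res),
                     file.path(manifest$out_dir, paste0("cond_", id, ".csv")),
                     row.names = FALSE)
    meta$conditions[[id]] <- list(
      layout = cfg$layout, agent = cfg$agent, sigma = cfg$sigma,
      lambda = cfg$lambda,
      trial_seeds = vapply(seq_len(cfg$n_trials),
                           function(k) trial_seed(cfg, k), integer(1))
    )
  }
  jsonlite::write_json(meta, file.path(manifest$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  tabs <- list(
    cumulative_reward = summary_table(results, "cumulative_reward"),
    final_window_length = summary_table(results, "final_window_length")
  )
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]],
                     file.path(manifest$out_dir, paste0("summary_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(tabs)
}

#' Rebuild summary tables from stored sweep output
#'
#' A pure function of the per-trial CSV records written by [run_sweep()]:
#' nothing is re-simulated.  Conditions listed in the manifest whose CSV is
#' missing are flagged in the returned `missing` element (and with a
#' warning) rather than silently dropped.
#'
#' @param results_dir Directory written by [run_sweep()].
#' @return A list with tibbles `cumulative_reward`, `final_window_length`,
#'   `episode_bins`, and a character vector `missing`.
#' @export
make_report <- function(results_dir) {
  manifest_path <- file.path(results_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json in ", results_dir, call. = FALSE)
  meta <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  ids <- names(meta$conditions)
  missing <- character()
  rows_cum <- list(); rows_len <- list(); rows_bin <- list()
  for (id in ids) {
    path <- file.path(results_dir, paste0("cond_", id, ".csv"))
    if (!file.exists(path)) {
      missing <- c(missing, id)
      next
    }
    rec <- utils::read.csv(path)
    cnd <- meta$conditions[[id]]
    cap <- grid_spec(cnd$layout)$step_cap
    by_trial <- split(rec, rec$trial)
    cum <- vapply(by_trial, function(x) sum(x$reward), numeric(1))
    fin <- vapply(by_trial, function(x) final_window_length(x$length), numeric(1))
    shrt <- vapply(by_trial,
                   function(x) unname(count_episode_bins(x$length, cap)["short"]),
                   numeric(1))
    mxd <- vapply(by_trial,
                  function(x) unname(count_episode_bins(x$length, cap)["maxed"]),
                  numeric(1))
    key <- tibble::tibble(condition = id, agent = cnd$agent,
                          sigma = cnd$sigma,
                          lambda = if (is.null(cnd$lambda)) NA_real_ else cnd$lambda)
    rows_cum[[id]] <- cbind(key, summarize_trials(cum))
    rows_len[[id]] <- cbind(key, summarize_trials(fin))
    rows_bin[[id]] <- cbind(key,
                            tibble::tibble(mean_short = mean(shrt),
                                           mean_maxed = mean(mxd)))
  }
  if (length(missing))
    warning("missing per-trial records for: ", paste(missing, collapse = ", "),
            call. = FALSE)
  bind_rows_or_empty <- function(rows) {
    if (length(rows)) tibble::as_tibble(do.call(rbind, rows)) else tibble::tibble()
  }
  list(
    cumulative_reward = bind_rows_or_empty(rows_cum),
    final_window_length = bind_rows_or_empty(rows_len),
    episode_bins = bind_rows_or_empty(rows_bin),
    missing = missing
  )
}

#' Learning-curve plot for a set of experiments
#'
#' Moving-averaged episode length (mean across trials, with an SEM band)
#' against episode number, one panel per condition.  Requires ggplot2.
#'
#' @param results A list of `experiment_result` objects.
#' @param window Moving-average window (default 20 episodes).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(results, window = 20L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_learning_curves requires ggplot2", call. = FALSE)
  if (inherits(results, "experiment_result")) results <- list(results)
  dat <- do.call(rbind, lapply(results, function(res) {
    sm <- vapply(res$trials,
                 function(tr) moving_average(tr$lengths, window),
                 numeric(res$config$n_episodes))
    m <- rowMeans(sm)
    sem <- apply(sm, 1, stats::sd) / sqrt(ncol(sm))
    data.frame(condition = res$condition,
               episode = seq_along(m), mean = m, sem = sem)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = episode, y = mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sem, ymax = mean + sem),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "episode", y = "episode length (20-episode MA)")
}
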