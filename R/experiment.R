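#' Experiment presets
#'
#' Ready-made configurations reproducing the package's benchmark pipelines.
#' Hyperparameters follow the defaults of each environment class: abstract
#' graphs use `n_s = 1000`, `eta_q = 0.1`, `eta_v = eta_w = 0.01`, 200 random
#' walks of length 32 replayed for 10 rounds; 2D grids use `n_s = 80` with
#' all learning rates 0.3 and the sparse 22-walks-of-length-3 protocol with
#' held-out edges; the point-mass preset trains by motor babbling only.
#'
#' @param name preset name: `"random32"`, `"weighted32"`, `"small_world"`,
#'   `"dead_end"`, `"multi_path"`, `"grid4x4"`, `"grid_hex"`, `"pointmass"`.
#' @param seed master integer seed; every stage's seed is derived from it.
#' @return an experiment config (a named list, serializable to YAML).
#' @export
preset <- function(name = c("random32", "weighted32", "small_world",
                            "dead_end", "multi_path", "grid4x4", "grid_hex",
                            "pointmass"),
                   seed = 1L) {
  name <- match.arg(name)
  seed <- as.integer(seed)
  graph_model <- list(n_s = 1000, eta_q = 0.1, eta_v = 0.01, eta_w = 0.01,
                      sigma_q = 1, sigma_v = 0.1, sigma_w = 0.1,
                      normalize_v = FALSE)
  grid_model <- list(n_s = 80, eta_q = 0.3, eta_v = 0.3, eta_w = 0.3,
                     sigma_q = 1, sigma_v = 0.1, sigma_w = 0.1,
                     normalize_v = FALSE)
  graph_explore <- list(n_walks = 200, walk_len = 32)
  base <- switch(name,
    random32 = list(
      env = list(kind = "random", n_nodes = 32, deg_min = 2, deg_max = 5),
      model = graph_model, explore = graph_explore, rounds = 10,
      evaluate = list(n_trials = 1000, use_w = TRUE,
                      forbid_repeat_action = FALSE)),
    weighted32 = list(
      env = list(kind = "random", n_nodes = 32, deg_min = 2, deg_max = 5,
                 cost_values = 4:7),
      model = graph_model, explore = graph_explore, rounds = 10,
      evaluate = list(n_trials = 1000, use_w = TRUE,
                      forbid_repeat_action = TRUE)),
    small_world = list(
      env = list(kind = "small_world", k_clusters = 4, cluster_size = 6,
                 topology = "chain"),
      model = graph_model, explore = graph_explore, rounds = 10,
      evaluate = list(n_trials = 1000, use_w = TRUE,
                      forbid_repeat_action = FALSE)),
    dead_end = list(
      env = list(kind = "dead_end", backbone_len = 10, n_pendants = 6,
                 pendant_len = 3),
      model = graph_model, explore = graph_explore, rounds = 10,
      evaluate = list(n_trials = 1000, use_w = TRUE,
                      forbid_repeat_action = FALSE)),
    multi_path = list(
      env = list(kind = "multi_path", rows = 4, cols = 6),
      model = graph_model, explore = graph_explore, rounds = 10,
      evaluate = list(n_trials = 1000, use_w = TRUE,
                      forbid_repeat_action = FALSE)),
    grid4x4 = list(
      env = list(kind = "grid", geometry = "rect", width = 4, height = 4),
      model = grid_model,
      explore = list(n_walks = 22, walk_len = 3, n_holdout = 4),
      rounds = 200,
      evaluate = list(n_trials = 240, use_w = TRUE,
                      forbid_repeat_action = FALSE)),
    grid_hex = list(
      env = list(kind = "grid", geometry = "hex", width = 3, height = 3),
      model = grid_model,
      explore = list(n_walks = 30, walk_len = 3, n_holdout = 3),
      rounds = 200,
      evaluate = list(n_trials = 72, use_w = TRUE,
                      forbid_repeat_action = FALSE)),
    pointmass = list(
      env = list(kind = "pointmass"),
      model = list(n_s = 128, eta_q = 0.005, eta_v = 0.02, eta_w = 0.02,
                   sigma_q = 0.1, sigma_v = 1, sigma_w = 0.1,
                   normalize_v = FALSE),
      explore = list(n_episodes = 150, ep_len = 20),
      rounds = 3,
      evaluate = list(n_trials = 8, goal_distance = 5, max_steps = 120))
  )
  c(list(name = name, seed = seed), base)
}

derive_seeds <- function(seed, n = 5L) {
  (as.integer(seed) + 104729L * seq_len(n)) %% .Machine$integer.max
}

build_env <- function(cfg, seed) {
  e <- cfg$env
  env <- switch(e$kind,
    random = generate_random_graph(e$n_nodes, e$deg_min, e$deg_max,
                                   seed = seed),
    small_world = generate_small_world(e$k_clusters, e$cluster_size,
                                       e$topology, seed = seed),
    dead_end = generate_challenge_graph("dead_end",
                                        backbone_len = e$backbone_len,
                                        n_pendants = e$n_pendants,
                                        pendant_len = e$pendant_len,
                                        seed = seed),
    multi_path = generate_challenge_graph("multi_path", rows = e$rows,
                                          cols = e$cols, seed = seed),
    grid = generate_grid(e$geometry, e$width, e$height),
    pointmass = pointmass_env(),
    stop(sprintf("unknown environment kind '%s'", e$kind))
  )
  if (!is.null(e$cost_values))
    env <- assign_edge_costs(env, e$cost_values, seed = seed + 1L)
  env
}

#' Run an experiment end to end
#'
#' Pipeline: build the environment, sample exploration, train by replay,
#' evaluate planning against Dijkstra, and compute the geometry diagnostics.
#' With `out_dir` set, writes the planning-stats CSV, learning curve,
#' model checkpoint, config YAML and a machine-readable summary.
#'
#' @param config an experiment config from [preset()] (or a compatible list,
#'   e.g. read from YAML).
#' @param out_dir optional output directory.
#' @return list with `$env`, `$buffer`, `$model`, `$curve`, `$stats` and
#'   `$diagnostics` (`$control` instead of `$stats`/`$diagnostics` for the
#'   point-mass preset).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(is.list(config), !is.null(config$seed))
  seeds <- derive_seeds(config$seed)
  env <- build_env(config, seeds[1])
  if (identical(config$env$kind, "pointmass"))
    return(run_pointmass_experiment(config, env, seeds, out_dir))
  mcfg <- config$model
  model <- cml(env$n_obs, env$n_a, mcfg$n_s,
               eta_q = mcfg$eta_q, eta_v = mcfg$eta_v, eta_w = mcfg$eta_w,
               sigma_q = mcfg$sigma_q, sigma_v = mcfg$sigma_v,
               sigma_w = mcfg$sigma_w, normalize_v = mcfg$normalize_v,
               seed = seeds[2])
  xcfg <- config$explore
  buffer <- if (inherits(env, "grid_env") && !is.null(xcfg$n_holdout)) {
    sample_grid_exploration(env, xcfg$n_walks, xcfg$walk_len,
                            n_holdout = xcfg$n_holdout, seed = seeds[3])
  } else {
    sample_exploration(env, xcfg$n_walks, xcfg$walk_len, seed = seeds[3])
  }
  fit <- train_on_replay(model, buffer, rounds = config$rounds)
  ecfg <- config$evaluate
  stats <- evaluate_planner(fit$model, env, n_trials = ecfg$n_trials,
                            seed = seeds[4], use_w = ecfg$use_w,
                            forbid_repeat_action = ecfg$forbid_repeat_action)
  diag <- list(
    closure = closure_errors(fit$model, buffer),
    distance_scaling = distance_scaling(fit$model, env, seed = seeds[5]),
    projection = map_projection(fit$model, 2)
  )
  res <- list(config = config, env = env, buffer = buffer,
              model = fit$model, curve = fit$curve, stats = stats,
              diagnostics = diag)
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

run_pointmass_experiment <- function(config, env, seeds, out_dir = NULL) {
  mcfg <- config$model
  model <- cml(env$n_o, env$n_a, mcfg$n_s,
               eta_q = mcfg$eta_q, eta_v = mcfg$eta_v, eta_w = mcfg$eta_w,
               sigma_q = mcfg$sigma_q, sigma_v = mcfg$sigma_v,
               sigma_w = mcfg$sigma_w, seed = seeds[2])
  xcfg <- config$explore
  bb <- babble(env, xcfg$n_episodes, xcfg$ep_len, seed = seeds[3])
  fit <- train_on_dense(model, bb$obs, bb$actions, bb$obs_next,
                        rounds = config$rounds, eta_recon = 0.001)
  ecfg <- config$evaluate
  local_seed(seeds[4])
  angles <- stats::runif(ecfg$n_trials, 0, 2 * pi)
  eps <- lapply(seq_len(ecfg$n_trials), function(i) {
    goal <- ecfg$goal_distance * c(cos(angles[i]), sin(angles[i]))
    reach_goal(fit$model, env, goal, max_steps = ecfg$max_steps)
  })
  control <- data.frame(
    trial = seq_len(ecfg$n_trials),
    initial_distance = vapply(eps, `[[`, 0, "initial_distance"),
    final_distance = vapply(eps, `[[`, 0, "final_distance"))
  res <- list(config = config, env = env, model = fit$model,
              curve = fit$curve, control = control, episodes = eps)
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_learning_curve(res$curve, file.path(out_dir, "learning_curve.csv"))
  save_cml(res$model, file.path(out_dir, "model.rds"))
  yaml::write_yaml(res$config, file.path(out_dir, "config.yaml"))
  if (!is.null(res$stats)) {
    s <- res$stats
    utils::write.csv(data.frame(
      n_trials = s$n_trials, success_rate = s$success_rate,
      mean_steps = s$mean_steps, sd_steps = s$sd_steps,
      mean_cost = s$mean_cost, sd_cost = s$sd_cost,
      oracle_mean = s$oracle_mean, oracle_sd = s$oracle_sd,
      ratio = s$ratio), file.path(out_dir, "planning_stats.csv"),
      row.names = FALSE)
  }
  if (!is.null(res$control))
    utils::write.csv(res$control, file.path(out_dir, "control.csv"),
                     row.names = FALSE)
  invisible(out_dir)
}

#' @rdname run_experiment
#' @param name,seed preset name and master seed (see [preset()]).
#' @export
run_preset <- function(name, seed = 1L, out_dir = NULL) {
  run_experiment(preset(name, seed), out_dir = out_dir)
}

#' Read / write an experiment config
#'
#' Configs are plain YAML mirrors of the [preset()] lists.
#'
#' @param path file path.
#' @param config an experiment config.
#' @return `read_config`: the config list; `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
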