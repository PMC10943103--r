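#' Evaluate a planner against the Dijkstra baseline
#'
#' Runs [plan_online()] on `n_trials` seeded random ordered start-goal pairs
#' (start != goal) and aggregates path lengths (or, on weighted environments,
#' summed costs) against the per-pair Dijkstra optimum. Episodes that fail to
#' reach the goal within the step cap are excluded from the means but counted
#' in the success rate.
#'
#' @param model a trained [cml()] model.
#' @param env a discrete environment.
#' @param n_trials number of start-goal pairs.
#' @param seed integer seed for the pair draw.
#' @param use_w,forbid_repeat_action,max_steps passed to [plan_online()].
#' @param weighted aggregate summed edge costs instead of step counts.
#' @return a `planning_stats` list: `n_trials`, `success_rate`, `mean_steps`,
#'   `sd_steps`, `mean_cost`, `sd_cost`, `oracle_mean`, `oracle_sd`, `ratio`
#'   (CML mean over oracle mean, successful trials only) and the `pairs`.
#' @export
evaluate_planner <- function(model, env, n_trials = 1000, seed = 1L,
                             use_w = TRUE, forbid_repeat_action = FALSE,
                             max_steps = 4L * env_diameter(env),
                             weighted = !is.null(env$costs)) {
  pairs <- sample_eval_pairs(env$n_obs, n_trials, seed)
  D <- dijkstra_distances(env, weighted = weighted)
  steps <- numeric(n_trials); cost <- numeric(n_trials)
  ok <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    p <- plan_online(model, env, pairs[i, 1], pairs[i, 2],
                     max_steps = max_steps, use_w = use_w,
                     forbid_repeat_action = forbid_repeat_action)
    ok[i] <- p$reached
    steps[i] <- p$n_steps
    cost[i] <- p$total_cost
  }
  opt <- D[pairs]
  cml_val <- if (weighted) cost else steps
  structure(list(
    n_trials = n_trials,
    success_rate = mean(ok),
    mean_steps = mean(steps[ok]), sd_steps = stats::sd(steps[ok]),
    mean_cost = mean(cost[ok]), sd_cost = stats::sd(cost[ok]),
    oracle_mean = mean(opt[ok]), oracle_sd = stats::sd(opt[ok]),
    ratio = mean(cml_val[ok]) / mean(opt[ok]),
    weighted = weighted, pairs = pairs, reached = ok
  ), class = "planning_stats")
}

#' @export
print.planning_stats <- function(x, ...) {
  metric <- if (x$weighted) "cost" else "steps"
  val <- if (x$weighted) x$mean_cost else x$mean_steps
  sdv <- if (x$weighted) x$sd_cost else x$sd_steps
  cat(sprintf(paste0("<planning_stats> %d trials, success %.1f%%\n",
                     "  mean %s %.3f (sd %.3f) vs optimal %.3f (sd %.3f), ",
                     "ratio %.3f\n"),
              x$n_trials, 100 * x$success_rate, metric, val, sdv,
              x$oracle_mean, x$oracle_sd, x$ratio))
  invisible(x)
}

#' Cosine similarity of action embeddings
#'
#' Entry `(i, j)` is the cosine of columns `i` and `j` of `V`. After training,
#' most action embeddings stay approximately orthogonal; exceptions are
#' actions sharing a node (correlated) and the two traversal directions of
#' one edge (anti-correlated).
#'
#' @param model a [cml()] model.
#' @return an `n_a x n_a` matrix; entries involving a zero column are `NA`.
#' @export
action_cosine_matrix <- function(model) {
  nrm <- sqrt(colSums(model$V^2))
  C <- crossprod(model$V) / outer(nrm, nrm)
  C[, nrm == 0] <- NA_real_
  C[nrm == 0, ] <- NA_real_
  C
}

#' Norm of the summed action embeddings around a cycle
#'
#' If the predictive-coding goal holds, the embeddings of the actions along
#' any closed walk must sum to (nearly) the zero vector. Returns
#' \eqn{\|\sum_k V a_k\|} divided by the mean column norm of `V`, after
#' validating that the action sequence really is a closed walk from
#' `start`.
#'
#' @param model a [cml()] model.
#' @param env a discrete environment.
#' @param start starting node of the walk.
#' @param actions integer vector of action indices (may be empty).
#' @return nonnegative scalar (0 for the empty cycle).
#' @export
cycle_embedding_norm <- function(model, env, start, actions) {
  node <- start
  for (a in actions) node <- step_env(env, node, a)
  if (node != start) stop("action sequence is not a closed walk")
  if (!length(actions)) return(0)
  v <- rowSums(model$V[, actions, drop = FALSE])
  sqrt(sum(v^2)) / mean(sqrt(colSums(model$V^2)))
}

#' State-space distance versus graph distance
#'
#' Samples random node pairs, bins them by Dijkstra shortest-path length `d`,
#' and reports the mean and sd of the state-space distance
#' \eqn{\|Q o_i - Q o_j\|} per bin, together with the Pearson correlation
#' between state-space distance and \eqn{\sqrt d} over all sampled pairs. In
#' a well-formed map the distances grow like the square root of the path
#' length (Pythagoras over approximately orthogonal unit action steps).
#'
#' @param model a [cml()] model.
#' @param env a discrete environment.
#' @param n_pairs number of sampled pairs.
#' @param seed integer seed.
#' @return list with `$table` (data.frame `graph_distance`,
#'   `mean_state_distance`, `sd_state_distance`, `n`), `$correlation`
#'   (pair-level Pearson correlation of distance with \eqn{\sqrt d}) and
#'   `$trend_correlation` (correlation of the per-bin mean distances with
#'   \eqn{\sqrt d}, the statistic the square-root scaling claim is about —
#'   pair-level correlation is additionally diluted by within-bin spread).
#' @export
distance_scaling <- function(model, env, n_pairs = 500, seed = 1L) {
  pairs <- sample_eval_pairs(env$n_obs, n_pairs, seed)
  D <- dijkstra_distances(env, weighted = FALSE)
  gd <- D[pairs]
  sdist <- sqrt(colSums((model$Q[, pairs[, 1]] - model$Q[, pairs[, 2]])^2))
  tab <- do.call(rbind, lapply(sort(unique(gd)), function(d) {
    sel <- gd == d
    data.frame(graph_distance = d,
               mean_state_distance = mean(sdist[sel]),
               sd_state_distance = stats::sd(sdist[sel]),
               n = sum(sel))
  }))
  pos <- tab$graph_distance > 0
  list(table = tab,
       correlation = stats::cor(sdist, sqrt(gd)),
       trend_correlation = if (sum(pos) >= 3)
         stats::cor(tab$mean_state_distance[pos],
                    sqrt(tab$graph_distance[pos])) else NA_real_)
}

#' Parallelism score of two observation pairs
#'
#' The cosine between the state differences of two observation pairs,
#' \eqn{\cos(Q o_{a2} - Q o_{a1},\; Q o_{b2} - Q o_{b1})}. When both pairs
#' are related by the same action, a score near 1 indicates the map encodes
#' that action as the same state-space displacement in both contexts — a
#' measure of compositional generalization.
#'
#' @param model a [cml()] model.
#' @param pair_a,pair_b length-2 integer vectors of observation indices
#'   (from, to).
#' @return scalar in `[-1, 1]`; `NA` with a warning if a difference vanishes.
#' @export
parallelism_score <- function(model, pair_a, pair_b) {
  stopifnot(length(pair_a) == 2, length(pair_b) == 2)
  da <- model$Q[, pair_a[2]] - model$Q[, pair_a[1]]
  db <- model$Q[, pair_b[2]] - model$Q[, pair_b[1]]
  na <- sqrt(sum(da^2)); nb <- sqrt(sum(db^2))
  if (na == 0 || nb == 0) {
    warning("zero state difference; parallelism score undefined")
    return(NA_real_)
  }
  sum(da * db) / (na * nb)
}

#' Principal-component projection of the cognitive map
#'
#' Projects the observation embeddings (columns of `Q`) onto their first `k`
#' principal components and reports the fraction of variance they explain.
#' The action embeddings (columns of `V`) are mapped into the same
#' projection as directions.
#'
#' @param model a [cml()] model.
#' @param k number of components (<= `n_s`).
#' @return list with `$coords` (`n_o x k`), `$action_coords` (`n_a x k`),
#'   `$variance_explained` (scalar in `[0, 1]`).
#' @export
map_projection <- function(model, k = 2) {
  if (k > model$n_s) stop("k may not exceed the state dimension")
  pts <- t(model$Q)
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  k_eff <- min(k, ncol(pc$rotation))
  list(coords = pc$x[, seq_len(k_eff), drop = FALSE],
       action_coords = t(model$V) %*% pc$rotation[, seq_len(k_eff),
                                                  drop = FALSE],
       variance_explained = sum(pc$sdev[seq_len(k_eff)]^2) /
         sum(pc$sdev^2))
}

#' Write projected map coordinates to CSV
#'
#' One row per observation with its projected coordinates, followed by one
#' row per action (marked in the `kind` column); consumable by any plotting
#' tool.
#'
#' @param projection result of [map_projection()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_projection <- function(projection, path) {
  k <- ncol(projection$coords)
  cn <- paste0("pc", seq_len(k))
  obs <- data.frame(kind = "observation",
                    index = seq_len(nrow(projection$coords)))
  obs[cn] <- projection$coords
  act <- data.frame(kind = "action",
                    index = seq_len(nrow(projection$action_coords)))
  act[cn] <- projection$action_coords
  utils::write.csv(rbind(obs, act), path, row.names = FALSE)
  invisible(path)
}

#' Relative closure error of explored transitions
#'
#' For each transition in the buffer, the predictive-coding residual
#' \eqn{\|Q o_{t+1} - Q o_t - V a_t\| / \|V a_t\|}. Values well below 1 on
#' every explored transition mean the map has internalized the environment's
#' transition structure.
#'
#' @param model a [cml()] model.
#' @param buffer a `replay_buffer`.
#' @return numeric vector, one residual per distinct explored transition.
#' @export
closure_errors <- function(model, buffer) {
  tr <- unique(buffer$transitions[, c("from", "action", "to")])
  va <- model$V[, tr$action, drop = FALSE]
  res <- model$Q[, tr$to, drop = FALSE] - model$Q[, tr$from, drop = FALSE] - va
  sqrt(colSums(res^2)) / sqrt(colSums(va^2))
}
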