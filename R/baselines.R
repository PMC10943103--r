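#' Dijkstra shortest path
#'
#' Computes a minimum-cost path between two nodes (unit costs when the
#' environment is unweighted). Ties are broken deterministically in favor of
#' the lowest node id, both in the priority queue and in predecessor choice.
#'
#' @param env a discrete environment.
#' @param start,goal node indices.
#' @return a list of class `optimal_path`: `$path` (node sequence), `$length`
#'   (edge count), `$cost` (summed edge costs), `$reachable`.
#' @export
dijkstra <- function(env, start, goal) {
  stopifnot(start >= 1, start <= env$n_obs, goal >= 1, goal <= env$n_obs)
  dist <- rep(Inf, env$n_obs)
  pred <- rep(NA_integer_, env$n_obs)
  done <- rep(FALSE, env$n_obs)
  dist[start] <- 0
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    u <- open[which.min(dist[open])]      # which.min: lowest index on ties
    if (u == goal) break
    done[u] <- TRUE
    for (a in which(!is.na(env$nbr[u, ]))) {
      v <- env$nbr[u, a]
      w <- edge_cost(env, env$edge_id[u, a])
      alt <- dist[u] + w
      if (alt < dist[v] || (alt == dist[v] && !is.na(pred[v]) && u < pred[v])) {
        dist[v] <- alt
        pred[v] <- u
      }
    }
  }
  if (!is.finite(dist[goal]))
    return(structure(list(path = integer(0), length = NA_integer_,
                          cost = NA_real_, reachable = FALSE),
                     class = "optimal_path"))
  path <- goal
  while (path[1] != start) path <- c(pred[path[1]], path)
  structure(list(path = path, length = length(path) - 1L,
                 cost = dist[goal], reachable = TRUE),
            class = "optimal_path")
}

#' All-sources shortest distances
#'
#' Distance matrix (entry `[i, j]` = minimal cost from i to j) by running
#' Dijkstra from every node; `weighted = FALSE` forces unit edge costs.
#'
#' @param env a discrete environment.
#' @param weighted use edge costs (default: yes, if present).
#' @return an `n_obs x n_obs` numeric matrix.
#' @export
dijkstra_distances <- function(env, weighted = !is.null(env$costs)) {
  e <- env
  if (!weighted) e$costs <- NULL
  D <- matrix(0, env$n_obs, env$n_obs)
  for (s in seq_len(env$n_obs)) {
    dist <- rep(Inf, e$n_obs); done <- rep(FALSE, e$n_obs)
    dist[s] <- 0
    repeat {
      open <- which(!done & is.finite(dist))
      if (!length(open)) break
      u <- open[which.min(dist[open])]
      done[u] <- TRUE
      for (a in which(!is.na(e$nbr[u, ]))) {
        v <- e$nbr[u, a]
        alt <- dist[u] + edge_cost(e, e$edge_id[u, a])
        if (alt < dist[v]) dist[v] <- alt
      }
    }
    D[s, ] <- dist
  }
  D
}

#' Mean optimal path length or cost over random node pairs
#'
#' Samples `n_pairs` uniformly random ordered start-goal pairs (start != goal)
#' and returns the mean and standard deviation of the Dijkstra shortest-path
#' length (edges) or cost.
#'
#' @param env a discrete environment.
#' @param n_pairs number of pairs.
#' @param seed integer seed.
#' @param weighted measure cost instead of edge count.
#' @return list with `mean`, `sd`, and the sampled `pairs` matrix.
#' @export
average_optimal <- function(env, n_pairs = 1000, seed = 1L,
                            weighted = !is.null(env$costs)) {
  pairs <- sample_eval_pairs(env$n_obs, n_pairs, seed)
  D <- dijkstra_distances(env, weighted = weighted)
  vals <- D[pairs]
  list(mean = mean(vals), sd = stats::sd(vals), pairs = pairs)
}

# n_pairs uniformly random ordered start != goal pairs, as a 2-column matrix
sample_eval_pairs <- function(n_nodes, n_pairs, seed) {
  stopifnot(n_nodes >= 2, n_pairs >= 1)
  local_seed(seed)
  start <- sample.int(n_nodes, n_pairs, replace = TRUE)
  goal <- sample.int(n_nodes - 1L, n_pairs, replace = TRUE)
  goal <- goal + (goal >= start)
  cbind(start, goal)
}
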