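#' Generate a 2D grid maze
#'
#' A rectangular or hexagonal grid of cells, each emitting a unique one-hot
#' observation. Actions are state-invariant moves: 4 cardinal moves for
#' `"rect"`, 6 axial moves for `"hex"`. An action that would leave the grid
#' has affordance 0 (the boundary is the only obstacle); all others have
#' affordance 1.
#'
#' Rectilinear cells are enumerated row-major with 0-based `(row, col)`
#' coordinates; the actions are, in order, north (row-1), east (col+1),
#' south (row+1), west (col-1). Hexagonal cells use axial coordinates
#' `(q, r)` with `q` in `0..width-1`, `r` in `0..height-1` and the six unit
#' moves `(+1,0), (+1,-1), (0,-1), (-1,0), (-1,+1), (0,+1)`.
#'
#' @param geometry `"rect"` or `"hex"`.
#' @param width,height grid extent (both >= 2).
#' @return a grid environment sharing the discrete-environment interface
#'   (see [affordances()]); `$coords` holds the cell coordinates.
#' @export
generate_grid <- function(geometry = c("rect", "hex"), width = 4, height = 4) {
  geometry <- match.arg(geometry)
  stopifnot(width >= 2, height >= 2)
  moves <- if (geometry == "rect") {
    rbind(c(-1, 0), c(0, 1), c(1, 0), c(0, -1))       # N, E, S, W as (row, col)
  } else {
    rbind(c(1, 0), c(1, -1), c(0, -1), c(-1, 0), c(-1, 1), c(0, 1))  # (q, r)
  }
  n_a <- nrow(moves)
  if (geometry == "rect") {
    coords <- expand.grid(col = 0:(width - 1), row = 0:(height - 1))
    coords <- cbind(row = coords$row, col = coords$col)   # row-major order
    cell_id <- function(r, c) r * width + c + 1L
    in_grid <- function(r, c) r >= 0 & r < height & c >= 0 & c < width
    ax1 <- coords[, "row"]; ax2 <- coords[, "col"]
  } else {
    coords <- expand.grid(q = 0:(width - 1), r = 0:(height - 1))
    coords <- cbind(q = coords$q, r = coords$r)
    cell_id <- function(q, r) r * width + q + 1L
    in_grid <- function(q, r) q >= 0 & q < width & r >= 0 & r < height
    ax1 <- coords[, "q"]; ax2 <- coords[, "r"]
  }
  n_obs <- nrow(coords)
  nbr <- matrix(NA_integer_, n_obs, n_a)
  edges <- NULL
  for (a in seq_len(n_a)) {
    t1 <- ax1 + moves[a, 1]; t2 <- ax2 + moves[a, 2]
    ok <- in_grid(t1, t2)
    nbr[ok, a] <- cell_id(t1[ok], t2[ok])
  }
  for (i in seq_len(n_obs)) for (j in nbr[i, !is.na(nbr[i, ])])
    if (i < j) edges <- rbind(edges, c(i, j))
  edges <- validate_edges(edges, n_obs)
  ekey <- edge_key_set(edges)
  edge_id <- matrix(NA_integer_, n_obs, n_a)
  for (a in seq_len(n_a)) {
    ok <- !is.na(nbr[, a])
    i <- which(ok); j <- nbr[ok, a]
    edge_id[ok, a] <- match(edge_key(pmin(i, j), pmax(i, j)), ekey)
  }
  afford <- matrix(as.numeric(!is.na(nbr)), n_obs, n_a)
  structure(list(
    n_obs = n_obs, n_a = as.integer(n_a),
    nbr = nbr, afford = afford, edge_id = edge_id,
    edges = edges, costs = NULL, kind = paste0("grid_", geometry),
    geometry = geometry, width = as.integer(width),
    height = as.integer(height), coords = coords
  ), class = c("grid_env", "cml_env"))
}

#' Sample exploration random walks
#'
#' Performs `n_walks` random walks of `walk_len` steps from uniformly random
#' starting nodes, picking at each step a uniformly random afforded action,
#' and returns the chained (observation, action, next-observation) transitions
#' as a replay buffer. Edges listed in `holdout_edges` are never traversed;
#' a walk trapped with no afforded non-holdout action is truncated (recorded
#' in the buffer's metadata). A warning is raised if some observation is
#' never visited, since the embeddings of unvisited observations cannot be
#' learned.
#'
#' @param env a discrete environment.
#' @param n_walks,walk_len number and length (in steps) of walks.
#' @param seed integer seed.
#' @param holdout_edges optional 2-column matrix of node pairs (undirected)
#'   to exclude from exploration.
#' @return a `replay_buffer`: list with `$transitions` (data.frame `walk`,
#'   `from`, `action`, `to`), dimensions, `$seed` and `$truncated`.
#' @export
sample_exploration <- function(env, n_walks, walk_len, seed = 1L,
                               holdout_edges = NULL) {
  stopifnot(n_walks >= 1, walk_len >= 1)
  local_seed(seed)
  hold_ids <- holdout_edge_ids(env, holdout_edges)
  blocked <- matrix(FALSE, env$n_obs, env$n_a)
  if (length(hold_ids))
    blocked <- !is.na(env$edge_id) & matrix(env$edge_id %in% hold_ids,
                                            env$n_obs, env$n_a)
  walks <- vector("list", n_walks)
  truncated <- integer(0)
  for (w in seq_len(n_walks)) {
    node <- sample.int(env$n_obs, 1L)
    from <- integer(walk_len); act <- integer(walk_len); to <- integer(walk_len)
    steps <- 0L
    for (k in seq_len(walk_len)) {
      avail <- which(env$afford[node, ] > 0 & !blocked[node, ])
      if (!length(avail)) { truncated <- c(truncated, w); break }
      a <- sample_one(avail)
      nxt <- env$nbr[node, a]
      steps <- steps + 1L
      from[steps] <- node; act[steps] <- a; to[steps] <- nxt
      node <- nxt
    }
    walks[[w]] <- data.frame(walk = w, from = from[seq_len(steps)],
                             action = act[seq_len(steps)],
                             to = to[seq_len(steps)])
  }
  tr <- do.call(rbind, walks)
  visited <- unique(c(tr$from, tr$to))
  if (length(visited) < env$n_obs)
    warning(sprintf("%d observation(s) never visited during exploration",
                    env$n_obs - length(visited)))
  structure(list(transitions = tr, n_obs = env$n_obs, n_a = env$n_a,
                 seed = as.integer(seed), truncated = truncated,
                 holdout_edges = holdout_edges),
            class = "replay_buffer")
}

holdout_edge_ids <- function(env, holdout_edges) {
  if (is.null(holdout_edges)) return(integer(0))
  holdout_edges <- matrix(as.integer(holdout_edges), ncol = 2)
  ids <- match(edge_key(pmin(holdout_edges[, 1], holdout_edges[, 2]),
                        pmax(holdout_edges[, 1], holdout_edges[, 2])),
               edge_key_set(env$edges))
  if (anyNA(ids)) stop("holdout pair is not an edge of the environment")
  ids
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat(sprintf("<replay_buffer> %d transitions in %d walks (%d truncated)\n",
              nrow(x$transitions), max(x$transitions$walk),
              length(x$truncated)))
  invisible(x)
}

#' Sample a grid exploration protocol with held-out edges
#'
#' Reproduces the partial-exploration protocol for 2D mazes: a seeded set of
#' `n_holdout` edges is held out, and short random walks are sampled that
#' never traverse them. The draw is retried (deterministically, from the
#' seed) until every cell is visited and every action occurs at least once,
#' so the environment remains learnable despite the unseen edges.
#'
#' @param env a grid environment.
#' @param n_walks,walk_len exploration budget (22 walks of length 3 emulate
#'   the sparse-maze protocol).
#' @param n_holdout number of held-out edges.
#' @param seed integer seed.
#' @param max_retries bound on redraws.
#' @return a `replay_buffer` whose `$holdout_edges` records the held-out node
#'   pairs.
#' @export
sample_grid_exploration <- function(env, n_walks = 22, walk_len = 3,
                                    n_holdout = 4, seed = 1L,
                                    max_retries = 200L) {
  stopifnot(inherits(env, "grid_env"), n_holdout < nrow(env$edges))
  for (try in seq_len(max_retries)) {
    sub_seed <- (seed + 7919L * try) %% .Machine$integer.max
    local_seed(sub_seed)
    hold <- env$edges[sample.int(nrow(env$edges), n_holdout), , drop = FALSE]
    buf <- withCallingHandlers(
      sample_exploration(env, n_walks, walk_len, seed = sub_seed + 1L,
                         holdout_edges = hold),
      warning = function(w) invokeRestart("muffleWarning"))
    tr <- buf$transitions
    if (length(unique(c(tr$from, tr$to))) == env$n_obs &&
        length(unique(tr$action)) == env$n_a &&
        !length(buf$truncated))
      return(buf)
  }
  stop("could not find a learnable exploration draw; relax the budget")
}
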