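#' Discrete environments
#'
#' All discrete environments (abstract graphs and 2D grids) share one internal
#' representation: `n_obs` observations (nodes/cells), `n_a` actions, and three
#' `n_obs x n_a` lookup tables — `nbr` (the node an action leads to, `NA` if
#' the action is unavailable there), `afford` (affordance values in `[0, 1]`,
#' 0 where unavailable) and `edge_id` (the undirected edge an action
#' traverses). For abstract graphs every directed edge traversal is its own
#' action (two actions per edge, each afforded at exactly one node); for grids
#' the actions are state-invariant moves afforded everywhere except across the
#' boundary.
#'
#' @name cml_env
#' @keywords internal
NULL

new_graph_env <- function(edges, n_nodes, costs = NULL, afford_enter = NULL,
                          kind = "graph") {
  edges <- validate_edges(edges, n_nodes)
  m <- nrow(edges)
  n_a <- 2L * m
  nbr <- matrix(NA_integer_, n_nodes, n_a)
  afford <- matrix(0, n_nodes, n_a)
  edge_id <- matrix(NA_integer_, n_nodes, n_a)
  if (!is.null(costs)) {
    stopifnot(length(costs) == m, all(costs > 0))
    g_val <- 1 / costs
  } else {
    g_val <- rep(1, m)
  }
  # affordance of entering a node may be overridden (virtual-goal rewards)
  for (e in seq_len(m)) {
    u <- edges[e, 1]; v <- edges[e, 2]
    a_uv <- 2L * e - 1L; a_vu <- 2L * e
    nbr[u, a_uv] <- v; nbr[v, a_vu] <- u
    afford[u, a_uv] <- if (is.null(afford_enter)) g_val[e] else afford_enter[e]
    afford[v, a_vu] <- g_val[e]
    edge_id[u, a_uv] <- e; edge_id[v, a_vu] <- e
  }
  structure(list(
    n_obs = as.integer(n_nodes), n_a = n_a,
    nbr = nbr, afford = afford, edge_id = edge_id,
    edges = edges, costs = costs, kind = kind
  ), class = c("graph_env", "cml_env"))
}

validate_edges <- function(edges, n_nodes) {
  edges <- matrix(as.integer(edges), ncol = 2)
  stopifnot(all(edges >= 1), all(edges <= n_nodes))
  edges <- t(apply(edges, 1, sort))
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) stop("duplicate edges")
  ig <- env_igraph_from_edges(edges, n_nodes)
  if (!igraph::is_connected(ig)) stop("graph is not connected")
  edges
}

env_igraph_from_edges <- function(edges, n_nodes) {
  igraph::graph_from_edgelist(edges, directed = FALSE) +
    igraph::vertices(setdiff(seq_len(n_nodes), unique(as.vector(edges))))
}

env_igraph <- function(env) env_igraph_from_edges(env$edges, env$n_obs)

#' @export
print.cml_env <- function(x, ...) {
  cat(sprintf("<%s> %d observations, %d actions, %d edges%s\n",
              class(x)[1], x$n_obs, x$n_a,
              if (is.null(x$edges)) NA_integer_ else nrow(x$edges),
              if (is.null(x$costs)) "" else " (weighted)"))
  invisible(x)
}

#' Environment interface
#'
#' `affordances()` returns the affordance vector of a node; `step_env()`
#' executes an action and returns the successor node; `env_diameter()` returns
#' the graph diameter (longest shortest path).
#'
#' @param env a discrete environment.
#' @param node node (observation) index.
#' @param action action index.
#' @return `affordances`: numeric vector of length `env$n_a`; `step_env`: the
#'   successor node index.
#' @export
affordances <- function(env, node) {
  stopifnot(node >= 1, node <= env$n_obs)
  env$afford[node, ]
}

#' @rdname affordances
#' @export
step_env <- function(env, node, action) {
  stopifnot(action >= 1, action <= env$n_a)
  to <- env$nbr[node, action]
  if (is.na(to)) stop(sprintf("action %d is not afforded at node %d",
                              action, node))
  to
}

#' @rdname affordances
#' @export
env_diameter <- function(env) {
  ig <- env_igraph(env)
  as.integer(igraph::diameter(ig, weights = NA))
}

edge_cost <- function(env, eid) {
  if (is.null(env$costs)) 1 else env$costs[eid]
}

#' Generate a degree-constrained connected random graph
#'
#' Builds a connected simple graph on `n_nodes` nodes in which every node's
#' degree lies in `[deg_min, deg_max]`: a uniformly random attachment spanning
#' tree is drawn first, then random edges are added until every node reaches
#' `deg_min`, rejecting any addition that would push a node past `deg_max`.
#' Constructions that get stuck (or whose tree already violates `deg_max`)
#' are retried up to `max_retries` times.
#'
#' @param n_nodes number of nodes (>= 3 for the defaults).
#' @param deg_min,deg_max inclusive degree bounds.
#' @param seed integer seed; the same seed reproduces the same graph.
#' @param max_retries bound on construction restarts.
#' @return a graph environment (see [affordances()]).
#' @export
generate_random_graph <- function(n_nodes, deg_min = 2, deg_max = 5,
                                  seed = 1L, max_retries = 100L) {
  stopifnot(n_nodes >= 2, deg_min >= 1, deg_max >= deg_min)
  if (deg_min > n_nodes - 1)
    stop("infeasible: deg_min exceeds n_nodes - 1")
  if (n_nodes == 2 && deg_min >= 2)
    stop("infeasible: no simple graph on 2 nodes has degree >= 2")
  local_seed(seed)
  for (try in seq_len(max_retries)) {
    edges <- random_tree_edges(n_nodes)
    deg <- tabulate(edges, n_nodes)
    if (max(deg) > deg_max) next
    adj <- edge_key_set(edges)
    ok <- TRUE
    guard <- 0L
    while (any(deg < deg_min)) {
      guard <- guard + 1L
      if (guard > 50L * n_nodes) { ok <- FALSE; break }
      u <- sample_one(which(deg < deg_min))
      cand <- setdiff(which(deg < deg_max), u)
      cand <- cand[!(edge_key(pmin(u, cand), pmax(u, cand)) %in% adj)]
      if (!length(cand)) { ok <- FALSE; break }
      v <- sample_one(cand)
      edges <- rbind(edges, c(min(u, v), max(u, v)))
      adj <- c(adj, edge_key(min(u, v), max(u, v)))
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    }
    if (ok) return(new_graph_env(edges, n_nodes, kind = "random"))
  }
  stop("could not generate a graph with the requested degree bounds")
}

random_tree_edges <- function(n_nodes) {
  ord <- sample.int(n_nodes)
  edges <- matrix(0L, n_nodes - 1L, 2L)
  for (i in 2:n_nodes) {
    parent <- ord[sample.int(i - 1L, 1L)]
    edges[i - 1L, ] <- sort(c(parent, ord[i]))
  }
  edges
}

edge_key <- function(u, v) u * 1e6 + v
edge_key_set <- function(edges) edge_key(edges[, 1], edges[, 2])
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Generate a small-world cluster graph
#'
#' `k_clusters` complete subgraphs ("clusters") of `cluster_size` nodes each,
#' joined by exactly one bridge edge between consecutive clusters; gateway
#' nodes are chosen at random. `topology = "ring"` also bridges the last
#' cluster back to the first.
#'
#' @param k_clusters number of clusters (>= 2).
#' @param cluster_size nodes per cluster (>= 2).
#' @param topology `"chain"` or `"ring"`.
#' @param seed integer seed.
#' @return a graph environment.
#' @export
generate_small_world <- function(k_clusters = 4, cluster_size = 6,
                                 topology = c("chain", "ring"), seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(k_clusters >= 2, cluster_size >= 2)
  local_seed(seed)
  n_nodes <- k_clusters * cluster_size
  members <- split(seq_len(n_nodes),
                   rep(seq_len(k_clusters), each = cluster_size))
  edges <- do.call(rbind, lapply(members, function(mm) t(utils::combn(mm, 2))))
  n_bridges <- if (topology == "ring") k_clusters else k_clusters - 1L
  for (b in seq_len(n_bridges)) {
    c1 <- b
    c2 <- if (b == k_clusters) 1L else b + 1L
    u <- sample_one(members[[c1]])
    v <- sample_one(members[[c2]])
    edges <- rbind(edges, sort(c(u, v)))
  }
  new_graph_env(edges, n_nodes, kind = "small_world")
}

#' Generate a challenge graph: dead ends or multiple equal paths
#'
#' `kind = "dead_end"`: a backbone cycle of `backbone_len` nodes with
#' `n_pendants` pendant chains of `pendant_len` nodes attached at random
#' backbone nodes — every pendant tip is a dead end. `kind = "multi_path"`:
#' a `rows x cols` lattice ("ladder") graph, which contains many pairs of
#' nodes joined by multiple vertex-disjoint shortest paths.
#'
#' @param kind `"dead_end"` or `"multi_path"`.
#' @param backbone_len,n_pendants,pendant_len dead-end parameters.
#' @param rows,cols multi-path lattice size.
#' @param seed integer seed (placement of pendants).
#' @return a graph environment.
#' @export
generate_challenge_graph <- function(kind = c("dead_end", "multi_path"),
                                     backbone_len = 6, n_pendants = 3,
                                     pendant_len = 2, rows = 2, cols = 4,
                                     seed = 1L) {
  kind <- match.arg(kind)
  local_seed(seed)
  if (kind == "dead_end") {
    stopifnot(backbone_len >= 3, n_pendants >= 1, pendant_len >= 1)
    bb <- seq_len(backbone_len)
    edges <- cbind(bb, c(bb[-1], 1L))          # backbone cycle
    nxt <- backbone_len
    anchors <- sample(bb, n_pendants, replace = n_pendants > backbone_len)
    for (a in anchors) {
      prev <- a
      for (k in seq_len(pendant_len)) {
        nxt <- nxt + 1L
        edges <- rbind(edges, sort(c(prev, nxt)))
        prev <- nxt
      }
    }
    new_graph_env(edges, nxt, kind = "dead_end")
  } else {
    stopifnot(rows >= 2, cols >= 2)
    id <- function(r, c) (r - 1L) * cols + c
    edges <- NULL
    for (r in seq_len(rows)) for (c in seq_len(cols)) {
      if (c < cols) edges <- rbind(edges, c(id(r, c), id(r, c + 1L)))
      if (r < rows) edges <- rbind(edges, c(id(r, c), id(r + 1L, c)))
    }
    new_graph_env(edges, rows * cols, kind = "multi_path")
  }
}

#' Assign random integer costs to a graph's edges
#'
#' Each edge receives a cost drawn uniformly from `cost_values`; both directed
#' traversals of an edge share its cost. The affordance of every action
#' becomes the reciprocal of its edge cost, which biases the winner-take-all
#' action selection toward cheap edges.
#'
#' @param env an unweighted graph environment.
#' @param cost_values vector of positive costs to sample from.
#' @param seed integer seed.
#' @return the weighted graph environment.
#' @export
assign_edge_costs <- function(env, cost_values = 4:7, seed = 1L) {
  stopifnot(inherits(env, "graph_env"))
  if (!is.null(env$costs)) stop("environment already has edge costs")
  if (any(cost_values <= 0)) stop("costs must be positive")
  local_seed(seed)
  costs <- sample(cost_values, nrow(env$edges), replace = TRUE)
  new_graph_env(env$edges, env$n_obs, costs = costs, kind = env$kind)
}

#' Reduce a best-reward task to goal reaching via a virtual goal node
#'
#' Appends one virtual node with an edge from every terminal node. The
#' affordance of entering the virtual node from terminal `i` is proportional
#' to `rewards[i]` (scaled so the best terminal has affordance 1), so planning
#' to the virtual goal prefers ending in highly rewarded terminals. All
#' pre-existing edges keep their affordances.
#'
#' @param env a graph environment.
#' @param terminal_nodes node indices that terminate the decision process.
#' @param rewards positive rewards, one per terminal.
#' @return the augmented environment; the virtual goal is node
#'   `env$n_obs + 1` of the input (`attr(out, "virtual_goal")`).
#' @export
add_virtual_goal <- function(env, terminal_nodes, rewards) {
  stopifnot(inherits(env, "graph_env"), length(terminal_nodes) >= 1,
            length(rewards) == length(terminal_nodes), all(rewards > 0))
  if (any(terminal_nodes < 1 | terminal_nodes > env$n_obs))
    stop("unknown terminal node")
  vg <- env$n_obs + 1L
  new_edges <- cbind(as.integer(terminal_nodes), vg)
  edges <- rbind(env$edges, new_edges)
  m_old <- nrow(env$edges)
  costs <- if (is.null(env$costs)) rep(1, m_old) else env$costs
  costs <- c(costs, rep(1, length(terminal_nodes)))
  enter <- c(1 / costs[seq_len(m_old)], rewards / max(rewards))
  out <- new_graph_env(edges, vg, costs = costs, afford_enter = enter,
                       kind = "virtual_goal")
  attr(out, "virtual_goal") <- vg
  out
}

#' Read / write a plain-text edge list
#'
#' One edge per line, `u<TAB>v[<TAB>cost]`, node ids 0-based, undirected.
#' The reader validates simplicity and connectivity and returns a graph
#' environment; the writer round-trips.
#'
#' @param path file path.
#' @param env a graph environment.
#' @return `read_edgelist`: a graph environment; `write_edgelist`: `path`,
#'   invisibly.
#' @export
read_edgelist <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE)
  if (!ncol(tab) %in% c(2L, 3L)) stop("expected 2 or 3 tab-separated columns")
  edges <- as.matrix(tab[, 1:2]) + 1L
  costs <- if (ncol(tab) == 3L) tab[[3]] else NULL
  new_graph_env(edges, max(edges), costs = costs, kind = "file")
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(env, path) {
  stopifnot(inherits(env, "graph_env"))
  tab <- data.frame(u = env$edges[, 1] - 1L, v = env$edges[, 2] - 1L)
  if (!is.null(env$costs)) tab$cost <- env$costs
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
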