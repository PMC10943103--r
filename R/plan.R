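#' Plan online from a start to a goal observation
#'
#' Iterates the online planning loop: form the goal direction
#' \eqn{d_t = Q o^* - Q o_t}, compute utilities, gate them by the
#' environment's affordances (and, optionally, by a per-episode ban on
#' re-selecting an already-used action), pick the winner-take-all action, and
#' step the environment — until the goal observation is reached or
#' `max_steps` is exhausted. No learning happens during planning unless
#' `learn_during_planning` is set.
#'
#' @param model a trained [cml()] model.
#' @param env a discrete environment.
#' @param start,goal node indices.
#' @param max_steps step cap; by default 4 x the graph diameter. An episode
#'   hitting the cap counts as a failure.
#' @param use_w use the learned `W` for utilities (default) instead of `t(V)`.
#' @param learn_during_planning apply plasticity to each experienced
#'   transition while planning.
#' @param forbid_repeat_action disallow selecting the same action twice in
#'   this episode (used for weighted graphs, where reciprocal-cost gating can
#'   otherwise induce loops).
#' @return a `plan_result`: list with `$start`, `$goal`, `$actions`,
#'   `$observations` (node sequence incl. start), `$reached`, `$n_steps`,
#'   `$total_cost` (summed traversed edge costs; equals `n_steps` when
#'   unweighted), `$trace` (a per-step data.frame) and, if learning was on,
#'   `$model`.
#' @export
plan_online <- function(model, env, start, goal,
                        max_steps = 4L * env_diameter(env),
                        use_w = TRUE, learn_during_planning = FALSE,
                        forbid_repeat_action = FALSE) {
  stopifnot(inherits(model, "cml"), inherits(env, "cml_env"),
            model$n_o == env$n_obs, model$n_a == env$n_a,
            start >= 1, start <= env$n_obs, goal >= 1, goal <= env$n_obs)
  s_goal <- model$Q[, goal]
  node <- start
  used <- rep(FALSE, env$n_a)
  actions <- integer(0)
  nodes <- node
  total_cost <- 0
  trace <- vector("list", max_steps)
  step <- 0L
  while (node != goal && step < max_steps) {
    g <- env$afford[node, ]
    if (forbid_repeat_action) g[used] <- 0
    if (!any(g > 0)) break
    d <- s_goal - model$Q[, node]
    u <- compute_utilities(model, d, use_w = use_w)
    a <- which.max(ifelse(g > 0, u * g, -Inf))
    nxt <- env$nbr[node, a]
    step <- step + 1L
    trace[[step]] <- data.frame(step = step, node_from = node,
                                action_index = a, node_to = nxt,
                                utility_of_chosen = u[a],
                                n_afforded = sum(g > 0))
    if (learn_during_planning) {
      model <- apply_plasticity(model, onehot(node, model$n_o),
                                onehot(a, model$n_a), onehot(nxt, model$n_o))
      s_goal <- model$Q[, goal]
    }
    total_cost <- total_cost + edge_cost(env, env$edge_id[node, a])
    used[a] <- TRUE
    actions <- c(actions, a)
    nodes <- c(nodes, nxt)
    node <- nxt
  }
  res <- structure(list(
    start = start, goal = goal, actions = actions, observations = nodes,
    reached = node == goal, n_steps = step, total_cost = total_cost,
    trace = if (step) do.call(rbind, trace[seq_len(step)]) else
      data.frame(step = integer(0), node_from = integer(0),
                 action_index = integer(0), node_to = integer(0),
                 utility_of_chosen = numeric(0), n_afforded = integer(0))
  ), class = "plan_result")
  if (learn_during_planning) res$model <- model
  res
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf("<plan_result> %d -> %d: %s in %d step(s), cost %g\n",
              x$start, x$goal,
              if (x$reached) "reached" else "NOT reached",
              x$n_steps, x$total_cost))
  invisible(x)
}

#' Write a plan trace to CSV
#'
#' @param plan a `plan_result` from [plan_online()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_plan_trace <- function(plan, path) {
  utils::write.csv(plan$trace, path, row.names = FALSE)
  invisible(path)
}
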