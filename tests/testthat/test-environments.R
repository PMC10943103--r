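test_that("random graphs respect degree bounds, connectivity and seeding", {
  env <- generate_random_graph(32, 2, 5, seed = 11)
  deg <- tabulate(env$edges, 32)
  expect_true(all(deg >= 2 & deg <= 5))
  ig <- cmlearn:::env_igraph(env)
  expect_true(igraph::is_connected(ig))
  expect_true(igraph::is_simple(ig))
  expect_equal(env$n_a, 2L * nrow(env$edges))
  env2 <- generate_random_graph(32, 2, 5, seed = 11)
  expect_identical(env2$edges, env$edges)
  expect_error(generate_random_graph(2, 2, 5), "infeasible")
})

test_that("action indices map bijectively onto directed edge traversals", {
  env <- generate_random_graph(16, 2, 4, seed = 3)
  hits <- matrix(FALSE, env$n_obs, env$n_a)
  for (u in seq_len(env$n_obs)) for (a in which(env$afford[u, ] > 0)) {
    v <- step_env(env, u, a)
    eid <- env$edge_id[u, a]
    expect_true(all(sort(c(u, v)) == env$edges[eid, ]))
    hits[u, a] <- TRUE
  }
  # every action is afforded at exactly one node
  expect_equal(unname(colSums(hits)), rep(1, env$n_a))
  expect_error(step_env(env, 1, which(env$afford[1, ] == 0)[1]),
               "not afforded")
})

test_that("small-world clusters are cliques joined by single bridges", {
  env <- generate_small_world(4, 6, "chain", seed = 2)
  expect_equal(env$n_obs, 24L)
  expect_equal(nrow(env$edges), 4 * choose(6, 2) + 3)
  tiny <- generate_small_world(2, 2, "chain", seed = 1)
  expect_equal(nrow(tiny$edges), 3L)
  ring <- generate_small_world(4, 4, "ring", seed = 5)
  expect_equal(nrow(ring$edges), 4 * choose(4, 2) + 4)
  expect_error(generate_small_world(1, 6), "k_clusters")
})

test_that("challenge graphs have the advertised structure", {
  de <- generate_challenge_graph("dead_end", backbone_len = 6,
                                 n_pendants = 3, pendant_len = 2, seed = 4)
  expect_equal(de$n_obs, 12L)
  deg <- tabulate(de$edges, de$n_obs)
  expect_equal(sum(deg == 1), 3L)   # three pendant tips
  mp <- generate_challenge_graph("multi_path", rows = 2, cols = 4, seed = 1)
  # two vertex-disjoint shortest paths between opposite corners of a ladder
  D <- dijkstra_distances(mp, weighted = FALSE)
  expect_equal(D[1, 8], 4)
  ig <- cmlearn:::env_igraph(mp)
  paths <- igraph::all_shortest_paths(ig, 1, 8)$res
  expect_gte(length(paths), 2)
  de2 <- generate_challenge_graph("dead_end", backbone_len = 6,
                                  n_pendants = 3, pendant_len = 2, seed = 4)
  expect_identical(de2$edges, de$edges)
})

test_that("edge costs come from the requested set and set affordances to 1/cost", {
  env <- generate_random_graph(16, 2, 4, seed = 5)
  w <- assign_edge_costs(env, 4:7, seed = 6)
  expect_true(all(w$costs %in% 4:7))
  for (u in seq_len(w$n_obs)) for (a in which(w$afford[u, ] > 0))
    expect_equal(w$afford[u, a], 1 / w$costs[w$edge_id[u, a]])
  # unit costs reduce to the unweighted case
  u1 <- assign_edge_costs(env, 1, seed = 6)
  expect_equal(u1$afford, env$afford)
  expect_error(assign_edge_costs(w, 4:7), "already")
  expect_error(assign_edge_costs(env, c(0, 1)), "positive")
})

test_that("virtual goal node encodes rewards as entry affordances", {
  # 2-step binary decision tree: root 1, mid 2-3, leaves 4-7
  edges <- rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(3, 6), c(3, 7))
  env <- cmlearn:::new_graph_env(edges, 7)
  aug <- add_virtual_goal(env, 4:7, rewards = c(1, 1, 1, 1))
  expect_equal(aug$n_obs, 8L)
  expect_equal(nrow(aug$edges), 10L)
  vg <- attr(aug, "virtual_goal")
  enter <- sapply(4:7, function(u) {
    a <- which(aug$nbr[u, ] == vg)
    aug$afford[u, a]
  })
  expect_equal(enter, rep(1, 4))
  # a dominant reward pulls the planner through that leaf
  aug2 <- add_virtual_goal(env, 4:7, rewards = c(1, 1, 10, 1))
  model <- cml(aug2$n_obs, aug2$n_a, 400, seed = 12)
  buf <- sample_exploration(aug2, 80, 8, seed = 13)
  model <- train_on_replay(model, buf, rounds = 10)$model
  p <- plan_online(model, aug2, 1, attr(aug2, "virtual_goal"),
                   forbid_repeat_action = TRUE)
  expect_true(p$reached)
  # brute force: best-reward 2-step path exits through leaf 6
  expect_true(6 %in% p$observations)
  expect_error(add_virtual_goal(env, 99, 1), "unknown")
})

test_that("grids enumerate cells row-major with boundary-gated actions", {
  g <- generate_grid("rect", 4, 4)
  expect_equal(g$n_obs, 16L)
  expect_equal(g$n_a, 4L)
  expect_equal(sum(g$afford[1, ]), 2)           # corner affords 2 moves
  expect_equal(sum(g$afford[6, ]), 4)           # interior affords all 4
  # east at the east boundary is blocked
  east_blocked <- which(g$coords[, "col"] == 3)
  expect_true(all(g$afford[east_blocked, 2] == 0))
  # stepping east from cell 1 lands on cell 2
  expect_equal(step_env(g, 1, 2), 2L)
  h <- generate_grid("hex", 3, 3)
  expect_equal(h$n_a, 6L)
  centre <- which(h$coords[, "q"] == 1 & h$coords[, "r"] == 1)
  expect_equal(sum(h$afford[centre, ]), 6)
  expect_error(generate_grid("rect", 1, 4), "width")
})

test_that("exploration walks chain correctly and honour holdout edges", {
  env <- generate_random_graph(32, 2, 5, seed = 20)
  buf <- sample_exploration(env, 200, 32, seed = 21)
  tr <- buf$transitions
  expect_lte(nrow(tr), 6400)
  for (w in unique(tr$walk)) {
    wt <- tr[tr$walk == w, ]
    if (nrow(wt) > 1)
      expect_equal(wt$from[-1], wt$to[-nrow(wt)])
  }
  # transitions follow the environment's action map
  expect_equal(env$nbr[cbind(tr$from, tr$action)], tr$to)
  # reproducibility
  buf2 <- sample_exploration(env, 200, 32, seed = 21)
  expect_identical(buf2$transitions, tr)
  # holdout edges are never traversed
  g <- generate_grid("rect", 4, 4)
  hold <- g$edges[c(1, 5, 9), ]
  bh <- suppressWarnings(
    sample_exploration(g, 22, 3, seed = 22, holdout_edges = hold))
  eids <- g$edge_id[cbind(bh$transitions$from, bh$transitions$action)]
  expect_false(any(eids %in% cmlearn:::holdout_edge_ids(g, hold)))
  expect_equal(nrow(bh$transitions), 66L)
})

test_that("isolating a node by holdout raises a learnability warning", {
  # cut all edges at one corner cell of a grid
  g <- generate_grid("rect", 3, 3)
  corner_edges <- g$edges[rowSums(g$edges == 1) > 0, ]
  expect_warning(sample_exploration(g, 10, 3, seed = 1,
                                    holdout_edges = corner_edges),
                 "never visited")
})

test_that("grid exploration protocol covers all cells and actions", {
  g <- generate_grid("rect", 4, 4)
  buf <- sample_grid_exploration(g, 22, 3, n_holdout = 4, seed = 31)
  tr <- buf$transitions
  expect_setequal(unique(c(tr$from, tr$to)), 1:16)
  expect_setequal(unique(tr$action), 1:4)
  expect_equal(nrow(buf$holdout_edges), 4L)
  eids <- g$edge_id[cbind(tr$from, tr$action)]
  expect_false(any(eids %in% cmlearn:::holdout_edge_ids(g,
                                                        buf$holdout_edges)))
})

test_that("edge lists round-trip through the tab-separated format", {
  env <- assign_edge_costs(generate_random_graph(12, 2, 4, seed = 2), 4:7,
                           seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(env, path)
  env2 <- read_edgelist(path)
  expect_identical(env2$edges, env$edges)
  expect_equal(env2$costs, env$costs)
  expect_equal(env2$afford, env$afford)
  # malformed input is rejected
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t1", "0\t1"), bad)
  expect_error(read_edgelist(bad), "duplicate")
})
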