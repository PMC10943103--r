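test_that("action remapping is the binary expansion of the index", {
  expect_equal(remap_action(0, 8), rep(-0.1, 8))
  expect_equal(remap_action(255, 8), rep(0.1, 8))
  r5 <- remap_action(5, 8)           # binary 00000101
  expect_equal(which(r5 > 0), c(1L, 3L))
  expect_equal(which(r5 < 0), c(2L, 4:8))
  expect_error(remap_action(256, 8), "index")
  # bijection between indices and sign patterns
  pats <- sapply(0:15, function(i) paste(sign(remap_action(i, 4)),
                                         collapse = ","))
  expect_equal(anyDuplicated(pats), 0L)
})

test_that("target observations overwrite exactly the requested fields", {
  o <- c(x = 1, y = 2, vx = 0.1, vy = -0.2)
  expect_equal(make_target_observation(o), o)
  t1 <- make_target_observation(o, list(x = 20, y = 0))
  expect_equal(unname(t1), c(20, 0, 0.1, -0.2))
  expect_equal(sum(t1 != o), 2)
  t2 <- make_target_observation(o, list(x = 5))
  expect_equal(sum(t2 != o), 1)
  # numeric-index targeting for schema-less vectors
  t3 <- make_target_observation(1:5, stats::setNames(list(99), "3"))
  expect_equal(t3[3], 99)
  expect_error(make_target_observation(o, list(nope = 1)), "unknown")
})

test_that("the ant observation schema lists all 29 components", {
  sch <- ant_observation_schema()
  expect_length(sch, 29)
  expect_equal(sch[1:2], c("torso_x", "torso_y"))
  expect_equal(anyDuplicated(sch), 0L)
})

test_that("relative target transform rotates by the agent heading", {
  pos <- c(2, 3)
  tgt <- c(5, 3)
  expect_equal(relative_target_transform(pos, 0, tgt), tgt)
  # half turn: a target ahead appears behind
  behind <- relative_target_transform(pos, pi, tgt)
  expect_equal(behind, c(-1, 3), tolerance = 1e-12)
  # quarter turn: target at (0, 1) offset becomes (1, 0) offset
  q <- relative_target_transform(c(0, 0), pi / 2, c(0, 1))
  expect_equal(q, c(1, 0), tolerance = 1e-12)
})

test_that("reconstruction regularization strictly reduces the error", {
  # orthonormal rows already reconstruct: update vanishes
  m <- cml(2, 4, 8, seed = 71)
  m$Q <- qr.Q(qr(matrix(rnorm(16), 8, 2)))
  o <- c(0.3, -0.7)
  m2 <- reconstruction_regularize(m, o, eta = 0.1)
  expect_equal(m2$Q, m$Q, tolerance = 1e-12)
  # zero rate: no change
  m3 <- cml(1, 2, 2, seed = 72)
  expect_equal(reconstruction_regularize(m3, 0.5, eta = 0)$Q, m3$Q)
  # scalar observation: error strictly decreases over 100 steps
  m4 <- cml(1, 2, 2, sigma_q = 0.2, seed = 73)
  err <- function(m) abs(0.5 - drop(crossprod(m$Q, m$Q %*% 0.5)))
  errs <- numeric(100)
  for (k in 1:100) {
    errs[k] <- err(m4)
    m4 <- reconstruction_regularize(m4, 0.5, eta = 0.05)
  }
  expect_true(all(diff(errs) < 0))
})

test_that("joint-limit affordances ramp near the limits and average over joints", {
  tab <- do.call(rbind, lapply(0:3, function(i) sign(remap_action(i, 2))))
  # all joints mid-range: every composite action scores 1
  g <- joint_limit_affordance(c(0, 0), c(-1, -1), c(1, 1), tab)
  expect_equal(g, rep(1, 4))
  # joint 1 at its upper limit: raising it scores 0 for that joint
  g2 <- joint_limit_affordance(c(1, 0), c(-1, -1), c(1, 1), tab)
  up1 <- tab[, 1] > 0
  expect_equal(g2[up1], rep(0.5, 2))    # mean(0, 1) across the two joints
  expect_equal(g2[!up1], rep(1, 2))
  expect_error(joint_limit_affordance(0, 1, 1, tab[, 1, drop = FALSE]),
               "degenerate")
  expect_warning(joint_limit_affordance(c(2, 0), c(-1, -1), c(1, 1), tab),
                 "clamping")
})

test_that("point-mass dynamics are damped, deterministic and monotone", {
  env <- pointmass_env(damping = 0)
  o <- env$reset()
  # constant east force with no damping: x strictly increases
  xs <- numeric(10)
  for (k in 1:10) {
    o <- env$step(o, 1)
    xs[k] <- o[1]
  }
  expect_true(all(diff(c(0, xs)) > 0))
  expect_equal(unname(o[2]), 0, tolerance = 1e-12)
  # determinism
  env2 <- pointmass_env(damping = 0)
  o2 <- env2$reset()
  for (k in 1:10) o2 <- env2$step(o2, 1)
  expect_identical(o2, o)
  expect_equal(env$affordances(o), rep(1, 8))
})

test_that("babbling produces chained transitions within episodes", {
  env <- pointmass_env()
  bb <- babble(env, n_episodes = 4, ep_len = 5, seed = 74)
  expect_equal(ncol(bb$obs), 20)
  expect_true(all(bb$actions %in% 1:8))
  # within an episode, o_next chains to the next o
  expect_equal(bb$obs[, 2], bb$obs_next[, 1])
  # episode boundary resets to the origin
  expect_equal(unname(bb$obs[, 6]), c(0, 0, 0, 0))
  bb2 <- babble(env, n_episodes = 4, ep_len = 5, seed = 74)
  expect_identical(bb2, bb)
})

test_that("babbling-trained control homes in on goals it never saw", {
  res <- run_preset("pointmass", seed = 3)
  frac <- res$control$final_distance / res$control$initial_distance
  expect_lt(mean(frac), 0.1)
  expect_equal(nrow(res$control), 8)
})
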