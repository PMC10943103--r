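# Shared fixtures. Heavy objects are trained once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a 4-cycle graph: 1-2-3-4-1
cycle4_env <- function() {
  cmlearn:::new_graph_env(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4)
}

# small trained model on a 12-node random graph (fast stand-in for the
# full benchmark in unit tests)
small_trained <- function() {
  memo("small_trained", {
    env <- generate_random_graph(12, 2, 4, seed = 7)
    buf <- sample_exploration(env, 80, 16, seed = 8)
    model <- cml(env$n_obs, env$n_a, 300, seed = 9)
    fit <- train_on_replay(model, buf, rounds = 10)
    list(env = env, buffer = buf, model = fit$model, curve = fit$curve)
  })
}

# full 32-node benchmark pipeline (used by the acceptance tests)
benchmark32 <- function() {
  memo("benchmark32", run_preset("random32", seed = 1))
}

expect_onehot <- function(a, idx) {
  expect_equal(which(a == 1), idx)
  expect_equal(sum(a != 0), 1L)
}
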