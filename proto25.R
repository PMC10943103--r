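library(cmlearn)
ratio_for <- function(seed, rounds) {
  sds <- cmlearn:::derive_seeds(seed)
  cfg <- preset("weighted32", seed)
  env <- cmlearn:::build_env(cfg, sds[1])
  buf <- sample_exploration(env, 200, 32, seed = sds[3])
  m <- cml(env$n_obs, env$n_a, 1000, seed = sds[2])
  m <- train_on_replay(m, buf, rounds = rounds)$model
  s <- evaluate_planner(m, env, 1000, seed = sds[4], forbid_repeat_action = TRUE)
  c(s$mean_cost, s$oracle_mean, s$ratio)
}
for (seed in c(6, 9, 11)) {
  a <- ratio_for(seed, 10); b <- ratio_for(seed, 40)
  cat(sprintf("seed %d: rounds10 ratio %.3f cost %.2f | rounds40 ratio %.3f cost %.2f\n",
      seed, a[3], a[1], b[3], b[1]))
}
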