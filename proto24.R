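library(cmlearn)
sds <- cmlearn:::derive_seeds(6)
cfg <- preset("weighted32", 6)
env <- cmlearn:::build_env(cfg, sds[1])
buf <- sample_exploration(env, 200, 32, seed = sds[3])
m <- cml(env$n_obs, env$n_a, 1000, seed = sds[2])
m <- train_on_replay(m, buf, rounds = 10)$model
D <- dijkstra_distances(env, weighted = TRUE)
pairs <- cmlearn:::sample_eval_pairs(32, 1000, sds[4])
exc <- numeric(1000); steps <- integer(1000)
for (k in 1:1000) {
  p <- plan_online(m, env, pairs[k,1], pairs[k,2], forbid_repeat_action = TRUE)
  exc[k] <- p$total_cost - D[pairs[k,1], pairs[k,2]]
  steps[k] <- p$n_steps
}
cat("excess cost: mean", mean(exc), "\n")
print(table(cut(exc, c(-1,0.5,3,6,12,100))))
# an example bad trial
k <- which.max(exc)
p <- plan_online(m, env, pairs[k,1], pairs[k,2], forbid_repeat_action = TRUE)
cat("worst pair:", pairs[k,], "cost", p$total_cost, "opt", D[pairs[k,1],pairs[k,2]], "\n")
print(p$trace)
print(dijkstra(env, pairs[k,1], pairs[k,2])$path)
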