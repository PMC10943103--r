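library(cmlearn)
for (s in 1:5) {
  r <- run_preset("weighted32", seed = s)
  cat(sprintf("weighted seed %d: cost %.3f opt %.3f ratio %.3f succ %.3f\n",
      s, r$stats$mean_cost, r$stats$oracle_mean, r$stats$ratio, r$stats$success_rate))
}
for (nm in c("small_world", "dead_end", "multi_path")) for (s in 1:3) {
  r <- run_preset(nm, seed = s)
  cat(sprintf("%s seed %d: ratio %.4f succ %.3f\n", nm, s, r$stats$ratio, r$stats$success_rate))
}
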