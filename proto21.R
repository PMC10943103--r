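library(cmlearn)
for (s in 1:8) {
  sds <- cmlearn:::derive_seeds(s)
  env <- generate_random_graph(32, 2, 5, seed = sds[1])
  D <- dijkstra_distances(env, weighted = FALSE)
  ap <- mean(D[row(D) != col(D)])
  pairs <- cmlearn:::sample_eval_pairs(32, 1000, sds[4])
  cat(sprintf("seed %d: all-pairs %.3f  sampled-pairs %.3f edges %d\n",
      s, ap, mean(D[pairs]), nrow(env$edges)))
}
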