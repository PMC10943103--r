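library(cmlearn)
v <- sapply(1:30, function(s) {
  env <- generate_random_graph(32, 2, 5, seed = cmlearn:::derive_seeds(s)[1])
  D <- dijkstra_distances(env, weighted = FALSE)
  c(mean(D[row(D) != col(D)]), nrow(env$edges))
})
cat("derived seeds: mean SP", mean(v[1,]), "sd", sd(v[1,]), " mean edges", mean(v[2,]), "\n")
v2 <- sapply(1:30, function(s) {
  env <- generate_random_graph(32, 2, 5, seed = s)
  nrow(env$edges)
})
cat("raw seeds mean edges:", mean(v2), "\n")
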