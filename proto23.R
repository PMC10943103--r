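library(cmlearn)
cost <- c(); opt <- c()
for (s in 6:12) {
  r <- run_preset("weighted32", seed = s)
  cost <- c(cost, r$stats$mean_cost); opt <- c(opt, r$stats$oracle_mean)
  cat(sprintf("seed %d: cost %.3f opt %.3f ratio %.3f\n", s, r$stats$mean_cost,
      r$stats$oracle_mean, r$stats$ratio))
}
prev_cost <- c(20.435, 21.682, 22.088, 19.897, 19.261)
prev_opt <- c(19.391, 20.483, 20.657, 18.562, 18.208)
for (k in c(5, 8, 10)) {
  cc <- c(prev_cost, cost)[1:k]; oo <- c(prev_opt, opt)[1:k]
  cat(sprintf("first %d: cost %.3f opt %.3f\n", k, mean(cc), mean(oo)))
}
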