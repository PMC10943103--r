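suppressMessages(library(igraph)); library(cmlearn)
# package generator, all-pairs mean SP
v1 <- sapply(1:30, function(s) {
  env <- generate_random_graph(32, 2, 5, seed = s)
  D <- dijkstra_distances(env, weighted = FALSE)
  mean(D[row(D) != col(D)])
})
cat("attachment tree: mean", mean(v1), "sd", sd(v1), "range", range(v1), "\n")
# Prufer uniform tree variant
prufer_edges <- function(n) {
  pr <- sample.int(n, n - 2, replace = TRUE)
  deg <- rep(1L, n); for (x in pr) deg[x] <- deg[x] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_along(pr)) {
    leaf <- min(which(deg == 1L))
    edges[k, ] <- sort(c(leaf, pr[k]))
    deg[leaf] <- 0L; deg[pr[k]] <- deg[pr[k]] - 1L
  }
  edges[n - 1, ] <- sort(which(deg == 1L))
  edges
}
v2 <- sapply(1:30, function(s) {
  set.seed(s)
  repeat {
    edges <- prufer_edges(32)
    deg <- tabulate(edges, 32)
    if (max(deg) > 5) next
    adj <- paste(edges[,1], edges[,2]); ok <- TRUE
    while (any(deg < 2)) {
      u <- which(deg < 2); u <- if (length(u) == 1) u else sample(u, 1)
      cand <- setdiff(which(deg < 5), u)
      cand <- cand[!(paste(pmin(u,cand), pmax(u,cand)) %in% adj)]
      if (!length(cand)) { ok <- FALSE; break }
      v <- if (length(cand) == 1) cand else sample(cand, 1)
      edges <- rbind(edges, sort(c(u, v))); adj <- c(adj, paste(min(u,v), max(u,v)))
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    }
    if (ok) break
  }
  g <- graph_from_edgelist(edges, directed = FALSE)
  D <- distances(g)
  mean(D[row(D) != col(D)])
})
cat("prufer tree    : mean", mean(v2), "sd", sd(v2), "range", range(v2), "\n")
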