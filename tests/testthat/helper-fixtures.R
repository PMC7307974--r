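# shared fixtures built in code at test time

# brute-force symmetric closure of an edge list; oracle for neighborGraph
bruteAdjacencyMatrix <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1L]; j <- edges[k, 2L]
    A[i, j] <- 1L
    A[j, i] <- 1L
  }
  A
}

# random simple graph on n nodes with edge probability p
randomGraph <- function(n, p = 0.3) {
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  neighborGraph(n, pairs[keep, , drop = FALSE])
}

# constant-risk dataset: Y ~ Poisson(E * exp(logRisk)), E constant
flatDataset <- function(N, T, E = 50, logRisk = 0) {
  surveillanceCounts(matrix(rpois(N * T, E * exp(logRisk)), N, T),
                     matrix(E, N, T))
}

# brute-force FDR rule: search all candidate ranks k; oracle for
# bayesianFdrClassify
bruteFdr <- function(f, alpha) {
  fs <- sort(f)
  k <- 0L
  for (cand in seq_along(fs)) {
    if (mean(fs[seq_len(cand)]) < alpha) k <- cand
  }
  C <- if (k > 0L) fs[k] else 0
  list(k = k, C = C, flagged = if (k > 0L) which(f <= C) else integer())
}

shortConfig <- function(nIter = 600, seed = 1, nChains = 1) {
  mcmcConfig(nIter = nIter, burnIn = nIter / 2, thin = 1,
             nChains = nChains, seed = seed)
}
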