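# Shared fixture builders: small hand-specified networks, random
# networks/data, and brute-force oracles used across the suite.

# Network from an explicit edge list: edges = list(c("A", "B", 1), ...)
netFromEdges <- function(nodes, edges = list(), stimuli = character()) {
  a <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (e in edges) a[e[[1]], e[[2]]] <- as.integer(e[[3]])
  SignedNetwork(a, stimuli = stimuli)
}

# Unconstrained random signed adjacency (for IO/counting tests; no
# reachability demands).
randomAdjacency <- function(n, density = 0.3) {
  nodes <- paste0("N", seq_len(n))
  a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  off <- which(row(a) != col(a))
  hit <- off[runif(length(off)) < density]
  a[hit] <- sample(c(1L, -1L), length(hit), replace = TRUE)
  a
}

randomSignedNetwork <- function(n, density = 0.3, nStimuli = 1) {
  a <- randomAdjacency(n, density)
  SignedNetwork(a, stimuli = sample(rownames(a), nStimuli))
}

# Brute-force enumeration of all distinct one-move neighbours under the
# six signed-edge move types (the oracle for neighbourhoodCounts).
enumerateNeighbours <- function(a) {
  n <- nrow(a)
  res <- list()
  add <- function(m) res[[length(res) + 1L]] <<- m
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- a[i, j]
    if (v == 0L) {
      m <- a; m[i, j] <- 1L; add(m)
      m <- a; m[i, j] <- -1L; add(m)
    } else {
      m <- a; m[i, j] <- 0L; add(m)        # delete
      m <- a; m[i, j] <- -v; add(m)        # switch type
      if (a[j, i] == 0L) {
        m <- a; m[i, j] <- 0L; m[j, i] <- v; add(m)   # revert
        m <- a; m[i, j] <- 0L; m[j, i] <- -v; add(m)  # revswitch
      }
    }
  }
  unique(res)
}

# All 3^(n(n-1)) signed adjacency matrices over n nodes (tiny n only).
allNetworks <- function(n) {
  nodes <- paste0("N", seq_len(n))
  off <- which(row(diag(n)) != col(diag(n)))
  grids <- do.call(expand.grid, rep(list(c(0L, 1L, -1L)), length(off)))
  lapply(seq_len(nrow(grids)), function(k) {
    a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
    a[off] <- unlist(grids[k, ])
    a
  })
}

adjKey <- function(a) paste(a[row(a) != col(a)], collapse = ",")

# Naive triple-loop emission log-likelihood (the oracle for
# logLikelihood()).
naiveLogLik <- function(data, gammas, assignment, theta) {
  total <- 0
  for (e in experimentNames(data)) {
    arr <- dataArray(data, e)
    g <- gammas[[e]]
    s <- assignment[[e]]
    for (i in seq_len(dim(arr)[1])) for (t in seq_len(dim(arr)[2]))
      for (r in seq_len(dim(arr)[3])) {
        if (g[i, s[t]]) {
          mu <- theta$muActive[i]; sd <- theta$sdActive[i]
        } else {
          mu <- theta$muPassive[i]; sd <- theta$sdPassive[i]
        }
        total <- total + dnorm(arr[i, t, r], mu, sd, log = TRUE)
      }
  }
  total
}

# Small well-separated simulated problem used by several tests.
simFixture <- function(N = 6, seed = 1, sigma = 0.5, T = 10, R = 4,
                       nStimuli = 2, density = 0.25) {
  cfg <- simConfig(N = N, nStimuli = nStimuli, edgeDensity = density,
                   T = T, R = R, sigma = sigma, seed = seed)
  net <- sampleNetwork(cfg)
  list(cfg = cfg, net = net, data = simulateData(net, cfg))
}
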