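# Population-based structure optimisation: quantile selection, uniform
# edge-mask crossover and single-edge mutation over signed adjacency
# matrices. Recommended settings: q = 0.3, m = 0.8 and a population of at
# least 500 networks for real inference; the per-generation cost
# bookkeeping is ceil(q p) individuals through crossover and ceil(m p)
# through mutation.

#' Quantile selection of surviving networks
#'
#' Keeps the networks scoring strictly above the population quantile
#' (the median), truncated to the \eqn{\lfloor (1-q) p \rfloor} best so
#' the best-scoring networks survive. If no score exceeds the quantile
#' (e.g. all scores equal) the best \eqn{\lfloor (1-q) p \rfloor} by
#' insertion order are retained instead.
#'
#' @param scores numeric vector of population scores.
#' @param q selection/crossover fraction in \[0, 1\].
#' @param quantile quantile function of the scores used as cutoff
#'   (default median).
#' @return Integer indices of the survivors, best first (ties broken by
#'   insertion order).
#' @export
gaSelect <- function(scores, q, quantile = stats::median) {
  p <- length(scores)
  if (!p) stop("empty population")
  k <- floor((1 - q) * p)
  cutoff <- quantile(scores)
  ord <- order(-scores)  # stable: ties keep insertion order
  above <- ord[scores[ord] > cutoff]
  if (!length(above)) return(utils::head(ord, k))
  utils::head(above, k)
}

# Uniform edge-mask crossover between paired participants; each pair
# exchanges a random subset of ordered off-diagonal slots, producing two
# offspring whose every slot comes from one of the two parents.
gaCrossover <- function(pop, q) {
  p <- length(pop)
  nPart <- min(ceiling(q * p), p)
  participants <- sample.int(p, nPart)
  offspring <- list()
  nPairs <- nPart %/% 2
  off <- which(row(pop[[1]]) != col(pop[[1]]))
  for (k in seq_len(nPairs)) {
    a <- pop[[participants[2 * k - 1]]]
    b <- pop[[participants[2 * k]]]
    mask <- off[stats::runif(length(off)) < 0.5]
    c1 <- a; c1[mask] <- b[mask]
    c2 <- b; c2[mask] <- a[mask]
    offspring[[2 * k - 1]] <- c1
    offspring[[2 * k]] <- c2
  }
  list(offspring = offspring, nProcessed = nPart,
       participants = participants)
}

# Single-edge mutation of ceil(m p) distinct individuals: one uniformly
# chosen ordered off-diagonal slot is reassigned to one of the two other
# edge states (never a no-op). `protect` indices are never mutated.
gaMutate <- function(pop, m, protect = integer()) {
  p <- length(pop)
  eligible <- setdiff(seq_len(p), protect)
  nMut <- min(ceiling(m * p), length(eligible))
  chosen <- if (length(eligible) == 1L) eligible else
    sample(eligible, nMut)
  off <- which(row(pop[[1]]) != col(pop[[1]]))
  for (i in chosen) {
    slot <- off[sample.int(length(off), 1L)]
    states <- setdiff(EDGE_STATES, pop[[i]][slot])
    pop[[i]][slot] <- states[sample.int(2L, 1L)]
  }
  list(pop = pop, mutated = chosen, nProcessed = nMut)
}

#' Run the genetic-algorithm structure search
#'
#' Evolves a population of `p` candidate networks: each generation
#' selects the survivors scoring above the population median
#' ([gaSelect()]), performs uniform edge-mask crossover within a random
#' fraction `q` of the population, refills to size `p`, mutates one edge
#' in a fraction `m` of the individuals and rescores every changed
#' network. The incumbent best network always survives unchanged
#' (elitism), so the best score is non-decreasing across generations.
#' Per generation the history records the log-likelihood and log-prior
#' differences of every changed individual to the population median —
#' the diagnostic used to calibrate the Laplace `lambda` (it should leave
#' the prior differences slightly above zero).
#'
#' @param data a [PerturbationData-class] (may be `NULL` when `scoreFun`
#'   is given).
#' @param prior a prior object or `NULL` (BIC score).
#' @param p population size (>= 2; at least 500 recommended for real
#'   inference).
#' @param nIter number of generations.
#' @param q selection/crossover fraction (default 0.3).
#' @param m mutation fraction (default 0.8).
#' @param seed optional integer seed; the run is reproducible given it.
#' @param init optional initial population (list of
#'   [SignedNetwork-class] or adjacency matrices); drawn at random
#'   otherwise.
#' @param scoreFun optional replacement score function as in
#'   [runMCMC()].
#' @param maxIter,sigmaFloor Viterbi-training controls.
#' @return List with `population` (list of [SignedNetwork-class]),
#'   `scores`, `best`, `bestScore` and `history` (per-generation summary
#'   data.frame plus `likelihoodDiff` / `priorDiff` lists).
#' @export
runGA <- function(data, prior = NULL, p = 500, nIter = 1000, q = 0.3,
                  m = 0.8, seed = NULL, init = NULL, scoreFun = NULL,
                  maxIter = 20, sigmaFloor = 1e-6) {
  stopifnot(p >= 2, q >= 0, q <= 1, m >= 0, m <= 1, nIter >= 1)
  if (is.null(scoreFun))
    scoreFun <- makeScoreFun(data, prior, maxIter, sigmaFloor)
  stim <- if (is.null(data)) character() else unique(unlist(stimuli(data)))
  wrap <- function(a) SignedNetwork(a, stimuli = stim)
  evalScore <- function(a) {
    r <- scoreFun(wrap(a))
    if (is.numeric(r)) r <- list(score = r, logLik = r, logPrior = 0)
    r[c("score", "logLik", "logPrior")]
  }
  withSeed(seed, {
    if (is.null(init)) {
      if (is.null(data)) stop("init population required when data is NULL")
      nodes <- rownames(data)
      pop <- lapply(seq_len(p), function(k)
        adjacency(randomInitNetwork(nodes, stim)))
    } else {
      pop <- lapply(init, function(x)
        if (is(x, "SignedNetwork")) adjacency(x) else x)
      if (length(pop) != p) stop("init population must have p individuals")
    }
    sc <- lapply(pop, evalScore)
    scores <- vapply(sc, `[[`, 0, "score")
    logLiks <- vapply(sc, `[[`, 0, "logLik")
    logPriors <- vapply(sc, `[[`, 0, "logPrior")
    summary <- data.frame(generation = integer(), bestScore = numeric(),
                          medianScore = numeric(), nCrossover = integer(),
                          nMutation = integer())
    likDiffs <- priorDiffs <- list()
    for (gen in seq_len(nIter)) {
      bestIdx <- order(-scores)[1]
      surv <- gaSelect(scores, q)
      cross <- gaCrossover(pop, q)
      keep <- unique(c(bestIdx, surv))
      newIdx <- c(keep, rep(NA_integer_, length(cross$offspring)))
      newPop <- c(pop[keep], cross$offspring)
      if (length(newPop) < p) {  # refill with the best remaining old nets
        fill <- utils::head(setdiff(order(-scores), keep), p - length(newPop))
        newPop <- c(newPop, pop[fill])
        newIdx <- c(newIdx, fill)
      } else if (length(newPop) > p) {
        newPop <- newPop[seq_len(p)]
        newIdx <- newIdx[seq_len(p)]
      }
      mut <- gaMutate(newPop, m, protect = 1L)
      newPop <- mut$pop
      changed <- union(which(is.na(newIdx)), mut$mutated)
      newScores <- ifelse(is.na(newIdx), NA_real_, scores[newIdx])
      newLogLiks <- ifelse(is.na(newIdx), NA_real_, logLiks[newIdx])
      newLogPriors <- ifelse(is.na(newIdx), NA_real_, logPriors[newIdx])
      for (i in changed) {
        r <- evalScore(newPop[[i]])
        newScores[i] <- r$score
        newLogLiks[i] <- r$logLik
        newLogPriors[i] <- r$logPrior
      }
      pop <- newPop
      scores <- newScores
      logLiks <- newLogLiks
      logPriors <- newLogPriors
      likDiffs[[gen]] <- logLiks[changed] - stats::median(logLiks)
      priorDiffs[[gen]] <- logPriors[changed] - stats::median(logPriors)
      summary[gen, ] <- list(gen, max(scores), stats::median(scores),
                             cross$nProcessed, mut$nProcessed)
    }
    bestIdx <- order(-scores)[1]
    list(population = lapply(pop, wrap), scores = scores,
         best = wrap(pop[[bestIdx]]), bestScore = scores[bestIdx],
         history = list(summary = summary, likelihoodDiff = likDiffs,
                        priorDiff = priorDiffs))
  })
}
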