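#' Simulation configuration
#'
#' Bundles the parameters of the synthetic ground-truth generator:
#' network size and shape, stimulus count, measurement grid and the
#' two-component Gaussian emission model. Defaults follow the package's
#' reference simulation design: a 15-node network measured at T = 10 time
#' points in R = 4 replicates, with active/passive means 2/0 and noise
#' sd 0.5 (moderate signal-to-noise), expected edge density 0.2 with a
#' quarter of the edges inhibitory, and two stimulus nodes.
#'
#' @param N number of nodes/proteins.
#' @param nStimuli number of stimulus nodes (>= 1).
#' @param edgeDensity expected fraction of nonzero ordered off-diagonal
#'   slots, in (0, 1).
#' @param pInhibition probability that an edge is inhibitory.
#' @param T,R time points and replicates per experiment.
#' @param muActive,muPassive,sigma Gaussian emission parameters
#'   (`sigma >= 0`; 0 gives noiseless data equal to the state template).
#' @param seed optional integer seed; fanned out with fixed offsets to
#'   the network and data generators.
#' @return A validated list of class `simConfig`.
#' @export
simConfig <- function(N = 15, nStimuli = 2, edgeDensity = 0.2,
                      pInhibition = 0.25, T = 10, R = 4, muActive = 2,
                      muPassive = 0, sigma = 0.5, seed = NULL) {
  cfg <- list(N = as.integer(N), nStimuli = as.integer(nStimuli),
              edgeDensity = edgeDensity, pInhibition = pInhibition,
              T = as.integer(T), R = as.integer(R), muActive = muActive,
              muPassive = muPassive, sigma = sigma, seed = seed)
  stopifnot(cfg$N >= 2, cfg$nStimuli >= 1, cfg$nStimuli < cfg$N,
            cfg$edgeDensity > 0, cfg$edgeDensity < 1,
            cfg$pInhibition >= 0, cfg$pInhibition <= 1,
            cfg$T >= 1, cfg$R >= 1, cfg$sigma >= 0)
  structure(cfg, class = "simConfig")
}

# Directed reachability of every non-stimulus node from the stimulus set
# (edge signs irrelevant for reachability).
allReachable <- function(a, stimIdx) {
  n <- nrow(a)
  reached <- logical(n)
  reached[stimIdx] <- TRUE
  frontier <- stimIdx
  while (length(frontier)) {
    nxt <- which(colSums(a[frontier, , drop = FALSE] != 0L) > 0 & !reached)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  all(reached)
}

#' Sample a random signed ground-truth network
#'
#' Draws each ordered off-diagonal slot as an edge with probability
#' `edgeDensity`, inhibitory with probability `pInhibition`. The stimuli
#' are the first `nStimuli` nodes with outgoing edges. Draws are repeated
#' until every non-stimulus node is reachable from some stimulus (so the
#' perturbation can, in principle, inform every protein); an error is
#' raised if no admissible network is found within `maxTries` draws.
#'
#' @param cfg a [simConfig()].
#' @param maxTries resampling budget.
#' @return A [SignedNetwork-class] with nodes `X1 ... XN`.
#' @export
sampleNetwork <- function(cfg, maxTries = 1000) {
  nodes <- paste0("X", seq_len(cfg$N))
  withSeed(cfg$seed, {
    for (try in seq_len(maxTries)) {
      a <- matrix(0L, cfg$N, cfg$N, dimnames = list(nodes, nodes))
      off <- which(row(a) != col(a))
      present <- stats::runif(length(off)) < cfg$edgeDensity
      sign <- ifelse(stats::runif(length(off)) < cfg$pInhibition, -1L, 1L)
      a[off[present]] <- sign[present]
      hasOut <- which(rowSums(a != 0L) > 0)
      if (length(hasOut) < cfg$nStimuli) next
      stimIdx <- hasOut[seq_len(cfg$nStimuli)]
      if (!allReachable(a, stimIdx)) next
      return(SignedNetwork(a, stimuli = nodes[stimIdx]))
    }
    stop("no admissible network found in ", maxTries,
         " draws; increase edgeDensity or decrease nStimuli")
  })
}

#' Simulate longitudinal perturbation data from a network
#'
#' Propagates the stimuli of each experiment through the network
#' ([propagate()]), stretches the resulting state sequence uniformly over
#' the T time points (time t sits in column \eqn{\lceil t M / T \rceil})
#' and draws every measurement from its protein's active or passive
#' Gaussian, i.i.d. across replicates.
#'
#' @param net a [SignedNetwork-class] with a non-empty stimulus set.
#' @param cfg a [simConfig()]; emission parameters, T, R and the seed are
#'   taken from it.
#' @param experiments optional list of stimulus sets (character vectors),
#'   one per experiment; defaults to a single experiment applying
#'   `stimuli(net)`.
#' @return A [PerturbationData-class].
#' @export
simulateData <- function(net, cfg, experiments = NULL) {
  if (is.null(experiments)) experiments <- list(stimuli(net))
  names(experiments) <- vapply(experiments, paste, "", collapse = "+")
  n <- length(nodeNames(net))
  seed <- if (is.null(cfg$seed)) NULL else cfg$seed + 1009L
  withSeed(seed, {
    blocks <- lapply(names(experiments), function(e) {
      gamma <- propagate(net, experiments[[e]])
      s <- spreadAssignment(cfg$T, ncol(gamma))
      mu <- ifelse(gamma[, s, drop = FALSE], cfg$muActive, cfg$muPassive)
      vals <- vapply(seq_len(cfg$R), function(r)
        stats::rnorm(length(mu), mean = mu, sd = cfg$sigma),
        numeric(length(mu)))
      m <- matrix(vals, nrow = n)  # columns: (time within replicate) x replicate
      list(m = m,
           experiment = rep(e, cfg$T * cfg$R),
           time = rep(rep(seq_len(cfg$T), each = 1), cfg$R),
           replicate = rep(seq_len(cfg$R), each = cfg$T))
    })
    intensity <- do.call(cbind, lapply(blocks, `[[`, "m"))
    rownames(intensity) <- nodeNames(net)
    PerturbationData(intensity,
                     experiment = unlist(lapply(blocks, `[[`, "experiment")),
                     time = unlist(lapply(blocks, `[[`, "time")),
                     replicate = unlist(lapply(blocks, `[[`, "replicate")),
                     stimuli = experiments)
  })
}

#' Generate a collection of corrupted reference networks
#'
#' Produces `nRefs` copies of the true network, each with a fraction
#' `corruption` of its ordered off-diagonal slots re-drawn uniformly from
#' \{0, 1, -1\}. `corruption = 0` reproduces the perfect-prior setting in
#' which [buildConfidenceMatrix()] returns exactly the signed adjacency
#' of the truth; `corruption = 1` yields confidences centred near zero.
#'
#' @param trueNet a [SignedNetwork-class].
#' @param nRefs number of reference networks.
#' @param corruption fraction of slots randomised, in \[0, 1\].
#' @param seed optional integer seed.
#' @return List of [SignedNetwork-class] objects.
#' @export
makeReferenceCollection <- function(trueNet, nRefs, corruption = 0,
                                    seed = NULL) {
  stopifnot(corruption >= 0, corruption <= 1, nRefs >= 1)
  a0 <- adjacency(trueNet)
  off <- which(row(a0) != col(a0))
  nCorrupt <- round(corruption * length(off))
  withSeed(seed, {
    lapply(seq_len(nRefs), function(k) {
      a <- a0
      if (nCorrupt > 0) {
        slots <- sample(off, nCorrupt)
        a[slots] <- sample(EDGE_STATES, nCorrupt, replace = TRUE)
      }
      SignedNetwork(a, stimuli = stimuli(trueNet))
    })
  })
}
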