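# Metropolis-Hastings structure sampling with six signed-edge move types:
# add_activation, add_inhibition, delete, revert, switch_type, revswitch.
# Candidates are drawn uniformly over the neighbourhood N(Phi) of the
# current network, so the proposal probability is 1/|N(Phi)| and the
# Hastings correction uses the candidate's neighbourhood size (the
# proposal is not symmetric: an empty two-node network has 4 neighbours,
# the same network with one activation edge has 6).

MOVE_TYPES <- c("add_activation", "add_inhibition", "delete", "revert",
                "switch_type", "revswitch")

# Linear index of the reverse slot (j, i) for slot (i, j) in an n x n matrix.
reverseSlot <- function(k, n) {
  i <- (k - 1L) %% n + 1L
  j <- (k - 1L) %/% n + 1L
  (i - 1L) * n + j
}

moveSlots <- function(a) {
  n <- nrow(a)
  offd <- which(row(a) != col(a))
  emptySlots <- offd[a[offd] == 0L]
  edgeSlots <- offd[a[offd] != 0L]
  revSlots <- edgeSlots[a[reverseSlot(edgeSlots, n)] == 0L]
  list(empty = emptySlots, edge = edgeSlots, rev = revSlots)
}

#' Neighbourhood size of a network under the six move types
#'
#' Every empty ordered node pair admits an activation and an inhibition
#' addition; every existing edge admits a deletion and a type switch; and
#' every edge whose reverse slot is empty admits a reversal and a
#' reverse-type-switch. Each move yields a distinct neighbour, so
#' `total = 2 nAdd + 2 nDelSwitch + 2 nRevPair` is the cardinality
#' \eqn{|N(\Phi)|} that sets the proposal probability
#' \eqn{1/|N(\Phi)|}.
#'
#' @param net a [SignedNetwork-class].
#' @return Named vector `c(nAdd, nDelSwitch, nRevPair, total)`.
#' @examples
#' empty2 <- SignedNetwork(matrix(0L, 2, 2), nodes = c("A", "B"))
#' neighbourhoodCounts(empty2)["total"]  # 4
#' @export
neighbourhoodCounts <- function(net) {
  s <- moveSlots(adjacency(net))
  nAdd <- length(s$empty)
  nDelSwitch <- length(s$edge)
  nRevPair <- length(s$rev)
  c(nAdd = nAdd, nDelSwitch = nDelSwitch, nRevPair = nRevPair,
    total = 2L * (nAdd + nDelSwitch + nRevPair))
}

#' Propose a neighbouring network uniformly
#'
#' Draws one of the \eqn{|N(\Phi)|} neighbours of `net` uniformly at
#' random (consuming the current RNG stream) and returns it with the move
#' type and the log forward/backward proposal probabilities
#' \eqn{-\log|N(\Phi_k)|} and \eqn{-\log|N(\Phi_{k+1})|}. The candidate
#' differs from `net` in exactly one node pair's edge state.
#'
#' @param net a [SignedNetwork-class] with at least two nodes.
#' @return List with `candidate`, `move`, `logQfwd`, `logQback`.
#' @export
proposeMove <- function(net) {
  a <- adjacency(net)
  n <- nrow(a)
  s <- moveSlots(a)
  nE <- length(s$empty); nD <- length(s$edge); nR <- length(s$rev)
  total <- 2L * (nE + nD + nR)
  if (total == 0L) stop("network has an empty neighbourhood")
  u <- sample.int(total, 1L)
  cand <- a
  if (u <= 2L * nE) {
    slot <- s$empty[(u - 1L) %% nE + 1L]
    if (u <= nE) {
      move <- "add_activation"; cand[slot] <- 1L
    } else {
      move <- "add_inhibition"; cand[slot] <- -1L
    }
  } else if (u <= 2L * nE + 2L * nD) {
    v <- u - 2L * nE
    slot <- s$edge[(v - 1L) %% nD + 1L]
    if (v <= nD) {
      move <- "delete"; cand[slot] <- 0L
    } else {
      move <- "switch_type"; cand[slot] <- -cand[slot]
    }
  } else {
    v <- u - 2L * (nE + nD)
    slot <- s$rev[(v - 1L) %% nR + 1L]
    rs <- reverseSlot(slot, n)
    if (v <= nR) {
      move <- "revert"; cand[rs] <- cand[slot]
    } else {
      move <- "revswitch"; cand[rs] <- -cand[slot]
    }
    cand[slot] <- 0L
  }
  candidate <- SignedNetwork(cand, stimuli = stimuli(net))
  sc <- moveSlots(cand)
  totalBack <- 2L * (length(sc$empty) + length(sc$edge) + length(sc$rev))
  list(candidate = candidate, move = move,
       logQfwd = -log(total), logQback = -log(totalBack))
}

#' Metropolis-Hastings acceptance decision
#'
#' \eqn{\alpha = \min(1, \exp(s_{cand} - s_{curr} + \log Q_{back} -
#' \log Q_{fwd}))} for unnormalised log posterior scores; the move is
#' accepted with probability \eqn{\alpha} (consuming one uniform draw).
#'
#' @param scoreCurr,scoreCand log posterior scores of the current and
#'   candidate networks.
#' @param logQfwd,logQback log proposal probabilities from
#'   [proposeMove()].
#' @return List with `accept` (logical) and `alpha`.
#' @export
acceptProbability <- function(scoreCurr, scoreCand, logQfwd, logQback) {
  if (!is.finite(scoreCurr) || !is.finite(scoreCand))
    stop("non-finite posterior scores")
  alpha <- min(1, exp(scoreCand - scoreCurr + logQback - logQfwd))
  list(accept = stats::runif(1) < alpha, alpha = alpha)
}

# Random initial structure: each off-diagonal slot empty with probability
# 1 - density, otherwise an activation or inhibition with equal chance.
randomInitNetwork <- function(nodes, stimuli, density = 0.2) {
  n <- length(nodes)
  a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  off <- which(row(a) != col(a))
  present <- stats::runif(length(off)) < density
  signs <- ifelse(stats::runif(length(off)) < 0.5, 1L, -1L)
  a[off[present]] <- signs[present]
  SignedNetwork(a, stimuli = stimuli)
}

#' Run the signed-edge structure MCMC sampler
#'
#' Iterates [proposeMove()] / score / [acceptProbability()] from an
#' initial network, recording the full per-iteration trace and the
#' thinned post-burn-in network samples. The run is deterministic given
#' `seed`.
#'
#' @param data a [PerturbationData-class]; scored networks live on its
#'   protein set and each experiment is propagated from its own stimulus
#'   set.
#' @param prior a [LaplacePrior-class], [ScaleFreePrior-class] or `NULL`
#'   (BIC-penalised likelihood).
#' @param nIter total number of iterations.
#' @param burnin number of initial iterations discarded from the sample
#'   record (default 10 percent of `nIter`).
#' @param thin thinning interval for recorded networks (default 50); the
#'   thinning counter advances every iteration, accepted or not.
#' @param seed optional integer seed.
#' @param init initial [SignedNetwork-class]; `NULL` draws a random
#'   structure.
#' @param scoreFun optional replacement score function `function(net)`
#'   returning either a numeric score or a list with `score`, `logLik`,
#'   `logPrior`; defaults to the likelihood/prior score of `data` (see
#'   [scoreNetwork()]). When supplied, `data` may be `NULL`.
#' @param maxIter,sigmaFloor Viterbi-training controls.
#' @return An [McmcTrace-class].
#' @examples
#' \dontrun{
#' net <- sampleNetwork(simConfig(N = 6, seed = 1))
#' d <- simulateData(net, simConfig(N = 6, seed = 1))
#' pri <- laplacePrior(net, lambda = 0.001, gamma = 1)
#' tr <- runMCMC(d, pri, nIter = 2000, burnin = 200, thin = 10, seed = 1)
#' }
#' @export
runMCMC <- function(data, prior = NULL, nIter = 50000,
                    burnin = floor(nIter * 0.1), thin = 50, seed = NULL,
                    init = NULL, scoreFun = NULL, maxIter = 20,
                    sigmaFloor = 1e-6) {
  if (nIter <= burnin || burnin < 0) stop("need nIter > burnin >= 0")
  if (thin < 1) stop("thin must be >= 1")
  if (is.null(scoreFun))
    scoreFun <- makeScoreFun(data, prior, maxIter, sigmaFloor)
  evalScore <- function(net) {
    r <- scoreFun(net)
    if (is.numeric(r)) r <- list(score = r, logLik = r, logPrior = 0)
    r
  }
  withSeed(seed, {
    if (is.null(init)) {
      if (is.null(data)) stop("init network required when data is NULL")
      init <- randomInitNetwork(rownames(data),
                                unique(unlist(stimuli(data))))
    }
    cur <- init
    curScore <- evalScore(cur)
    logLikV <- logPriorV <- numeric(nIter)
    moveV <- character(nIter)
    accV <- logical(nIter)
    networks <- vector("list", (nIter - burnin) %/% thin)
    nSaved <- 0L
    for (it in seq_len(nIter)) {
      prop <- proposeMove(cur)
      candScore <- evalScore(prop$candidate)
      dec <- acceptProbability(curScore$score, candScore$score,
                               prop$logQfwd, prop$logQback)
      if (dec$accept) {
        cur <- prop$candidate
        curScore <- candScore
      }
      logLikV[it] <- curScore$logLik
      logPriorV[it] <- curScore$logPrior
      moveV[it] <- prop$move
      accV[it] <- dec$accept
      if (it > burnin && (it - burnin) %% thin == 0L) {
        nSaved <- nSaved + 1L
        networks[[nSaved]] <- adjacency(cur)
      }
    }
    networks <- networks[seq_len(nSaved)]
    steps <- data.frame(iteration = seq_len(nIter), logLik = logLikV,
                        logPrior = logPriorV,
                        posterior = logLikV + logPriorV,
                        move = moveV, accepted = accV)
    params <- list(nIter = nIter, burnin = burnin, thin = thin, seed = seed,
                   nodes = nodeNames(cur), stimuli = stimuli(cur),
                   prior = if (is.null(prior)) "none" else class(prior))
    if (is(prior, "LaplacePrior")) {
      params$lambda <- prior@lambda
      params$gamma <- prior@gamma
    }
    new("McmcTrace", steps = steps, networks = networks, params = params)
  })
}

#' Write an MCMC trace to disk
#'
#' Writes `trace.tsv` (the per-iteration bookkeeping) and
#' `networks.tsv` (the thinned network samples, stacked edge lists with a
#' `sample` column) into `dir`.
#'
#' @param trace an [McmcTrace-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTrace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(trace@steps, file.path(dir, "trace.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rows <- list()
  for (k in seq_along(trace@networks)) {
    a <- trace@networks[[k]]
    idx <- which(a != 0L, arr.ind = TRUE)
    if (nrow(idx))
      rows[[k]] <- data.frame(sample = k, source = rownames(a)[idx[, 1]],
                              type = a[idx], target = colnames(a)[idx[, 2]])
  }
  nets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = integer(), source = character(),
               type = integer(), target = character())
  utils::write.table(nets, file.path(dir, "networks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- trace@params
  meta$nSamples <- length(trace@networks)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}

#' Read an MCMC trace back from disk
#'
#' Reconstructs the [McmcTrace-class] written by [writeTrace()] from a
#' directory containing `trace.tsv`, `networks.tsv` and `meta.json`.
#'
#' @param dir directory to read.
#' @return An [McmcTrace-class].
#' @export
readTrace <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("not a trace directory: ", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  steps <- utils::read.delim(file.path(dir, "trace.tsv"),
                             stringsAsFactors = FALSE)
  nets <- readNetworkCollection(file.path(dir, "networks.tsv"),
                                nodes = meta$nodes,
                                nSamples = meta$nSamples)
  params <- meta
  params$nSamples <- NULL
  new("McmcTrace", steps = steps, networks = nets, params = params)
}
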