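# Gaussian-HMM likelihood of perturbation data given a network: Viterbi
# training of the two-component emission model over the propagated
# system-state columns, with a monotone state-assignment path per
# experiment.
#
# The expensive inner quantities only depend on the data through the
# per-(protein, time) replicate sums S1 and sums of squares S2, which are
# precomputed once per dataset:
#   sum_r log N(d_itr; mu, sd) =
#     -R log sd - R/2 log(2 pi) - (S2 - 2 mu S1 + R mu^2) / (2 sd^2)

# Per-experiment sufficient statistics.
dataSummaries <- function(data) {
  out <- lapply(experimentNames(data), function(e) {
    arr <- dataArray(data, e)
    list(name = e,
         S1 = apply(arr, c(1, 2), sum),
         S2 = apply(arr, c(1, 2), function(v) sum(v * v)),
         R = dim(arr)[3], T = dim(arr)[2])
  })
  names(out) <- experimentNames(data)
  out
}

# N x T matrix of replicate-summed log densities under per-protein
# Gaussians (mu, sd recycled along rows).
classLogDens <- function(S1, S2, R, mu, sd) {
  -R * log(sd) - 0.5 * R * log(2 * pi) -
    (S2 - 2 * mu * S1 + R * mu * mu) / (2 * sd * sd)
}

# Gaussian parameter estimation from the current active/passive labels.
# Class MLE (mean, sqrt of the biased variance) with the sd floored;
# a protein whose class has no assigned observations falls back to its
# pooled mean and pooled (floored) sd, which leaves the attained
# likelihood untouched because no observation uses those parameters.
estimateTheta <- function(summaries, gammas, assignments, sigmaFloor) {
  n <- nrow(summaries[[1]]$S1)
  nAct <- nTot <- numeric(n)
  s1Act <- s2Act <- s1Tot <- s2Tot <- numeric(n)
  for (e in names(summaries)) {
    sm <- summaries[[e]]
    g <- gammas[[e]][, assignments[[e]], drop = FALSE]  # N x T active flags
    nAct <- nAct + sm$R * rowSums(g)
    s1Act <- s1Act + rowSums(sm$S1 * g)
    s2Act <- s2Act + rowSums(sm$S2 * g)
    nTot <- nTot + sm$R * sm$T
    s1Tot <- s1Tot + rowSums(sm$S1)
    s2Tot <- s2Tot + rowSums(sm$S2)
  }
  nPas <- nTot - nAct
  s1Pas <- s1Tot - s1Act
  s2Pas <- s2Tot - s2Act
  muPool <- s1Tot / nTot
  sdPool <- sqrt(pmax(s2Tot / nTot - muPool^2, 0))
  sdPool[sdPool < sigmaFloor] <- sigmaFloor
  mom <- function(nn, s1, s2) {
    mu <- s1 / nn
    sd <- sqrt(pmax(s2 / nn - mu * mu, 0))
    empty <- nn == 0
    mu[empty] <- muPool[empty]
    sd[empty] <- sdPool[empty]
    sd[sd < sigmaFloor] <- sigmaFloor
    list(mu = mu, sd = sd)
  }
  a <- mom(nAct, s1Act, s2Act)
  p <- mom(nPas, s1Pas, s2Pas)
  list(muActive = a$mu, sdActive = a$sd,
       muPassive = p$mu, sdPassive = p$sd,
       proteins = rownames(summaries[[1]]$S1))
}

# Exported-surface form of the emission parameters.
thetaFrame <- function(theta) {
  if (is.data.frame(theta)) return(theta)
  data.frame(muActive = theta$muActive, sdActive = theta$sdActive,
             muPassive = theta$muPassive, sdPassive = theta$sdPassive,
             row.names = theta$proteins)
}

# Best monotone non-decreasing path through the M x T cell-score matrix
# (dynamic programming; ties resolved towards the smallest column).
viterbiPath <- function(cellScore) {
  M <- nrow(cellScore)
  T <- ncol(cellScore)
  best <- matrix(0, M, T)
  back <- matrix(1L, M, T)
  best[, 1] <- cellScore[, 1]
  for (t in seq_len(T)[-1]) {
    cur <- 1L
    for (m in seq_len(M)) {
      if (best[m, t - 1] > best[cur, t - 1]) cur <- m
      back[m, t] <- cur
      best[m, t] <- cellScore[m, t] + best[cur, t - 1]
    }
  }
  path <- integer(T)
  path[T] <- which.max(best[, T])
  if (T > 1) for (t in T:2) path[t - 1] <- back[path[t], t]
  list(path = path, logLik = best[path[T], T])
}

# M x T cell scores: summed per-protein log densities when the system sits
# in column m at time t.
cellScores <- function(gamma, LA, LP) {
  g <- gamma + 0
  crossprod(g, LA) + crossprod(1 - g, LP)
}

# Default initial assignment: T time points spread uniformly over the M
# columns, ceil(t M / T).
spreadAssignment <- function(T, M) pmax(1L, as.integer(ceiling(seq_len(T) * M / T)))

viterbiTrainingCore <- function(summaries, gammas, init, maxIter, sigmaFloor) {
  assignments <- init
  trace <- numeric(0)
  theta <- NULL
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    theta <- estimateTheta(summaries, gammas, assignments, sigmaFloor)
    total <- 0
    nxt <- assignments
    for (e in names(summaries)) {
      sm <- summaries[[e]]
      LA <- classLogDens(sm$S1, sm$S2, sm$R, theta$muActive, theta$sdActive)
      LP <- classLogDens(sm$S1, sm$S2, sm$R, theta$muPassive, theta$sdPassive)
      vp <- viterbiPath(cellScores(gammas[[e]], LA, LP))
      nxt[[e]] <- vp$path
      total <- total + vp$logLik
    }
    trace <- c(trace, total)
    if (identical(nxt, assignments)) {
      converged <- TRUE
      break
    }
    assignments <- nxt
  }
  list(theta = theta, assignment = assignments,
       logLik = trace[length(trace)], logLikTrace = trace,
       iterations = length(trace), converged = converged)
}

#' Viterbi training of the Gaussian emission model
#'
#' Alternates (a) per-protein Gaussian parameter estimation for the
#' active and passive classes from the data partitioned by the current
#' state assignment and (b) the best monotone non-decreasing reassignment
#' of time points to system-state columns by dynamic programming. The
#' attained log-likelihood is non-decreasing across iterations; training
#' stops when the assignment is stable or `maxIter` is reached.
#'
#' @param data a [PerturbationData-class].
#' @param gammas named list (one entry per experiment) of system-state
#'   matrices from [propagate()].
#' @param init optional named list of initial assignments (integer
#'   vectors of length T, monotone, values in 1..M); defaults to a
#'   uniform spread of the time points over the columns.
#' @param maxIter maximum number of training iterations.
#' @param sigmaFloor lower bound for estimated standard deviations.
#' @param nStarts number of training starts; starts beyond the first use
#'   random monotone initial assignments (drawn from the current RNG
#'   stream) and the best final log-likelihood wins.
#' @return List with elements `theta` (data.frame `muActive`, `sdActive`,
#'   `muPassive`, `sdPassive` per protein), `assignment` (named list of
#'   integer paths), `logLik`, `logLikTrace`, `iterations`, `converged`.
#' @export
viterbiTraining <- function(data, gammas, init = NULL, maxIter = 20,
                            sigmaFloor = 1e-6, nStarts = 1) {
  summaries <- dataSummaries(data)
  if (!setequal(names(gammas), names(summaries)))
    stop("gammas must name every experiment of the data")
  gammas <- gammas[names(summaries)]
  defaultInit <- lapply(summaries, function(sm)
    spreadAssignment(sm$T, ncol(gammas[[sm$name]])))
  if (is.null(init)) init <- defaultInit
  best <- viterbiTrainingCore(summaries, gammas, init, maxIter, sigmaFloor)
  if (nStarts > 1) {
    for (s in seq_len(nStarts - 1)) {
      rinit <- lapply(summaries, function(sm)
        sort(sample.int(ncol(gammas[[sm$name]]), sm$T, replace = TRUE)))
      cand <- viterbiTrainingCore(summaries, gammas, rinit, maxIter, sigmaFloor)
      if (cand$logLik > best$logLik) best <- cand
    }
  }
  best$theta <- thetaFrame(best$theta)
  best
}

#' Log-likelihood of perturbation data under a state assignment
#'
#' The emission log-likelihood: the sum over proteins, time points and
#' replicates of the log Gaussian density of each measurement under its
#' protein's active or passive parameters, as selected by the
#' system-state matrix column assigned to its time point.
#'
#' @param data a [PerturbationData-class].
#' @param gammas named list of system-state matrices per experiment.
#' @param assignment named list of integer paths per experiment.
#' @param theta data.frame with per-protein `muActive`, `sdActive`,
#'   `muPassive`, `sdPassive` (as returned by [viterbiTraining()]).
#' @return A single numeric log-likelihood.
#' @export
logLikelihood <- function(data, gammas, assignment, theta) {
  if (any(theta$sdActive <= 0) || any(theta$sdPassive <= 0))
    stop("standard deviations must be positive")
  summaries <- dataSummaries(data)
  total <- 0
  for (e in names(summaries)) {
    sm <- summaries[[e]]
    LA <- classLogDens(sm$S1, sm$S2, sm$R, theta$muActive, theta$sdActive)
    LP <- classLogDens(sm$S1, sm$S2, sm$R, theta$muPassive, theta$sdPassive)
    cs <- cellScores(gammas[[e]], LA, LP)
    total <- total + sum(cs[cbind(assignment[[e]], seq_len(sm$T))])
  }
  total
}

# Closure scoring networks against a fixed dataset (and optional prior);
# the data summaries are computed once, so repeated calls from the MCMC
# and GA loops stay cheap. Returns function(net) -> list(score, logLik,
# logPrior, theta, assignment).
makeScoreFun <- function(data, prior = NULL, maxIter = 20, sigmaFloor = 1e-6) {
  summaries <- dataSummaries(data)
  stim <- stimuli(data)
  proteins <- rownames(data)
  nObs <- sum(vapply(summaries, function(sm) nrow(sm$S1) * sm$T * sm$R, 1))
  nProt <- length(proteins)
  function(net) {
    if (!identical(nodeNames(net), proteins))
      stop("network nodes must match the data proteins (same order)")
    gammas <- lapply(stim, function(s) propagate(net, s))
    init <- lapply(names(summaries), function(e)
      spreadAssignment(summaries[[e]]$T, ncol(gammas[[e]])))
    names(init) <- names(summaries)
    fit <- viterbiTrainingCore(summaries, gammas, init, maxIter, sigmaFloor)
    if (is.null(prior)) {
      k <- sum(adjacency(net) != 0L) + 4 * nProt
      logPrior <- -0.5 * k * log(nObs)
    } else {
      logPrior <- logNetworkPrior(prior, net)
    }
    list(score = fit$logLik + logPrior, logLik = fit$logLik,
         logPrior = logPrior, theta = fit$theta, assignment = fit$assignment,
         gammas = gammas)
  }
}

#' Posterior score of a network given perturbation data
#'
#' Runs [propagate()] for every experiment's stimulus set, fits the
#' emission model by [viterbiTraining()] and returns the structure score:
#' the log-likelihood plus the log prior when a prior model is supplied,
#' or a BIC-penalised log-likelihood (`logLik - 0.5 k log(nObs)`, with
#' `k` = number of edges + 4N emission parameters) when `prior` is
#' `NULL`. Deterministic for fixed inputs.
#'
#' @param net a [SignedNetwork-class]; its nodes must equal the data's
#'   proteins, in the same order.
#' @param data a [PerturbationData-class].
#' @param prior a [LaplacePrior-class], [ScaleFreePrior-class] or `NULL`.
#' @param maxIter,sigmaFloor passed to the Viterbi training.
#' @return List with `score`, `logLik`, `logPrior`, `theta`,
#'   `assignment` and `gammas`.
#' @export
scoreNetwork <- function(net, data, prior = NULL, maxIter = 20,
                         sigmaFloor = 1e-6) {
  r <- makeScoreFun(data, prior, maxIter, sigmaFloor)(net)
  r$theta <- thetaFrame(r$theta)
  r
}
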