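#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
NULL

EDGE_STATES <- c(-1L, 0L, 1L)

#' SignedNetwork: a directed network with activation and inhibition edges
#'
#' The central network container. Edges are encoded in an adjacency matrix
#' over \{0, 1, -1\}: entry \eqn{(i, j)} describes the edge from node
#' \eqn{i} (row, source) to node \eqn{j} (column, target), with 1 an
#' activation, -1 an inhibition and 0 no edge. A subset of the nodes is
#' flagged as stimuli: the externally perturbed inputs from which activity
#' is propagated through the network. Self-edges are not allowed. Stimulus
#' nodes may carry incoming edges structurally, but signal propagation
#' clamps them to the active state, so such edges never influence the
#' dynamics.
#'
#' @slot adjacency integer matrix, square, entries in \{0, 1, -1\},
#'   zero diagonal, identical row and column names giving the node labels.
#' @slot stimuli character vector of stimulus node labels (possibly empty
#'   for a purely structural network; propagation and scoring require at
#'   least one).
#'
#' @seealso [SignedNetwork()] for the constructor, [adjacency()],
#'   [nodeNames()], [stimuli()], [edgeCount()], [readNetwork()].
#' @export
setClass("SignedNetwork",
  representation(adjacency = "matrix", stimuli = "character"))

setValidity("SignedNetwork", function(object) {
  a <- object@adjacency
  if (!is.matrix(a) || nrow(a) != ncol(a))
    return("adjacency must be a square matrix")
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("adjacency must carry node labels as dimnames")
  if (!identical(rownames(a), colnames(a)))
    return("adjacency row and column labels differ")
  if (anyDuplicated(rownames(a)))
    return("node labels must be unique")
  if (!all(a %in% EDGE_STATES))
    return("adjacency entries must be in {0, 1, -1}")
  if (nrow(a) > 0 && any(diag(a) != 0L))
    return("self-edges are not allowed (nonzero diagonal)")
  if (!all(object@stimuli %in% rownames(a)))
    return("stimuli must be a subset of the node labels")
  if (anyDuplicated(object@stimuli))
    return("duplicated stimulus labels")
  TRUE
})

#' Construct a SignedNetwork
#'
#' @param adjacency square numeric/integer matrix with entries in
#'   \{0, 1, -1\}; row = source, column = target. If it has no dimnames,
#'   `nodes` must be given.
#' @param stimuli character vector of stimulus node labels.
#' @param nodes optional character vector of node labels, used when
#'   `adjacency` carries none.
#' @return A validated [SignedNetwork-class] object.
#' @examples
#' adj <- matrix(0L, 2, 2, dimnames = list(c("S", "B"), c("S", "B")))
#' adj["S", "B"] <- 1L
#' net <- SignedNetwork(adj, stimuli = "S")
#' edgeCount(net)
#' @export
SignedNetwork <- function(adjacency, stimuli = character(), nodes = NULL) {
  adjacency <- as.matrix(adjacency)
  if (!is.null(nodes)) dimnames(adjacency) <- list(nodes, nodes)
  storage.mode(adjacency) <- "integer"
  new("SignedNetwork", adjacency = adjacency, stimuli = as.character(stimuli))
}

setMethod("show", "SignedNetwork", function(object) {
  n <- nrow(object@adjacency)
  cnt <- edgeCount(object)
  cat(sprintf(
    "SignedNetwork: %d nodes, %d activation / %d inhibition edges\n",
    n, cnt[["activation"]], cnt[["inhibition"]]))
  if (length(object@stimuli))
    cat("  stimuli:", paste(object@stimuli, collapse = ", "), "\n")
  else
    cat("  stimuli: none\n")
  invisible(NULL)
})

#' PerturbationData: longitudinal perturbation measurements
#'
#' A [SummarizedExperiment-class] holding an `intensity` assay of N
#' proteins (rows) by all measured samples (columns). Each column belongs
#' to one experiment (one stimulation condition), one time point and one
#' replicate, recorded in `colData` columns `experiment`, `time` and
#' `replicate`. The stimulus set of each experiment (a character vector of
#' protein labels) is kept in `metadata(x)$stimuli`, a list named by
#' experiment. Every experiment must contain the full, balanced T x R grid
#' of time points and replicates, shared across experiments.
#'
#' @seealso [PerturbationData()], [dataArray()], [readPerturbationData()],
#'   [simulateData()].
#' @export
setClass("PerturbationData", contains = "SummarizedExperiment")

setValidity("PerturbationData", function(object) {
  cd <- colData(object)
  need <- c("experiment", "time", "replicate")
  if (!all(need %in% colnames(cd)))
    return("colData must contain experiment, time and replicate")
  if (length(SummarizedExperiment::assays(object)) < 1)
    return("an intensity assay is required")
  if (is.null(rownames(object)))
    return("protein labels (rownames) are required")
  m <- assay(object, 1)
  if (nrow(m) > 0 && any(apply(m, 1, function(x) all(!is.finite(x)))))
    return("entirely missing protein rows are not allowed")
  exps <- unique(as.character(cd$experiment))
  tt <- sort(unique(cd$time))
  rr <- sort(unique(cd$replicate))
  for (e in exps) {
    sel <- cd$experiment == e
    tab <- table(factor(cd$time[sel], levels = tt),
                 factor(cd$replicate[sel], levels = rr))
    if (any(tab != 1))
      return(sprintf("experiment '%s' is not a balanced time x replicate grid", e))
  }
  stim <- metadata(object)$stimuli
  if (is.null(stim) || !is.list(stim) || !setequal(names(stim), exps))
    return("metadata()$stimuli must be a list naming every experiment")
  if (!all(unlist(stim) %in% rownames(object)))
    return("stimulus labels must be measured proteins")
  if (any(vapply(stim, length, 1L) == 0))
    return("every experiment needs a non-empty stimulus set")
  TRUE
})

#' Construct a PerturbationData object
#'
#' @param intensity numeric matrix, proteins x samples.
#' @param experiment,time,replicate per-column annotations (recycled
#'   checks apply); `experiment` is coerced to character.
#' @param stimuli named list mapping each experiment to the character
#'   vector of its stimulated proteins.
#' @return A validated [PerturbationData-class] object with columns
#'   ordered canonically by (experiment, time, replicate).
#' @examples
#' m <- matrix(rnorm(12), 2, 6,
#'   dimnames = list(c("S", "A"), NULL))
#' pd <- PerturbationData(m,
#'   experiment = rep("S", 6), time = rep(1:3, each = 2),
#'   replicate = rep(1:2, 3), stimuli = list(S = "S"))
#' nTimepoints(pd)
#' @export
PerturbationData <- function(intensity, experiment, time, replicate, stimuli) {
  intensity <- as.matrix(intensity)
  experiment <- as.character(experiment)
  cd <- DataFrame(experiment = experiment,
                  time = as.numeric(time),
                  replicate = as.integer(replicate))
  ord <- order(cd$experiment, cd$time, cd$replicate)
  intensity <- intensity[, ord, drop = FALSE]
  cd <- cd[ord, , drop = FALSE]
  colnames(intensity) <- sprintf(
    "%s:%s:%d", cd$experiment,
    format(cd$time, trim = TRUE, scientific = FALSE), cd$replicate)
  se <- SummarizedExperiment(
    assays = list(intensity = intensity), colData = cd)
  metadata(se)$stimuli <- stimuli[sort(names(stimuli))]
  new("PerturbationData", se)
}

setMethod("show", "PerturbationData", function(object) {
  cd <- colData(object)
  cat(sprintf(
    "PerturbationData: %d proteins, %d experiment(s), T=%d, R=%d\n",
    nrow(object), length(unique(cd$experiment)),
    length(unique(cd$time)), length(unique(cd$replicate))))
  stim <- metadata(object)$stimuli
  for (e in names(stim))
    cat(sprintf("  %s: stimuli {%s}\n", e, paste(stim[[e]], collapse = ", ")))
  invisible(NULL)
})

#' McmcTrace: recorded output of a structure-MCMC run
#'
#' Holds the per-iteration bookkeeping of [runMCMC()]: move type, log
#' likelihood, log prior and posterior score of the current network at
#' every iteration, plus the thinned post-burn-in network samples.
#'
#' @slot steps data.frame with columns `iteration`, `logLik`, `logPrior`,
#'   `posterior`, `move`, `accepted`; one row per iteration.
#' @slot networks list of adjacency matrices: the state of the chain at
#'   the thinned, post-burn-in iterations.
#' @slot params list of run metadata (lambda, gamma, seed, burnin, thin,
#'   nodes, stimuli, prior type).
#' @export
setClass("McmcTrace",
  representation(steps = "data.frame", networks = "list", params = "list"))

setValidity("McmcTrace", function(object) {
  st <- object@steps
  need <- c("iteration", "logLik", "logPrior", "posterior", "move", "accepted")
  if (!all(need %in% colnames(st)))
    return("steps must record iteration, logLik, logPrior, posterior, move, accepted")
  if (nrow(st) &&
      max(abs(st$posterior - (st$logLik + st$logPrior))) > 1e-9)
    return("posterior must equal logLik + logPrior")
  TRUE
})

setMethod("show", "McmcTrace", function(object) {
  st <- object@steps
  cat(sprintf(
    "McmcTrace: %d iterations, %d thinned samples, acceptance rate %.3f\n",
    nrow(st), length(object@networks), mean(st$accepted)))
  invisible(NULL)
})

#' Laplace reference-network prior
#'
#' Structure prior that penalises deviations of a candidate network from a
#' matrix `B` of signed prior edge confidences in \[-1, 1\]. The per-edge
#' log prior is \eqn{-\log 2 - \log\lambda - \Delta_{ij}/\lambda} with
#' \eqn{\Delta_{ij} = |\phi_{ij} - b_{ij}|^\gamma}; the network log prior
#' sums over all ordered off-diagonal pairs (edges are a priori
#' independent).
#'
#' @slot B numeric matrix of prior confidences, diagonal 0, entries in
#'   \[-1, 1\]; positive = activation belief, negative = inhibition.
#' @slot lambda positive scale: smaller values sharpen the prior.
#' @slot gamma positive weight exponent: larger values widen the plateau
#'   of tolerated small deviations.
#' @slot useTypes logical; if `FALSE`, signs of both the network and `B`
#'   are dropped before computing differences.
#' @seealso [laplacePrior()], [logNetworkPrior()], [buildConfidenceMatrix()]
#' @export
setClass("LaplacePrior",
  representation(B = "matrix", lambda = "numeric", gamma = "numeric",
                 useTypes = "logical"))

setValidity("LaplacePrior", function(object) {
  B <- object@B
  if (nrow(B) != ncol(B)) return("B must be square")
  if (is.null(rownames(B)) || !identical(rownames(B), colnames(B)))
    return("B must carry matching node labels")
  if (any(abs(B) > 1)) return("prior confidences must lie in [-1, 1]")
  if (nrow(B) > 0 && any(diag(B) != 0)) return("diagonal of B must be 0")
  if (length(object@lambda) != 1 || object@lambda <= 0)
    return("lambda must be a single positive number")
  if (length(object@gamma) != 1 || object@gamma <= 0)
    return("gamma must be a single positive number")
  TRUE
})

#' Construct a Laplace reference-network prior
#'
#' @param B signed confidence matrix (e.g. from
#'   [buildConfidenceMatrix()]), or a [SignedNetwork-class] taken as exact
#'   confidences \{0, 1, -1\} (the "perfect prior" setting).
#' @param lambda positive prior scale \eqn{\lambda}. Tuning rule: if log
#'   likelihood differences along the chain are of order \eqn{10^3}, a
#'   unit edge mismatch should contribute comparably, i.e.
#'   \eqn{\lambda = 10^{-3}} at \eqn{\gamma = 1}.
#' @param gamma positive weight exponent \eqn{\gamma}.
#' @param useTypes use edge-sign information (default `TRUE`).
#' @return A [LaplacePrior-class] object.
#' @export
laplacePrior <- function(B, lambda, gamma = 1, useTypes = TRUE) {
  if (is(B, "SignedNetwork")) B <- adjacency(B)
  B <- as.matrix(B)
  storage.mode(B) <- "double"
  new("LaplacePrior", B = B, lambda = as.numeric(lambda),
      gamma = as.numeric(gamma), useTypes = isTRUE(useTypes))
}

setMethod("show", "LaplacePrior", function(object) {
  cat(sprintf("LaplacePrior: %d nodes, lambda=%g, gamma=%g, types %s\n",
              nrow(object@B), object@lambda, object@gamma,
              if (object@useTypes) "on" else "off"))
  invisible(NULL)
})

#' Scale-free degree prior
#'
#' Structure prior favouring networks whose node degrees follow a power
#' law \eqn{P(d) \propto d^{-\gamma}}. Node weights \eqn{P_i \propto
#' i^{-\mu}} with \eqn{\mu = 1/(\gamma - 1)} are assigned along random
#' node permutations; an ordered node pair is unconnected with probability
#' \eqn{(1 - P_i P_j)^{KN}}. The structure probability is the product over
#' pairs, averaged over the stored permutations. Edge signs are ignored:
#' the prior only sees the degree structure, so sparse networks are
#' preferred for small `K`.
#'
#' @slot gammaSF power-law exponent, \eqn{\ge 2}.
#' @slot K positive scalar controlling the mean number of edges.
#' @slot permutations integer matrix, one permutation per row, drawn once
#'   at construction so that scores are deterministic.
#' @seealso [scaleFreePrior()], [logNetworkPrior()]
#' @export
setClass("ScaleFreePrior",
  representation(gammaSF = "numeric", K = "numeric", permutations = "matrix"))

setValidity("ScaleFreePrior", function(object) {
  if (object@gammaSF < 2) return("gammaSF must be >= 2")
  if (object@K <= 0) return("K must be positive")
  if (nrow(object@permutations) < 1) return("need at least one permutation")
  TRUE
})

#' Construct a scale-free degree prior
#'
#' @param nNodes number of network nodes the prior will score.
#' @param gammaSF power-law exponent \eqn{\gamma \ge 2} (a warning is
#'   emitted at the boundary \eqn{\gamma = 2}, where \eqn{\mu = 1}).
#' @param K positive scalar controlling the expected edge count.
#' @param nPerm number of node permutations to average over.
#' @param seed optional integer seed for drawing the permutations.
#' @return A [ScaleFreePrior-class] object.
#' @export
scaleFreePrior <- function(nNodes, gammaSF = 2.5, K = 1, nPerm = 50,
                           seed = NULL) {
  if (gammaSF < 2) stop("gammaSF must be >= 2")
  if (gammaSF == 2)
    warning("gammaSF = 2 gives mu = 1, the boundary of the admissible range")
  perms <- withSeed(seed, {
    t(vapply(seq_len(nPerm), function(k) sample.int(nNodes), integer(nNodes)))
  })
  new("ScaleFreePrior", gammaSF = as.numeric(gammaSF), K = as.numeric(K),
      permutations = perms)
}

setMethod("show", "ScaleFreePrior", function(object) {
  cat(sprintf("ScaleFreePrior: gamma=%g, K=%g, %d permutations of %d nodes\n",
              object@gammaSF, object@K, nrow(object@permutations),
              ncol(object@permutations)))
  invisible(NULL)
})
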