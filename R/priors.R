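#' Weighted per-edge difference to the prior confidence
#'
#' \eqn{\Delta_{ij} = |\phi_{ij} - b_{ij}|^\gamma}. With edge-type (sign)
#' information, \eqn{\phi_{ij} \in \{0, 1, -1\}} and \eqn{b_{ij} \in
#' [-1, 1]}, so all differences lie in \eqn{[0, 2^\gamma]}; without type
#' information both signs are dropped first and \eqn{\Delta_{ij} \in
#' [0, 1]}.
#'
#' @param phi edge value(s) in \{0, 1, -1\} (vectorised).
#' @param b prior confidence(s) in \[-1, 1\].
#' @param gamma positive weight exponent.
#' @return Numeric, same length as the inputs.
#' @examples
#' edgeDelta(1, -1, 1)    # 2, the upper end of [0, 2^gamma]
#' edgeDelta(0, 0.5, 2)   # 0.25
#' @export
edgeDelta <- function(phi, b, gamma) {
  stopifnot(all(abs(b) <= 1))
  abs(phi - b)^gamma
}

#' Per-edge Laplace log prior
#'
#' The log of the Laplace kernel \eqn{\frac{1}{2\lambda}
#' e^{-\Delta/\lambda}}: `-log(2) - log(lambda) - delta / lambda`,
#' maximal at \eqn{\Delta = 0}. In score differences the constant
#' \eqn{-\log 2 - \log\lambda} cancels, so the prior's influence is
#' carried entirely by \eqn{\Delta/\lambda}: at \eqn{\lambda = 10^{-3}},
#' \eqn{\gamma = 1}, a unit edge mismatch contributes \eqn{10^3}.
#'
#' @param delta non-negative difference(s) from [edgeDelta()].
#' @param lambda positive prior scale.
#' @return Numeric log prior value(s).
#' @export
logEdgePrior <- function(delta, lambda) {
  if (length(lambda) != 1 || lambda <= 0) stop("lambda must be positive")
  stopifnot(all(delta >= 0))
  -log(2) - log(lambda) - delta / lambda
}

#' @describeIn logNetworkPrior Laplace reference prior: the sum of
#'   [logEdgePrior()] over all ordered off-diagonal node pairs (edges are
#'   a priori independent). With `useTypes = FALSE` the signs of the
#'   network and of `B` are dropped before the differences are taken.
#' @export
setMethod("logNetworkPrior", signature(prior = "LaplacePrior"),
  function(prior, net) {
    phi <- adjacency(net)
    B <- prior@B
    if (!all(dim(phi) == dim(B)))
      stop("network and prior confidence matrix dimensions differ")
    if (!prior@useTypes) {
      phi <- abs(phi)
      B <- abs(B)
    }
    off <- row(phi) != col(phi)
    sum(logEdgePrior(edgeDelta(phi[off], B[off], prior@gamma), prior@lambda))
  })

#' @describeIn logNetworkPrior Scale-free degree prior: the log of the
#'   structure probability averaged over the stored node permutations;
#'   edge signs are ignored.
#' @export
setMethod("logNetworkPrior", signature(prior = "ScaleFreePrior"),
  function(prior, net) {
    phi <- adjacency(net)
    n <- nrow(phi)
    if (ncol(prior@permutations) != n)
      stop("prior was built for ", ncol(prior@permutations), " nodes")
    P <- scaleFreeNodeWeights(n, prior@gammaSF)
    off <- row(phi) != col(phi)
    present <- (phi != 0L)[off]
    logs <- apply(prior@permutations, 1, function(sigma) {
      w <- P[sigma]
      pp <- outer(w, w)[off]
      logNo <- prior@K * n * log1p(-pp)
      logYes <- log1p(-exp(logNo))
      sum(ifelse(present, logYes, logNo))
    })
    logMeanExp(logs)
  })

#' @describeIn logNetworkPrior No prior: contributes 0.
#' @export
setMethod("logNetworkPrior", signature(prior = "NULL"),
  function(prior, net) 0)

#' Power-law node weights for the scale-free prior
#'
#' Assigns each node rank \eqn{i = 1 \dots N} the weight \eqn{P_i \propto
#' i^{-\mu}} with \eqn{\mu = 1/(\gamma - 1)}, normalised to sum to one;
#' strictly decreasing in \eqn{i}. \eqn{\gamma \ge 2} keeps \eqn{\mu} in
#' \eqn{(0, 1]}; the boundary \eqn{\gamma = 2} (\eqn{\mu = 1}) is accepted
#' with a warning.
#'
#' @param n number of nodes.
#' @param gammaSF power-law exponent \eqn{\ge 2}.
#' @return Numeric probability vector of length `n`.
#' @examples
#' scaleFreeNodeWeights(2, 3)  # ~(0.586, 0.414)
#' @export
scaleFreeNodeWeights <- function(n, gammaSF) {
  if (gammaSF < 2) stop("gammaSF must be >= 2")
  if (gammaSF == 2)
    warning("gammaSF = 2 gives mu = 1, the boundary of the admissible range")
  mu <- 1 / (gammaSF - 1)
  w <- seq_len(n)^(-mu)
  w / sum(w)
}

#' Build a signed prior confidence matrix from reference networks
#'
#' For every ordered node pair, counts the number of reference networks
#' containing both nodes (`M`), and how often the pair is connected by an
#' activation (`Mact`) or inhibition (`Minh`) edge. The confidence is
#' \eqn{b = (M_{act} - M_{inh})/M}, set to 0 for pairs occurring in no
#' reference. Activation support yields positive, inhibition support
#' negative confidences; conflicting types partially cancel.
#'
#' @param refs list of [SignedNetwork-class] objects (possibly over
#'   different subsets of the node universe).
#' @param nodes node universe; defaults to the union of all reference
#'   node sets. Supplying a universe missing some reference node is an
#'   error.
#' @return Numeric confidence matrix with entries in \[-1, 1\] and zero
#'   diagonal, labelled by `nodes`.
#' @seealso [laplacePrior()]
#' @export
buildConfidenceMatrix <- function(refs, nodes = NULL) {
  if (!length(refs)) stop("at least one reference network is required")
  allNodes <- unique(unlist(lapply(refs, nodeNames)))
  if (is.null(nodes)) nodes <- allNodes
  if (!all(allNodes %in% nodes))
    stop("reference networks mention nodes outside the node universe")
  n <- length(nodes)
  M <- Mact <- Minh <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (ref in refs) {
    idx <- match(nodeNames(ref), nodes)
    M[idx, idx] <- M[idx, idx] + 1
    a <- adjacency(ref)
    Mact[idx, idx] <- Mact[idx, idx] + (a == 1L)
    Minh[idx, idx] <- Minh[idx, idx] + (a == -1L)
  }
  B <- ifelse(M > 0, (Mact - Minh) / pmax(M, 1), 0)
  diag(B) <- 0
  B
}
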