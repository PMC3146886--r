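# Summarisation of network collections (MCMC samples, GA populations),
# ROC/AUC edge-recovery scoring against a known truth, consensus networks
# across chains and convergence diagnostics.

# Normalise the accepted inputs (McmcTrace, list of SignedNetwork, list
# of adjacency matrices) to a list of integer adjacency matrices.
asAdjacencyList <- function(x) {
  if (is(x, "McmcTrace")) return(x@networks)
  if (is.list(x) && length(x)) {
    if (is(x[[1]], "SignedNetwork")) return(lapply(x, adjacency))
    if (is.matrix(x[[1]])) return(x)
  }
  stop("expected an McmcTrace or a list of networks")
}

#' Edge-type frequencies across a network collection
#'
#' For every ordered node pair, the fraction of networks in which the
#' pair is an activation, an inhibition, or empty (the three fractions
#' sum to one).
#'
#' @param x an [McmcTrace-class] or a list of [SignedNetwork-class] /
#'   adjacency matrices over a common node set.
#' @return List of class `edgeFrequencyTable` with matrices `activation`,
#'   `inhibition`, `none`, plus `n` (collection size) and `nodes`.
#' @export
edgeFrequencyTable <- function(x) {
  mats <- asAdjacencyList(x)
  if (!length(mats)) stop("empty network collection")
  n <- nrow(mats[[1]])
  act <- inh <- matrix(0, n, n, dimnames = dimnames(mats[[1]]))
  for (a in mats) {
    act <- act + (a == 1L)
    inh <- inh + (a == -1L)
  }
  act <- act / length(mats)
  inh <- inh / length(mats)
  structure(list(activation = act, inhibition = inh,
                 none = 1 - act - inh, n = length(mats),
                 nodes = rownames(mats[[1]])),
            class = "edgeFrequencyTable")
}

#' Summarise a network collection at an inclusion threshold
#'
#' A typed edge enters the summary network iff its type's frequency in
#' the collection is at least `th` (and positive); when both the
#' activation and the inhibition frequency pass the threshold, the more
#' frequent type wins (an exact tie resolves to activation). High enough
#' thresholds empty the network.
#'
#' @param x a collection as in [edgeFrequencyTable()], or an
#'   `edgeFrequencyTable` itself.
#' @param th inclusion threshold in \[0, 1\].
#' @return A [SignedNetwork-class] (no stimuli attached).
#' @export
summariseNetworks <- function(x, th) {
  stopifnot(th >= 0, th <= 1)
  ft <- if (inherits(x, "edgeFrequencyTable")) x else edgeFrequencyTable(x)
  n <- length(ft$nodes)
  a <- matrix(0L, n, n, dimnames = list(ft$nodes, ft$nodes))
  passA <- ft$activation >= th & ft$activation > 0
  passI <- ft$inhibition >= th & ft$inhibition > 0
  a[passA & (!passI | ft$activation >= ft$inhibition)] <- 1L
  a[passI & (!passA | ft$inhibition > ft$activation)] <- -1L
  diag(a) <- 0L
  SignedNetwork(a)
}

#' ROC curve and AUC of edge recovery against a known truth
#'
#' Edge recovery is scored as a typed classification: every ordered node
#' pair contributes two candidate edges, one activation and one
#' inhibition, whose score is the corresponding edge-type frequency in
#' the collection. A candidate is a true positive only when direction
#' and sign both match the true network — a sign mismatch is a false
#' positive on the wrongly-signed candidate while the true edge stays a
#' false negative. Sweeping the inclusion threshold over the observed
#' frequencies (plus 0 and 1, predicting every candidate scoring at
#' least the threshold) traces the ROC curve; the AUC is the trapezoid
#' area under the (FPR, TPR) points, pinned at (0,0) and (1,1). A
#' collection holding only the true network attains AUC 1; frequencies
#' unrelated to the truth give AUC 1/2 in expectation.
#'
#' @param x a collection as in [edgeFrequencyTable()], or an
#'   `edgeFrequencyTable`.
#' @param truth the true [SignedNetwork-class] (must contain at least one
#'   edge, else the ROC is undefined).
#' @return List with `points` (data.frame `th`, `TP`, `FP`, `TN`, `FN`,
#'   `TPR`, `FPR`) and `auc`.
#' @export
rocAuc <- function(x, truth) {
  ft <- if (inherits(x, "edgeFrequencyTable")) x else edgeFrequencyTable(x)
  tr <- adjacency(truth)
  if (!identical(rownames(tr), ft$nodes))
    stop("collection and truth are over different node sets")
  if (all(tr == 0L)) stop("truth has no edges; ROC undefined")
  off <- row(tr) != col(tr)
  scores <- c(ft$activation[off], ft$inhibition[off])
  labels <- c(tr[off] == 1L, tr[off] == -1L)
  nPos <- sum(labels)
  nNeg <- sum(!labels)
  ths <- sort(unique(c(0, 1, scores)), decreasing = TRUE)
  pts <- do.call(rbind, lapply(ths, function(th) {
    pred <- scores >= th
    tp <- sum(pred & labels)
    fp <- sum(pred & !labels)
    data.frame(th = th, TP = tp, FP = fp, TN = nNeg - fp, FN = nPos - tp,
               TPR = tp / nPos, FPR = fp / nNeg)
  }))
  xy <- unique(rbind(c(0, 0), cbind(pts$FPR, pts$TPR), c(1, 1)))
  xy <- xy[order(xy[, 1], xy[, 2]), , drop = FALSE]
  auc <- sum(diff(xy[, 1]) *
               (utils::head(xy[, 2], -1) + utils::tail(xy[, 2], -1)) / 2)
  list(points = pts, auc = auc)
}

#' Consensus network across per-chain summary networks
#'
#' Per ordered node pair, the modal edge state (activation, inhibition or
#' none) across the summaries wins. Ties are broken in favour of the tied
#' state with the larger posterior frequency averaged over the summaries
#' carrying that state, which requires the per-chain
#' [edgeFrequencyTable()]s; a tie without that information is an error
#' naming the pair.
#'
#' @param summaries list of [SignedNetwork-class] summary networks (one
#'   per chain).
#' @param edgeFreqs optional list of `edgeFrequencyTable`s, parallel to
#'   `summaries`.
#' @return A [SignedNetwork-class].
#' @export
consensusNetwork <- function(summaries, edgeFreqs = NULL) {
  if (!length(summaries)) stop("at least one summary network is required")
  mats <- lapply(summaries, adjacency)
  nodes <- rownames(mats[[1]])
  n <- length(nodes)
  a <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  freqOf <- function(k, i, j, state) {
    ft <- edgeFreqs[[k]]
    switch(as.character(state),
           "1" = ft$activation[i, j],
           "-1" = ft$inhibition[i, j],
           "0" = ft$none[i, j])
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    states <- vapply(mats, `[`, 0L, i, j)
    tab <- table(states)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) {
      a[i, j] <- as.integer(top)
    } else {
      if (is.null(edgeFreqs))
        stop(sprintf("tie at edge %s -> %s needs per-chain posterior frequencies",
                     nodes[i], nodes[j]))
      means <- vapply(top, function(st) {
        ks <- which(states == as.integer(st))
        mean(vapply(ks, freqOf, 0, i = i, j = j, state = as.integer(st)))
      }, 0)
      a[i, j] <- as.integer(top[which.max(means)])
    }
  }
  SignedNetwork(a)
}

#' Convergence diagnostics across MCMC chains
#'
#' Summarises a set of independent chains: the posterior trace of each
#' chain, per-sample activation/inhibition edge counts of the thinned
#' post-burn-in networks, per-edge type frequencies per chain, the
#' cross-chain variance of those frequencies, and the node pairs whose
#' frequency variance exceeds `flagThreshold` — pairs on which the
#' chains disagree and that deserve a closer look before trusting a
#' consensus edge.
#'
#' @param traces list of [McmcTrace-class] objects over a common node
#'   set.
#' @param flagThreshold variance level above which a pair is flagged.
#' @return List with `posterior` (iterations x chains matrix),
#'   `edgeCounts` (data.frame `chain`, `sample`, `nActivation`,
#'   `nInhibition`), `edgeFrequencies` (list of per-chain
#'   `edgeFrequencyTable`s), `variance` (list of `activation` /
#'   `inhibition` variance matrices) and `flagged` (data.frame `source`,
#'   `target`, `maxVariance`).
#' @export
mcmcDiagnostics <- function(traces, flagThreshold = 0.05) {
  if (!length(traces)) stop("at least one trace is required")
  post <- vapply(traces, function(tr) tr@steps$posterior,
                 numeric(nrow(traces[[1]]@steps)))
  post <- matrix(post, ncol = length(traces))
  colnames(post) <- paste0("chain", seq_along(traces))
  counts <- do.call(rbind, lapply(seq_along(traces), function(k) {
    nets <- traces[[k]]@networks
    data.frame(chain = k, sample = seq_along(nets),
               nActivation = vapply(nets, function(a) sum(a == 1L), 1L),
               nInhibition = vapply(nets, function(a) sum(a == -1L), 1L))
  }))
  freqs <- lapply(traces, edgeFrequencyTable)
  varOf <- function(type) {
    stack <- vapply(freqs, `[[`, freqs[[1]][[type]], type)
    arr <- array(stack, dim = c(dim(freqs[[1]][[type]]), length(freqs)))
    v <- apply(arr, c(1, 2), stats::var)
    if (length(freqs) == 1) v[] <- 0
    dimnames(v) <- dimnames(freqs[[1]][[type]])
    v
  }
  variance <- list(activation = varOf("activation"),
                   inhibition = varOf("inhibition"))
  maxVar <- pmax(variance$activation, variance$inhibition)
  diag(maxVar) <- 0
  idx <- which(maxVar > flagThreshold, arr.ind = TRUE)
  flagged <- data.frame(
    source = rownames(maxVar)[idx[, 1]],
    target = colnames(maxVar)[idx[, 2]],
    maxVariance = maxVar[idx])
  flagged <- flagged[order(-flagged$maxVariance), , drop = FALSE]
  list(posterior = post, edgeCounts = counts, edgeFrequencies = freqs,
       variance = variance, flagged = flagged)
}

#' Likelihood/prior ratio diagnostics for tuning lambda
#'
#' Computes the successive differences of the recorded log likelihood and
#' log prior along a chain (the log of the likelihood and prior ratios)
#' and compares their dispersions. The Laplace prior scale `lambda` is
#' well calibrated when both vary on a comparable scale; when the
#' dispersions differ by more than a factor of 10 the result carries a
#' flag and the multiplicative lambda adjustment that would match the
#' scales (prior differences scale as 1/lambda).
#'
#' @param trace an [McmcTrace-class].
#' @return List with `likelihoodDiff`, `priorDiff` (series of length
#'   iterations - 1), `likelihoodScale`, `priorScale` (standard
#'   deviations), `ratio`, `rescaleFlag` and `suggestedLambdaFactor`.
#' @export
ratioDiagnostics <- function(trace) {
  ld <- diff(trace@steps$logLik)
  pd <- diff(trace@steps$logPrior)
  ls <- stats::sd(ld)
  ps <- stats::sd(pd)
  ratio <- if (isTRUE(ls > 0)) ps / ls else NA_real_
  flag <- is.finite(ratio) && (ratio > 10 || ratio < 0.1)
  list(likelihoodDiff = ld, priorDiff = pd,
       likelihoodScale = ls, priorScale = ps, ratio = ratio,
       rescaleFlag = flag,
       suggestedLambdaFactor = if (flag) ratio else 1)
}
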