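#' @include AllClasses.R
NULL

#' Accessors for SignedNetwork and PerturbationData
#'
#' `adjacency()` returns the integer adjacency matrix (row = source,
#' column = target, entries in \{0, 1, -1\}); `nodeNames()` the node
#' labels; `stimuli()` the stimulus labels of a network, or the named list
#' of per-experiment stimulus sets of a data object; `nTimepoints()`,
#' `nReplicates()` and `experimentNames()` describe the measurement grid.
#'
#' @param x a [SignedNetwork-class] or [PerturbationData-class] object.
#' @return See the individual descriptions.
#' @name accessors
#' @aliases adjacency nodeNames stimuli nTimepoints nReplicates
#'   experimentNames
NULL

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setMethod("adjacency", "SignedNetwork", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname accessors
#' @export
setMethod("nodeNames", "SignedNetwork", function(x) rownames(x@adjacency))

#' @rdname accessors
#' @export
setGeneric("stimuli", function(x) standardGeneric("stimuli"))

#' @rdname accessors
#' @export
setMethod("stimuli", "SignedNetwork", function(x) x@stimuli)

#' @rdname accessors
#' @export
setMethod("stimuli", "PerturbationData",
          function(x) metadata(x)$stimuli)

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname accessors
#' @export
setMethod("nTimepoints", "PerturbationData",
          function(x) length(unique(colData(x)$time)))

#' @rdname accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname accessors
#' @export
setMethod("nReplicates", "PerturbationData",
          function(x) length(unique(colData(x)$replicate)))

#' @rdname accessors
#' @export
setGeneric("experimentNames", function(x) standardGeneric("experimentNames"))

#' @rdname accessors
#' @export
setMethod("experimentNames", "PerturbationData",
          function(x) names(metadata(x)$stimuli))

#' Count activation and inhibition edges
#'
#' @param x a [SignedNetwork-class].
#' @return Named integer vector `c(activation = , inhibition = )`.
#' @examples
#' net <- SignedNetwork(matrix(c(0, -1, 1, 0), 2, 2), nodes = c("A", "B"))
#' edgeCount(net)  # one of each
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname edgeCount
#' @export
setMethod("edgeCount", "SignedNetwork", function(x) {
  a <- x@adjacency
  c(activation = sum(a == 1L), inhibition = sum(a == -1L))
})

#' Extract one experiment as an N x T x R array
#'
#' @param x a [PerturbationData-class].
#' @param experiment experiment name (default: the first).
#' @return Numeric array `proteins x times x replicates`, with dimnames;
#'   time points in increasing order.
#' @export
setGeneric("dataArray", function(x, experiment) standardGeneric("dataArray"))

#' @rdname dataArray
#' @export
setMethod("dataArray", "PerturbationData", function(x, experiment) {
  if (missing(experiment)) experiment <- experimentNames(x)[1]
  cd <- colData(x)
  sel <- which(cd$experiment == experiment)
  if (!length(sel)) stop("unknown experiment: ", experiment)
  tt <- sort(unique(cd$time[sel]))
  rr <- sort(unique(cd$replicate[sel]))
  m <- assay(x, 1)[, sel, drop = FALSE]
  # replicate-major column order so the array fills (protein, time, rep)
  ord <- order(match(cd$replicate[sel], rr), match(cd$time[sel], tt))
  array(m[, ord], dim = c(nrow(x), length(tt), length(rr)),
        dimnames = list(rownames(x), tt, rr))
})

#' Log prior probability of a network structure
#'
#' Dispatches on the prior model: [LaplacePrior-class] returns the summed
#' per-edge Laplace log densities; [ScaleFreePrior-class] returns the log
#' of the permutation-averaged structure probability under the power-law
#' degree model. `NULL` means no prior (returns 0, so that the posterior
#' reduces to the likelihood-based score).
#'
#' @param prior a prior object or `NULL`.
#' @param net a [SignedNetwork-class].
#' @return A single finite numeric, the (unnormalised) log prior.
#' @export
setGeneric("logNetworkPrior",
           function(prior, net) standardGeneric("logNetworkPrior"))
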