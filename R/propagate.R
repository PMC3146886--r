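#' Propagate stimulus activity to the system-state matrix
#'
#' Deterministic Boolean effects propagation. Starting from the state in
#' which exactly the stimulus nodes are active, states are updated
#' synchronously: a node is active at the next step iff at least one of
#' its activating parents is active and none of its inhibiting parents
#' is; stimulus nodes are clamped active throughout. The update is
#' iterated until a previously visited global state recurs; the distinct
#' states visited, in order, form the columns of the returned system-state
#' matrix \eqn{\Gamma}.
#'
#' Propagation always terminates (at most \eqn{2^N} states) and is a pure
#' function of the adjacency matrix and the stimulus set. The first
#' column is the stimulus indicator vector and consecutive columns always
#' differ.
#'
#' @param net a [SignedNetwork-class].
#' @param stimuli stimulus node labels; defaults to `stimuli(net)`.
#' @return Logical matrix, nodes x M (`TRUE` = active), rownames = node
#'   labels.
#' @examples
#' adj <- matrix(0L, 3, 3, dimnames = rep(list(c("S", "A", "B")), 2))
#' adj["S", "A"] <- 1L; adj["A", "B"] <- 1L
#' propagate(SignedNetwork(adj, stimuli = "S"))  # {S}, {S,A}, {S,A,B}
#' @export
propagate <- function(net, stimuli = NULL) {
  a <- adjacency(net)
  if (is.null(stimuli)) stimuli <- stimuli(net)
  stimIdx <- match(stimuli, rownames(a))
  if (!length(stimIdx) || anyNA(stimIdx))
    stop("propagation requires a non-empty stimulus set of known nodes")
  act <- a == 1L
  inh <- a == -1L
  n <- nrow(a)
  state <- logical(n)
  state[stimIdx] <- TRUE
  seen <- character()
  states <- list()
  repeat {
    key <- paste(as.integer(state), collapse = "")
    if (key %in% seen) break
    seen <- c(seen, key)
    states[[length(states) + 1L]] <- state
    nxt <- (colSums(act[state, , drop = FALSE]) > 0) &
           (colSums(inh[state, , drop = FALSE]) == 0)
    nxt[stimIdx] <- TRUE
    state <- nxt
  }
  gamma <- do.call(cbind, states)
  rownames(gamma) <- rownames(a)
  colnames(gamma) <- NULL
  gamma
}
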