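#' Read a signed network from disk
#'
#' Two plain-text formats are supported. `"adjacency"`: a tab-separated
#' labelled matrix (header row and first column carry the node labels,
#' row = source, column = target, entries in \{0, 1, -1\}), optionally
#' preceded by a comment line `#stimuli<TAB>label...` naming the stimulus
#' nodes. `"edgelist"`: one edge per line as `source<TAB>type<TAB>target`
#' with type 1 (activation) or -1 (inhibition), SIF-like; the node set is
#' the union of mentioned labels unless `nodes` is given.
#'
#' @param path file to read.
#' @param format `"adjacency"` (default) or `"edgelist"`.
#' @param stimuli stimulus labels; overrides any `#stimuli` line.
#' @param nodes optional node universe for the edge-list format.
#' @return A [SignedNetwork-class].
#' @seealso [writeNetwork()]
#' @export
readNetwork <- function(path, format = c("adjacency", "edgelist"),
                        stimuli = NULL, nodes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path)
  fileStim <- character()
  isStim <- startsWith(lines, "#stimuli")
  if (any(isStim)) {
    fileStim <- strsplit(lines[which(isStim)[1]], "\t", fixed = TRUE)[[1]][-1]
    fileStim <- fileStim[nzchar(fileStim)]
  }
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (format == "adjacency") {
    cells <- strsplit(lines, "\t", fixed = TRUE)
    labels <- cells[[1]][-1]
    n <- length(labels)
    if (length(cells) != n + 1)
      stop("adjacency file: expected ", n, " data rows, found ", length(cells) - 1)
    adj <- matrix(0L, n, n, dimnames = list(labels, labels))
    for (i in seq_len(n)) {
      row <- cells[[i + 1]]
      if (length(row) != n + 1)
        stop("adjacency file: row ", i, " has ", length(row) - 1, " entries, expected ", n)
      vals <- suppressWarnings(as.integer(row[-1]))
      bad <- which(is.na(vals) | !(vals %in% EDGE_STATES))
      if (length(bad))
        stop(sprintf("adjacency file: entry '%s' at row %s, column %s is not in {0, 1, -1}",
                     row[bad[1] + 1], row[1], labels[bad[1]]))
      adj[i, ] <- vals
    }
    rn <- vapply(cells[-1], `[`, "", 1)
    if (!identical(rn, labels))
      stop("adjacency file: row labels do not match column labels")
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    parts <- lapply(parts, function(p) p[nzchar(trimws(p))])
    bad <- which(vapply(parts, length, 1L) != 3)
    if (length(bad))
      stop("edge list: line ", bad[1], " does not have 3 fields")
    src <- vapply(parts, `[`, "", 1)
    typ <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
    tgt <- vapply(parts, `[`, "", 3)
    if (any(is.na(typ) | !(typ %in% c(1L, -1L))))
      stop("edge list: edge type must be 1 or -1")
    labels <- if (is.null(nodes)) unique(c(src, tgt)) else nodes
    if (!all(c(src, tgt) %in% labels))
      stop("edge list mentions nodes outside the given node universe")
    adj <- matrix(0L, length(labels), length(labels),
                  dimnames = list(labels, labels))
    adj[cbind(match(src, labels), match(tgt, labels))] <- typ
  }
  SignedNetwork(adj, stimuli = if (is.null(stimuli)) fileStim else stimuli)
}

#' Write a signed network to disk
#'
#' Inverse of [readNetwork()]; the adjacency format round-trips a network
#' (including its stimulus set) bit-exactly.
#'
#' @param net a [SignedNetwork-class].
#' @param path output file.
#' @param format `"adjacency"` (default) or `"edgelist"`.
#' @export
writeNetwork <- function(net, path, format = c("adjacency", "edgelist")) {
  format <- match.arg(format)
  a <- adjacency(net)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(stimuli(net)))
    writeLines(paste(c("#stimuli", stimuli(net)), collapse = "\t"), con)
  if (format == "adjacency") {
    writeLines(paste(c("", rownames(a)), collapse = "\t"), con)
    for (i in seq_len(nrow(a)))
      writeLines(paste(c(rownames(a)[i], a[i, ]), collapse = "\t"), con)
  } else {
    idx <- which(a != 0L, arr.ind = TRUE)
    if (nrow(idx))
      writeLines(paste(rownames(a)[idx[, 1]], a[idx], colnames(a)[idx[, 2]],
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Read longitudinal perturbation data
#'
#' Expects a tab-separated table whose first column (`protein`) holds the
#' protein labels and whose remaining column names encode
#' `experiment:time:replicate`, e.g. `EGF+HRG:10:2` for the second
#' replicate of the 10-minute time point of the experiment stimulating
#' EGF and HRG. The experiment token doubles as its stimulus set: labels
#' joined by `+`, each of which must be a measured protein. Column order
#' on disk is irrelevant; the in-memory object is canonically ordered.
#'
#' @param path file to read.
#' @return A [PerturbationData-class].
#' @seealso [writePerturbationData()]
#' @export
readPerturbationData <- function(path) {
  if (!file.exists(path)) stop("data file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("data file needs a protein column plus measurements")
  proteins <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- proteins
  key <- strsplit(colnames(m), ":", fixed = TRUE)
  bad <- which(vapply(key, length, 1L) != 3)
  if (length(bad))
    stop("malformed column header (need experiment:time:replicate): ",
         colnames(m)[bad[1]])
  experiment <- vapply(key, `[`, "", 1)
  time <- as.numeric(vapply(key, `[`, "", 2))
  replicate <- as.integer(vapply(key, `[`, "", 3))
  if (anyNA(time) || anyNA(replicate))
    stop("non-numeric time or replicate in a column header")
  stim <- lapply(unique(experiment), function(e)
    strsplit(e, "+", fixed = TRUE)[[1]])
  names(stim) <- unique(experiment)
  PerturbationData(m, experiment, time, replicate, stim)
}

#' Write longitudinal perturbation data
#'
#' @param x a [PerturbationData-class].
#' @param path output file.
#' @export
writePerturbationData <- function(x, path) {
  cd <- colData(x)
  hdr <- sprintf("%s:%s:%d", cd$experiment,
                 format(cd$time, trim = TRUE, scientific = FALSE),
                 cd$replicate)
  m <- assay(x, 1)
  tab <- data.frame(protein = rownames(x), m, check.names = FALSE)
  colnames(tab) <- c("protein", hdr)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a prior confidence matrix
#'
#' A labelled tab-separated matrix of signed edge confidences in
#' \[-1, 1\] (rows = sources, columns = targets), as consumed by
#' [laplacePrior()].
#'
#' @param path file to read or write.
#' @return `readConfidenceMatrix`: a numeric matrix with dimnames.
#' @export
readConfidenceMatrix <- function(path) {
  if (!file.exists(path)) stop("confidence matrix file not found: ", path)
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  B <- as.matrix(tab)
  if (nrow(B) != ncol(B) || !identical(rownames(B), colnames(B)))
    stop("confidence matrix must be square with matching labels")
  if (any(abs(B) > 1)) stop("confidences must lie in [-1, 1]")
  B
}

#' @rdname readConfidenceMatrix
#' @param B numeric confidence matrix with matching dimnames.
#' @export
writeConfidenceMatrix <- function(B, path) {
  tab <- data.frame(B, check.names = FALSE)
  utils::write.table(cbind(data.frame(" " = rownames(B), check.names = FALSE),
                           tab),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a network collection (stacked edge lists)
#'
#' Parses the `networks.tsv` format written by [writeTrace()] and the
#' GA/CLI outputs: columns `sample`, `source`, `type`, `target`, one row
#' per edge. Samples without edges are represented by their absence only
#' if `nSamples` is given.
#'
#' @param path file to read.
#' @param nodes node universe (labels); required so that isolated nodes
#'   and empty networks round-trip.
#' @param nSamples total number of samples in the collection (defaults
#'   to the largest sample index present).
#' @return List of adjacency matrices.
#' @export
readNetworkCollection <- function(path, nodes, nSamples = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(nSamples))
    nSamples <- if (nrow(tab)) max(tab$sample) else 0L
  lapply(seq_len(nSamples), function(k) {
    a <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    sub <- tab[tab$sample == k, , drop = FALSE]
    if (nrow(sub))
      a[cbind(match(sub$source, nodes), match(sub$target, nodes))] <-
        as.integer(sub$type)
    a
  })
}
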