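#' Build a character-transition network
#'
#' Turns a transcript's transition structure into a directed weighted graph
#' with one node per observed character.  Two weight modes are supported:
#' \code{"raw_count"} (edge weight = observed transition count; default
#' threshold 0 retains exactly the observed pairs) and
#' \code{"smoothed_prob"} (edge weight = Laplace-smoothed transition
#' probability; default threshold 0.01 suppresses pure-smoothing edges of
#' magnitude \eqn{\alpha / (\mathrm{rowsum} + 27\alpha)}).  Symbols
#' incident to no retained edge are omitted.
#'
#' @param x A [TransitionModel-class] object, or a 27x27 matrix (counts for
#'   \code{"raw_count"}, smoothed probabilities for \code{"smoothed_prob"}).
#' @param weightKind \code{"raw_count"} (default) or \code{"smoothed_prob"}.
#' @param edgeThreshold Retain edges with weight strictly greater than
#'   this; must be >= 0.  Default 0 for counts, 0.01 for probabilities.
#' @return An [igraph][igraph::igraph-package] directed graph with vertex
#'   attribute \code{symbol} and edge attributes \code{weight} and
#'   \code{kind}.  Export with [exportGraphML()].
#' @examples
#' g <- buildTransitionNetwork(countTransitions(encodeTranscript("abc")))
#' igraph::ecount(g)  # a->b, b->c
#' @export
buildTransitionNetwork <- function(x, weightKind = c("raw_count", "smoothed_prob"),
                                   edgeThreshold = NULL) {
  weightKind <- match.arg(weightKind)
  if (is(x, "TransitionModel")) {
    W <- if (weightKind == "raw_count") transitionCounts(x) else transitionProbs(x)
  } else {
    W <- as.matrix(x)
  }
  if (!all(dim(W) == .K)) stop("expected a 27x27 matrix")
  if (is.null(edgeThreshold)) {
    edgeThreshold <- if (weightKind == "raw_count") 0 else 0.01
  }
  if (edgeThreshold < 0) stop("edgeThreshold must be >= 0")
  keep <- which(W > edgeThreshold, arr.ind = TRUE)
  labels <- alphabetLabels()
  edges <- data.frame(
    from = labels[keep[, 1L]],
    to = labels[keep[, 2L]],
    weight = W[keep],
    kind = weightKind,
    stringsAsFactors = FALSE
  )
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes, symbol = nodes,
                          stringsAsFactors = FALSE)
  )
  g
}

#' Structural rigidity summary of a transcript's transitions
#'
#' Summaries that operationalize the "rigid vs. flexible" contrast between
#' transition networks: \code{self_loop_mass} is the fraction of transition
#' events that return to the same character (repetitive production);
#' \code{mean_out_entropy} is the count-weighted mean Shannon entropy (in
#' bits) of the unsmoothed conditional next-character distributions over
#' observed rows, bounded by \eqn{\log_2 27 \approx 4.75}; low entropy plus
#' high self-loop mass indicates constrained, repetitive sequencing.
#' Weighting rows by their event mass keeps rare rows from dominating the
#' summary.  \code{n_nodes}/\code{n_edges} count the observed symbols and
#' distinct observed transitions; \code{edge_density} is
#' \code{n_edges / n_nodes^2} (directed, self-loops allowed).
#'
#' @param x A [TransitionModel-class] object or a 27x27 count matrix with
#'   at least one event.
#' @return A list: \code{self_loop_mass}, \code{mean_out_entropy},
#'   \code{n_nodes}, \code{n_edges}, \code{edge_density}.
#' @examples
#' summarizeTransitions(countTransitions(rep(1L, 5)))$self_loop_mass  # 1
#' @export
summarizeTransitions <- function(x) {
  counts <- if (is(x, "TransitionModel")) transitionCounts(x) else as.matrix(x)
  if (!all(dim(counts) == .K) || any(counts < 0)) {
    stop("expected a non-negative 27x27 count matrix")
  }
  n <- sum(counts)
  if (n < 1) stop("zero transition events: summary undefined")
  rs <- rowSums(counts)
  obsRows <- which(rs > 0)
  ent <- vapply(obsRows, function(i) {
    p <- counts[i, ] / rs[i]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  observed <- counts > 0
  nodes <- sort(unique(c(which(rowSums(observed) > 0), which(colSums(observed) > 0))))
  nEdges <- sum(observed)
  list(self_loop_mass = sum(diag(counts)) / n,
       mean_out_entropy = sum((rs[obsRows] / n) * ent),
       n_nodes = length(nodes),
       n_edges = nEdges,
       edge_density = nEdges / length(nodes)^2)
}

#' Per-transcript network summary table
#'
#' Applies [summarizeTransitions()] to a list of fitted
#' [TransitionModel-class] objects (as produced by [buildFingerprints()])
#' and returns one row per transcript.
#'
#' @param models List of [TransitionModel-class] objects.
#' @return Data.frame with columns \code{transcript_id}, \code{group},
#'   \code{self_loop_mass}, \code{mean_out_entropy}, \code{n_nodes},
#'   \code{n_edges}, \code{edge_density}.
#' @export
networkSummaryTable <- function(models) {
  stopifnot(length(models) > 0L)
  rows <- lapply(models, function(m) {
    s <- summarizeTransitions(m)
    data.frame(transcript_id = m@transcriptId, group = m@group,
               self_loop_mass = s$self_loop_mass,
               mean_out_entropy = s$mean_out_entropy,
               n_nodes = s$n_nodes, n_edges = s$n_edges,
               edge_density = s$edge_density,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a transition network as GraphML
#'
#' @param graph An igraph graph from [buildTransitionNetwork()].
#' @param path Output file path (written atomically).
#' @return Invisibly, the path.
#' @export
exportGraphML <- function(graph, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".graphml")
  igraph::write_graph(graph, tmp, format = "graphml")
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}
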