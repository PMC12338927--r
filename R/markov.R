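#' @useDynLib charmark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Count first-order character transitions
#'
#' Tallies adjacent pairs of an encoded transcript into a 27x27 matrix:
#' entry (i, j) is the number of positions t with \code{seq[t] == i} and
#' \code{seq[t+1] == j}.  The final character emits no outgoing event, so a
#' length-L sequence contributes exactly L - 1 events; there is no
#' wrap-around.
#'
#' @param seq Integer index sequence in \code{1:27} (see
#'   [encodeTranscript()]), length >= 2.
#' @return Integer 27x27 matrix with dimnames [alphabetLabels()].
#' @examples
#' cts <- countTransitions(encodeTranscript("abab"))
#' cts["a", "b"]  # 2
#' sum(cts)       # 3 events for a length-4 sequence
#' @export
countTransitions <- function(seq) {
  seq <- as.integer(seq)
  if (length(seq) < 2L) {
    stop("transcript too short: need at least 2 characters for one transition event")
  }
  if (anyNA(seq) || any(seq < 1L | seq > .K)) {
    stop("sequence indices must all lie in 1:27")
  }
  L <- length(seq)
  cell <- (seq[-L] - 1L) * .K + seq[-1L]
  counts <- matrix(tabulate(cell, nbins = .K * .K), nrow = .K, byrow = TRUE,
                   dimnames = list(alphabetLabels(), alphabetLabels()))
  storage.mode(counts) <- "integer"
  counts
}

#' Laplace-smooth transition counts into a row-stochastic matrix
#'
#' Applies additive (Laplace) smoothing to a square count matrix:
#' \deqn{P_{ij} = (n_{ij} + \alpha) / (\sum_u n_{iu} + k\alpha)}
#' with k the number of states.  Any \code{alpha > 0} makes every entry
#' strictly positive, which guarantees a unique stationary distribution
#' (Perron--Frobenius).  \code{alpha = 0} (maximum likelihood) is permitted
#' only when every row has at least one observed count.
#'
#' @param counts Square non-negative count matrix (any k >= 2; the pipeline
#'   uses k = 27).
#' @param alpha Smoothing constant, default \code{0.01}.
#' @return Row-stochastic numeric matrix of the same dimension.
#' @examples
#' cts <- countTransitions(encodeTranscript("aab"))
#' P <- smoothTransitions(cts, alpha = 0.01)
#' rowSums(P)  # all 1
#' @export
smoothTransitions <- function(counts, alpha = 0.01) {
  counts <- as.matrix(counts)
  k <- nrow(counts)
  if (ncol(counts) != k || k < 2L) stop("counts must be a square k x k matrix, k >= 2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("invalid smoothing parameter: alpha must be a single number >= 0")
  }
  rs <- rowSums(counts)
  if (alpha == 0 && any(rs == 0)) {
    stop("alpha = 0 with an all-zero row: unsmoothed estimate undefined ",
         "(row ", which(rs == 0)[1L], ")")
  }
  P <- (counts + alpha) / (rs + k * alpha)
  dimnames(P) <- dimnames(counts)
  P
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solves \eqn{\pi = \pi P}, \eqn{\sum_i \pi_i = 1} by power iteration from
#' the uniform vector, stopping when the L1 change between successive
#' iterates falls below \code{tol} (default 1e-12, iteration cap 1e5).  For
#' the strictly positive matrices produced by Laplace smoothing the fixed
#' point is unique and convergence is geometric.  After iterating, entries
#' below zero by numerical noise are clipped at 0 and the vector
#' renormalized; the achieved residual \eqn{\|\pi P - \pi\|_\infty} is
#' returned and must be <= 1e-10, otherwise a convergence error reporting
#' the achieved residual is raised.
#'
#' @param P Row-stochastic k x k matrix, k >= 2 (rows must sum to 1 within
#'   1e-8; entries non-negative).
#' @param tol Successive-iterate L1 stopping tolerance.
#' @param maxIter Iteration cap.
#' @return A list with elements \code{pi} (length-k probability vector,
#'   named when \code{P} has rownames), \code{residual}
#'   (\eqn{\|\pi P - \pi\|_\infty}) and \code{iterations}.
#' @examples
#' P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
#' stationaryDistribution(P)$pi  # 5/6, 1/6
#' @export
stationaryDistribution <- function(P, tol = 1e-12, maxIter = 1e5) {
  P <- as.matrix(P)
  k <- nrow(P)
  if (ncol(P) != k || k < 2L) stop("P must be a square k x k matrix, k >= 2")
  if (any(!is.finite(P)) || any(P < 0)) {
    stop("invalid transition matrix: entries must be finite and non-negative")
  }
  if (any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("invalid transition matrix: rows must sum to 1 (max deviation ",
         format(max(abs(rowSums(P) - 1)), digits = 3), ")")
  }
  sol <- .stationary_power_cpp(P, tol, as.integer(maxIter))
  pi <- sol$pi
  if (any(pi < -1e-12)) {
    stop("stationary solve produced a negative component of magnitude ",
         format(-min(pi), digits = 3))
  }
  pi[pi < 0] <- 0
  pi <- pi / sum(pi)
  resid <- max(abs(drop(pi %*% P) - pi))
  if (resid > 1e-10) {
    stop("stationary distribution failed to converge: achieved residual ",
         format(resid, digits = 6), " > 1e-10 after ", sol$iterations,
         " iterations")
  }
  if (!is.null(rownames(P))) names(pi) <- rownames(P)
  list(pi = pi, residual = resid, iterations = sol$iterations)
}

#' Fit the full per-transcript character Markov model
#'
#' Composes the whole estimation chain for one transcript:
#' [normalizeText()] then [encodeTranscript()] then [countTransitions()]
#' then [smoothTransitions()] then [stationaryDistribution()], returning a
#' [TransitionModel-class] object whose stationary distribution is the
#' transcript's 27-dimensional fingerprint.
#'
#' @param text Raw transcript text (a single string).
#' @param transcriptId Identifier attached to the model.
#' @param group Group label (\code{"dementia"}, \code{"control"} or
#'   \code{"unlabeled"}).
#' @param alpha Laplace smoothing constant (default 0.01).
#' @param collapseSpaces Passed to [normalizeText()].
#' @return A [TransitionModel-class] object.
#' @examples
#' m <- transcriptModel("the boy took the cookie", "t1")
#' steadyState(m)["space"]
#' @export
transcriptModel <- function(text, transcriptId = "transcript", group = "unlabeled",
                            alpha = 0.01, collapseSpaces = TRUE) {
  norm <- normalizeText(text, collapseSpaces = collapseSpaces)
  seq <- tryCatch(encodeTranscript(norm), error = function(e) {
    stop("transcript '", transcriptId, "': ", conditionMessage(e), call. = FALSE)
  })
  counts <- countTransitions(seq)
  P <- smoothTransitions(counts, alpha = alpha)
  sol <- stationaryDistribution(P)
  methods::new("TransitionModel",
               transcriptId = as.character(transcriptId),
               group = as.character(group),
               counts = counts, probs = P, alpha = alpha,
               pi = unname(sol$pi), residual = sol$residual)
}

#' Steady-state fingerprint of a single transcript
#'
#' Convenience wrapper around [transcriptModel()] returning just the
#' stationary distribution.
#'
#' @inheritParams transcriptModel
#' @return Named numeric vector of length 27 summing to 1.
#' @export
transcriptSteadyState <- function(text, alpha = 0.01, collapseSpaces = TRUE) {
  steadyState(transcriptModel(text, alpha = alpha,
                              collapseSpaces = collapseSpaces))
}
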