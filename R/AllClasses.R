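#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

.GROUP_LEVELS <- c("dementia", "control", "unlabeled")

#' Per-transcript character-transition model
#'
#' Holds everything estimated from one transcript: the raw 27x27 transition
#' counts, the Laplace-smoothed row-stochastic transition matrix, the
#' smoothing constant, and the stationary distribution (the transcript's
#' fingerprint) together with the achieved fixed-point residual
#' \eqn{\|\pi P - \pi\|_\infty}.
#'
#' @slot transcriptId Single transcript identifier.
#' @slot group Group label, one of \code{"dementia"}, \code{"control"},
#'   \code{"unlabeled"}.
#' @slot counts 27x27 integer matrix of observed transition counts.
#' @slot probs 27x27 Laplace-smoothed row-stochastic matrix.
#' @slot alpha Laplace smoothing constant used.
#' @slot pi Stationary distribution (length 27, sums to 1).
#' @slot residual Achieved \eqn{\|\pi P - \pi\|_\infty}.
#'
#' @seealso [transcriptModel()], [steadyState()], [transitionCounts()],
#'   [transitionProbs()]
#' @exportClass TransitionModel
setClass("TransitionModel",
  representation(
    transcriptId = "character",
    group = "character",
    counts = "matrix",
    probs = "matrix",
    alpha = "numeric",
    pi = "numeric",
    residual = "numeric"
  )
)

setValidity("TransitionModel", function(object) {
  msg <- character()
  if (length(object@transcriptId) != 1L || !nzchar(object@transcriptId))
    msg <- c(msg, "transcriptId must be a single non-empty string")
  if (length(object@group) != 1L || !object@group %in% .GROUP_LEVELS)
    msg <- c(msg, "group must be one of dementia/control/unlabeled")
  if (!all(dim(object@counts) == .K) || any(object@counts < 0))
    msg <- c(msg, "counts must be a non-negative 27x27 matrix")
  if (!all(dim(object@probs) == .K))
    msg <- c(msg, "probs must be 27x27")
  if (any(abs(rowSums(object@probs) - 1) > 1e-12))
    msg <- c(msg, "probs rows must sum to 1 within 1e-12")
  if (length(object@pi) != .K || any(object@pi < 0) ||
      abs(sum(object@pi) - 1) > 1e-12)
    msg <- c(msg, "pi must be a length-27 probability vector (sum 1 within 1e-12)")
  if (length(object@residual) != 1L || object@residual > 1e-10)
    msg <- c(msg, "stationary residual must be <= 1e-10")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TransitionModel", function(object) {
  top <- order(object@pi, decreasing = TRUE)[1:3]
  cat("TransitionModel for transcript '", object@transcriptId,
      "' (group: ", object@group, ")\n", sep = "")
  cat("  transition events:", sum(object@counts),
      " | smoothing alpha:", object@alpha, "\n")
  cat("  top stationary symbols:",
      paste(sprintf("%s=%.3f", alphabetLabels()[top], object@pi[top]),
            collapse = ", "), "\n")
  cat("  fixed-point residual:", format(object@residual, digits = 3), "\n")
  invisible(NULL)
})

#' Container for steady-state character fingerprints
#'
#' `CharFingerprints` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' the single assay \code{"pi"} is the 27 x n matrix of stationary character
#' probabilities (rows = the 27 alphabet symbols in fixed order a--z then
#' space; columns = transcripts), and \code{colData} carries the transcript
#' id and group label for every column.  All downstream screening,
#' clustering and classification operate on this object.
#'
#' Use the [CharFingerprints()] constructor or [buildFingerprints()]; access
#' the n x 27 feature matrix with [fingerprintMatrix()] and the labels with
#' [groupLabels()] / [transcriptIds()].
#'
#' @exportClass CharFingerprints
setClass("CharFingerprints", contains = "SummarizedExperiment")

setValidity("CharFingerprints", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assay(object, "pi")
  if (nrow(object) != .K || !identical(rownames(object), alphabetLabels()))
    msg <- c(msg, "must have exactly 27 rows named a..z, space")
  if (any(a < 0))
    msg <- c(msg, "fingerprint entries must be non-negative")
  if (ncol(a) && any(abs(colSums(a) - 1) > 1e-10))
    msg <- c(msg, "every fingerprint must sum to 1 within 1e-10")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("transcript_id", "group") %in% colnames(cd)))
    msg <- c(msg, "colData must contain transcript_id and group")
  else {
    if (anyDuplicated(cd$transcript_id))
      msg <- c(msg, "transcript ids must be unique")
    if (!all(cd$group %in% .GROUP_LEVELS))
      msg <- c(msg, "group labels must be dementia/control/unlabeled")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CharFingerprints object
#'
#' @param values Numeric n x 27 matrix of stationary distributions, one row
#'   per transcript, columns in alphabet order (a--z, space).
#' @param transcriptIds Character vector of unique ids, length n.
#' @param groups Character vector of group labels (\code{"dementia"},
#'   \code{"control"} or \code{"unlabeled"}), length n.
#' @return A [CharFingerprints-class] object with one column per transcript.
#' @examples
#' v <- matrix(1 / 27, nrow = 2, ncol = 27)
#' fp <- CharFingerprints(v, c("t1", "t2"), c("dementia", "control"))
#' fingerprintMatrix(fp)[, 1:3]
#' @export
CharFingerprints <- function(values, transcriptIds, groups) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == .K,
            nrow(values) == length(transcriptIds),
            length(groups) == length(transcriptIds))
  a <- t(values)
  dimnames(a) <- list(alphabetLabels(), transcriptIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(pi = a),
    colData = S4Vectors::DataFrame(
      transcript_id = as.character(transcriptIds),
      group = as.character(groups),
      row.names = transcriptIds
    )
  )
  methods::new("CharFingerprints", se)
}

#' @describeIn CharFingerprints Compact display.
#' @param object A `CharFingerprints` object.
#' @export
setMethod("show", "CharFingerprints", function(object) {
  g <- table(groupLabels(object))
  cat("CharFingerprints:", ncol(object), "transcripts x", nrow(object),
      "character features\n")
  cat("  groups:", paste(sprintf("%s=%d", names(g), g), collapse = ", "), "\n")
  if (ncol(object)) {
    sp <- fingerprintMatrix(object)[, "space"]
    cat("  space stationary mass: mean", sprintf("%.4f", mean(sp)),
        " range [", sprintf("%.4f", min(sp)), ",",
        sprintf("%.4f", max(sp)), "]\n")
  }
  invisible(NULL)
})

#' Accessors for CharFingerprints and TransitionModel objects
#'
#' `fingerprintMatrix` returns the n x 27 matrix of stationary distributions
#' (rows = transcripts, columns = a--z, space); `transcriptIds` and
#' `groupLabels` return the aligned id and group vectors; `steadyState`
#' returns a transcript's stationary distribution; `transitionCounts` and
#' `transitionProbs` return a model's count and smoothed probability
#' matrices.
#'
#' @param x A [CharFingerprints-class] or [TransitionModel-class] object.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fingerprintMatrix", function(x) standardGeneric("fingerprintMatrix"))
#' @rdname accessors
#' @export
setMethod("fingerprintMatrix", "CharFingerprints", function(x) {
  t(SummarizedExperiment::assay(x, "pi"))
})

#' @rdname accessors
#' @export
setGeneric("transcriptIds", function(x) standardGeneric("transcriptIds"))
#' @rdname accessors
#' @export
setMethod("transcriptIds", "CharFingerprints", function(x) {
  as.character(SummarizedExperiment::colData(x)$transcript_id)
})

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setMethod("groupLabels", "CharFingerprints", function(x) {
  as.character(SummarizedExperiment::colData(x)$group)
})

#' @rdname accessors
#' @export
setGeneric("steadyState", function(x) standardGeneric("steadyState"))
#' @rdname accessors
#' @export
setMethod("steadyState", "TransitionModel", function(x) {
  stats::setNames(x@pi, alphabetLabels())
})

#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setMethod("transitionCounts", "TransitionModel", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("transitionProbs", function(x) standardGeneric("transitionProbs"))
#' @rdname accessors
#' @export
setMethod("transitionProbs", "TransitionModel", function(x) x@probs)
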