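.asFeatureMatrix <- function(x) {
  if (is(x, "CharFingerprints")) fingerprintMatrix(x) else as.matrix(x)
}

#' k-means clustering with silhouette-based selection of k
#'
#' Runs k-means (Euclidean, multiple restarts, seeded) on the raw
#' steady-state vectors for every candidate k, scores each solution by the
#' mean silhouette width, and returns the k that maximizes it together with
#' its assignments.  Clustering operates on the full 27-dimensional
#' fingerprints, not on PCA scores; PCA is visualization-only
#' (see [pcaProject()]).
#'
#' When group labels are available, \code{agreement} reports the best
#' cluster-to-label mapping accuracy (each cluster mapped to the majority
#' group inside it), which is invariant to relabelling the clusters.
#'
#' @param x A [CharFingerprints-class] object or an n x p numeric matrix.
#' @param kRange Candidate numbers of clusters (default \code{2:8}; must
#'   start at >= 2 and n must exceed \code{max(kRange)}).
#' @param nstart Random restarts per k (default 10).
#' @param seed Integer seed; fixed seed gives identical selection and
#'   assignments.
#' @return A list: \code{kSelected}, \code{assignments} (integer labels in
#'   \code{1:kSelected}), \code{silhouetteByK} (named numeric),
#'   \code{agreement} (best label-mapping accuracy in [0, 1], `NA` without
#'   two-group labels).
#' @export
clusterFingerprints <- function(x, kRange = 2:8, nstart = 10L, seed = 1L) {
  X <- .asFeatureMatrix(x)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 2L)) stop("kRange must start at 2 or more")
  n <- nrow(X)
  if (n <= max(kRange)) {
    stop("need more points (", n, ") than the largest candidate k (",
         max(kRange), ")")
  }
  if (all(apply(X, 2L, stats::var) < 1e-30)) {
    stop("degenerate data: all points identical, silhouette undefined")
  }
  d <- stats::dist(X)
  sil <- stats::setNames(numeric(length(kRange)), kRange)
  fits <- vector("list", length(kRange))
  for (i in seq_along(kRange)) {
    k <- kRange[i]
    set.seed(seed + k)  # per-k stream: result independent of kRange order
    fits[[i]] <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100L)
    sw <- cluster::silhouette(fits[[i]]$cluster, d)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- which.max(sil)  # ties resolve to the smallest k
  assignments <- fits[[best]]$cluster
  agreement <- NA_real_
  if (is(x, "CharFingerprints")) {
    g <- groupLabels(x)
    if (length(unique(g)) == 2L) {
      tab <- table(assignments, g)
      agreement <- sum(apply(tab, 1L, max)) / n
    }
  }
  list(kSelected = kRange[best],
       assignments = unname(assignments),
       silhouetteByK = sil,
       agreement = agreement)
}

#' Two-dimensional PCA projection of fingerprints
#'
#' Mean-centers the columns (no variance scaling: all 27 features are
#' probabilities on a common scale) and projects onto the top two principal
#' axes.  Eigenvector sign is arbitrary, so a deterministic convention is
#' applied: the largest-magnitude loading of each component is made
#' positive, keeping output files diffable across runs.
#'
#' @param x A [CharFingerprints-class] object or an n x p numeric matrix,
#'   n >= 3.
#' @return A list: \code{coords} (n x 2 score matrix, columns \code{pc1},
#'   \code{pc2}), \code{explainedVarianceRatio} (length 2, non-increasing),
#'   \code{loadings} (p x 2 matrix of component loadings).
#' @export
pcaProject <- function(x) {
  X <- .asFeatureMatrix(x)
  if (nrow(X) < 3L) stop("PCA projection needs at least 3 transcripts")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  var <- pc$sdev^2
  ratio <- var / sum(var)
  ncomp <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  sco <- pc$x[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  if (ncomp < 2L) {  # degenerate p = 1 input
    rot <- cbind(rot, 0)
    sco <- cbind(sco, 0)
  }
  colnames(sco) <- colnames(rot) <- c("pc1", "pc2")
  if (is(x, "CharFingerprints")) rownames(sco) <- transcriptIds(x)
  list(coords = sco,
       explainedVarianceRatio = c(ratio, 0, 0)[1:2],
       loadings = rot)
}
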