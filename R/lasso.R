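#' ROC curve points and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores (predict positive
#' when score >= threshold), returning the ordered (FPR, TPR) points with
#' the (0, 0) and (1, 1) anchors, and the area under the curve by the
#' trapezoidal rule.  With tied scores the trapezoid gives each tied
#' positive/negative pair half credit, so the AUC equals the Mann-Whitney
#' concordance probability \eqn{P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)}.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @return A list: \code{points} (data.frame \code{fpr}, \code{tpr},
#'   \code{threshold}; the anchors carry \code{Inf} / \code{-Inf}
#'   thresholds) and \code{auc}.
#' @examples
#' rocCurvePoints(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc  # 0.75
#' @export
rocCurvePoints <- function(scores, labels) {
  y <- .asBinary(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    tpr[i] <- sum(pred & y == 1L) / nPos
    fpr[i] <- sum(pred & y == 0L) / nNeg
  }
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                    threshold = c(Inf, thr, -Inf))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

.asBinary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(as.integer(labels == levels(labels)[2L]))
  }
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("labels must take exactly two values")
  as.integer(labels == u[2L])
}

.stratifiedFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  fold
}

.zscoreFit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

.zscoreApply <- function(X, z) sweep(sweep(X, 2L, z$mu), 2L, z$sd, "/")

# Mean inner-CV AUC for every lambda in the grid on (X, y); used for the
# penalty-strength selection inside each training fold.
.innerCvAuc <- function(X, y, lambdaGrid, innerFolds) {
  fold <- .stratifiedFolds(y, innerFolds)
  aucs <- matrix(NA_real_, innerFolds, length(lambdaGrid))
  for (f in seq_len(innerFolds)) {
    tr <- fold != f
    z <- .zscoreFit(X[tr, , drop = FALSE])
    fit <- glmnet::glmnet(.zscoreApply(X[tr, , drop = FALSE], z), y[tr],
                          family = "binomial", alpha = 1,
                          lambda = lambdaGrid, standardize = FALSE)
    pred <- stats::predict(fit, .zscoreApply(X[!tr, , drop = FALSE], z),
                           s = lambdaGrid, type = "response")
    for (l in seq_along(lambdaGrid)) {
      aucs[f, l] <- tryCatch(rocCurvePoints(pred[, l], y[!tr])$auc,
                             error = function(e) NA_real_)
    }
  }
  colMeans(aucs, na.rm = TRUE)
}

#' L1-penalized logistic regression with cross-validated ROC-AUC
#'
#' Fits and evaluates a lasso logistic classifier on the 27 steady-state
#' character features.  The protocol is stratified \code{nFolds}-fold
#' cross-validation; inside each training fold the features are z-scored
#' (statistics from the training fold only), the penalty strength is chosen
#' from \code{lambdaGrid} by inner 3-fold AUC, and the model is refit at
#' that strength; the AUC of each held-out fold comes from the predicted
#' probabilities via [rocCurvePoints()].  The reported coefficients come
#' from a final fit on all data at a strength chosen the same way, mapped
#' back to the original probability scale.
#'
#' The grid is parameterized directly by the lasso penalty \eqn{\lambda}
#' (larger = stronger penalty = sparser model); the default 20 log-spaced
#' values from 1e-4 to 1 cover the useful range for standardized designs
#' with a few hundred transcripts.
#'
#' @param x A [CharFingerprints-class] object, or an n x p numeric matrix
#'   (then supply \code{labels}).
#' @param labels Optional binary labels when \code{x} is a plain matrix;
#'   for fingerprints, \code{"dementia"} is the positive class.
#' @param nFolds Outer folds (default 5); both classes must have at least
#'   \code{nFolds} members.
#' @param lambdaGrid Decreasing-sorted internally; default
#'   \code{10^seq(-4, 0, length.out = 20)}.
#' @param innerFolds Inner folds for penalty selection (default 3).
#' @param seed Integer seed controlling every fold split.
#' @return A list: \code{cvAucMean}, \code{cvAucPerFold},
#'   \code{selectedFeatures} (data.frame \code{character},
#'   \code{coefficient}; nonzero coefficients only, original scale),
#'   \code{regularizationChosen} (the final-fit lambda), \code{nFolds},
#'   \code{seed}, \code{lambdaGrid}, \code{oofScores} (pooled out-of-fold
#'   predicted probabilities, aligned with the input rows) and
#'   \code{labels} (the 0/1 response used).
#' @export
lassoClassifier <- function(x, labels = NULL, nFolds = 5L,
                            lambdaGrid = 10^seq(-4, 0, length.out = 20),
                            innerFolds = 3L, seed = 1L) {
  if (is(x, "CharFingerprints")) {
    X <- fingerprintMatrix(x)
    g <- groupLabels(x)
    if (!all(g %in% c("dementia", "control"))) {
      stop("classifier needs dementia/control labels only")
    }
    y <- as.integer(g == "dementia")
    featNames <- alphabetLabels()
  } else {
    X <- as.matrix(x)
    if (is.null(labels)) stop("labels required when x is a plain matrix")
    y <- .asBinary(labels)
    featNames <- colnames(X)
    if (is.null(featNames)) featNames <- paste0("f", seq_len(ncol(X)))
  }
  if (length(unique(y)) < 2L) stop("both classes must be present")
  nFolds <- as.integer(nFolds)
  if (min(table(y)) < nFolds) {
    stop("nFolds (", nFolds, ") exceeds the smaller class size (",
         min(table(y)), ")")
  }
  lambdaGrid <- sort(unique(lambdaGrid), decreasing = TRUE)
  if (any(lambdaGrid <= 0)) stop("lambdaGrid must be strictly positive")
  colnames(X) <- featNames

  set.seed(seed)
  fold <- .stratifiedFolds(y, nFolds)
  aucPerFold <- numeric(nFolds)
  oof <- numeric(length(y))
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    inner <- .innerCvAuc(X[tr, , drop = FALSE], y[tr], lambdaGrid, innerFolds)
    lam <- lambdaGrid[which.max(inner)]  # ties resolve to the sparser model
    z <- .zscoreFit(X[tr, , drop = FALSE])
    fit <- glmnet::glmnet(.zscoreApply(X[tr, , drop = FALSE], z), y[tr],
                          family = "binomial", alpha = 1,
                          lambda = lambdaGrid, standardize = FALSE)
    pred <- stats::predict(fit, .zscoreApply(X[!tr, , drop = FALSE], z),
                           s = lam, type = "response")
    oof[!tr] <- drop(pred)
    aucPerFold[f] <- rocCurvePoints(drop(pred), y[!tr])$auc
  }

  # final reporting fit on all data, penalty chosen by the same inner scheme
  inner <- .innerCvAuc(X, y, lambdaGrid, innerFolds)
  lamFinal <- lambdaGrid[which.max(inner)]
  z <- .zscoreFit(X)
  fit <- glmnet::glmnet(.zscoreApply(X, z), y, family = "binomial", alpha = 1,
                        lambda = lambdaGrid, standardize = FALSE)
  betaStd <- drop(as.matrix(stats::coef(fit, s = lamFinal)))[-1L]
  betaOrig <- betaStd / z$sd
  nz <- which(betaStd != 0)
  list(cvAucMean = mean(aucPerFold),
       cvAucPerFold = aucPerFold,
       selectedFeatures = data.frame(character = featNames[nz],
                                     coefficient = unname(betaOrig[nz]),
                                     stringsAsFactors = FALSE),
       regularizationChosen = lamFinal,
       nFolds = nFolds,
       seed = seed,
       lambdaGrid = lambdaGrid,
       oofScores = oof,
       labels = y)
}

# Number of nonzero coefficients along the penalty path on fixed data;
# exposed for the sparsity-monotonicity property.
.lassoSelectionPath <- function(X, y, lambdaGrid) {
  lambdaGrid <- sort(unique(lambdaGrid), decreasing = TRUE)
  z <- .zscoreFit(X)
  fit <- glmnet::glmnet(.zscoreApply(X, z), .asBinary(y), family = "binomial",
                        alpha = 1, lambda = lambdaGrid, standardize = FALSE)
  b <- as.matrix(fit$beta)
  stats::setNames(colSums(b != 0), lambdaGrid)
}
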