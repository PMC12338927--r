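# Independent oracles and small fixture builders shared across the suite.
# Oracles deliberately use a different route than the implementation:
# stationary distributions via a dense eigendecomposition, KS via a brute
# force double loop over pooled points, AUC via pairwise concordance.

# left eigenvector of P for eigenvalue 1 (stationary distribution oracle)
eigenStationary <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# sup over pooled sample points of |F1 - F2|, by explicit double loop
bruteForceKS <- function(x, y) {
  pooled <- c(x, y)
  d <- 0
  for (p in pooled) {
    d <- max(d, abs(mean(x <= p) - mean(y <= p)))
  }
  d
}

# Mann-Whitney concordance AUC with half credit for ties
concordanceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# random strictly positive row-stochastic matrix
randomStochastic <- function(k) {
  m <- matrix(stats::runif(k * k, min = 0.05, max = 1), k)
  m / rowSums(m)
}

# n points per cloud around k well-separated centers in d dimensions
makeClouds <- function(k, nPer, d = 5, sep = 20, sd = 1) {
  centers <- matrix(0, k, d)
  for (i in seq_len(k)) centers[i, 1:2] <- sep * c(cos(2 * pi * i / k),
                                                   sin(2 * pi * i / k))
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(stats::rnorm(nPer * d, sd = sd), nPer, d) +
      matrix(centers[i, ], nPer, d, byrow = TRUE)
  }))
  list(X = X, labels = rep(seq_len(k), each = nPer))
}

# tiny in-memory manifest of hand-written transcripts
tinyManifest <- function() {
  data.frame(
    transcript_id = c("d1", "d2", "c1", "c2"),
    group = c("dementia", "dementia", "control", "control"),
    text = c("the boy took the cookie from the jar",
             "the the the boy um the cookie",
             "a girl is asking her brother for a cookie",
             "mother is washing dishes while the sink overflows"),
    stringsAsFactors = FALSE
  )
}

# small two-group synthetic corpus at the calibrated default conditions
shiftCorpus <- function(nPer = 100, len = c(500, 500), seed = 11) {
  generateCorpus(list(
    groupSpec("dementia", nPer, targetSpaceMass = 0.19, lengthRange = len),
    groupSpec("control", nPer, targetSpaceMass = 0.17, lengthRange = len)
  ), seed = seed, returnGroundTruth = FALSE)
}
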