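test_that("silhouette selection recovers the true number of separated clouds", {
  set.seed(31)
  two <- makeClouds(2, 40)
  res2 <- clusterFingerprints(two$X, kRange = 2:6, seed = 31)
  expect_identical(res2$kSelected, 2L)
  expect_identical(unname(which.max(res2$silhouetteByK)), 1L)
  # assignments align with the generating clouds up to label swap
  tab <- table(res2$assignments, two$labels)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
  set.seed(32)
  three <- makeClouds(3, 30)
  res3 <- clusterFingerprints(three$X, kRange = 2:6, seed = 32)
  expect_identical(res3$kSelected, 3L)
})

test_that("clustering is deterministic under a fixed seed and rejects degenerate input", {
  set.seed(33)
  X <- makeClouds(2, 20)$X
  a <- clusterFingerprints(X, kRange = 2:4, seed = 9)
  b <- clusterFingerprints(X, kRange = 2:4, seed = 9)
  expect_identical(a$kSelected, b$kSelected)
  expect_identical(a$assignments, b$assignments)
  expect_equal(a$silhouetteByK, b$silhouetteByK)
  expect_error(clusterFingerprints(matrix(0.5, 20, 3)), "degenerate")
  expect_error(clusterFingerprints(X[1:4, ], kRange = 2:8), "more points")
})

test_that("label agreement is invariant under swapping cluster ids", {
  corpus <- shiftCorpus(nPer = 20, len = c(2000, 2000), seed = 35)
  fp <- buildFingerprints(corpus$manifest)$fingerprints
  res <- clusterFingerprints(fp, kRange = 2:3, seed = 1)
  # agreement computed from the contingency table is permutation-invariant:
  # recompute after relabeling clusters
  tab <- table(res$assignments, groupLabels(fp))
  swapped <- table(3L - res$assignments, groupLabels(fp))
  expect_equal(sum(apply(tab, 1, max)), sum(apply(swapped, 1, max)))
  expect_true(res$agreement >= 0 && res$agreement <= 1)
})

test_that("PCA projection centers, orders variance, and fixes component signs", {
  # variance along a single coordinate
  set.seed(36)
  X <- cbind(rnorm(30), 0, 0)
  p <- pcaProject(X)
  expect_equal(p$explainedVarianceRatio[1], 1, tolerance = 1e-10)
  expect_equal(p$explainedVarianceRatio[2], 0, tolerance = 1e-10)
  # 2-D data: the projection is a rotation, distances preserved
  Y <- cbind(rnorm(25), rnorm(25))
  py <- pcaProject(Y)
  expect_equal(as.matrix(dist(py$coords)), as.matrix(dist(Y)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading of each component positive
  expect_true(all(apply(py$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_error(pcaProject(Y[1:2, ]), "at least 3")
})

test_that("projection is invariant to row reordering up to the fixed convention", {
  set.seed(37)
  X <- makeClouds(2, 15, d = 6)$X
  ord <- sample(nrow(X))
  p1 <- pcaProject(X)
  p2 <- pcaProject(X[ord, ])
  expect_equal(p2$coords, p1$coords[ord, ], tolerance = 1e-8)
  expect_equal(p2$loadings, p1$loadings, tolerance = 1e-8)
})

test_that("two-group corpus with a calibrated shift separates in the projection", {
  corpus <- shiftCorpus(nPer = 25, len = c(3000, 3000), seed = 38)
  fp <- buildFingerprints(corpus$manifest)$fingerprints
  p <- pcaProject(fp)
  g <- groupLabels(fp)
  cd <- colMeans(p$coords[g == "dementia", , drop = FALSE])
  cc <- colMeans(p$coords[g == "control", , drop = FALSE])
  sep <- sqrt(sum((cd - cc)^2))
  radius <- mean(c(
    sqrt(rowSums((p$coords[g == "dementia", ] -
                    matrix(cd, sum(g == "dementia"), 2, byrow = TRUE))^2)),
    sqrt(rowSums((p$coords[g == "control", ] -
                    matrix(cc, sum(g == "control"), 2, byrow = TRUE))^2))
  ))
  expect_gt(sep, radius)
})
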