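test_that("transition counting enumerates adjacent pairs with no wrap-around", {
  cts <- countTransitions(c(1L, 2L, 1L, 2L))
  expect_identical(cts[1, 2], 2L)
  expect_identical(cts[2, 1], 1L)
  expect_identical(sum(cts), 3L)  # L - 1 events
  cts2 <- countTransitions(c(6L, 6L))
  expect_identical(cts2[6, 6], 1L)
  expect_identical(sum(cts2), 1L)
  expect_error(countTransitions(7L), "too short")
  # exhaustive-enumeration oracle on random sequences
  set.seed(7)
  for (i in 1:10) {
    s <- sample.int(27, 100, replace = TRUE)
    cts <- countTransitions(s)
    for (pair in list(c(1, 1), c(3, 27), c(27, 3))) {
      expect_identical(cts[pair[1], pair[2]],
                       sum(s[-100] == pair[1] & s[-1] == pair[2]))
    }
    expect_identical(sum(cts), 99L)
  }
})

test_that("Laplace smoothing matches the additive formula exactly", {
  cts <- matrix(0L, 27, 27)
  cts[1, 2] <- 2L
  P <- smoothTransitions(cts, alpha = 0.01)
  expect_equal(P[1, 2], 2.01 / 2.27, tolerance = 1e-15)
  expect_equal(P[1, 3], 0.01 / 2.27, tolerance = 1e-15)
  # all-zero row smooths to uniform
  expect_equal(unname(P[5, ]), rep(1 / 27, 27), tolerance = 1e-15)
  expect_equal(unname(rowSums(P)), rep(1, 27), tolerance = 1e-12)
  # unsmoothed ML: a single observed transition gets probability exactly 1
  ctsFull <- matrix(1L, 27, 27)
  ctsFull[1, ] <- 0L; ctsFull[1, 2] <- 1L
  expect_identical(smoothTransitions(ctsFull, alpha = 0)[1, 2], 1)
  # errors
  expect_error(smoothTransitions(cts, alpha = -1), "alpha")
  expect_error(smoothTransitions(cts, alpha = 0), "all-zero row")
})

test_that("rows sum to 1 after smoothing on many random transcripts", {
  set.seed(8)
  for (i in 1:200) {
    s <- sample.int(27, sample(2:200, 1), replace = TRUE)
    P <- smoothTransitions(countTransitions(s), 0.01)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    expect_true(all(P > 0))
  }
})

test_that("stationary solver recovers closed forms and satisfies its contract", {
  # uniform chain: pi uniform
  U <- matrix(1 / 27, 27, 27)
  expect_equal(stationaryDistribution(U)$pi, rep(1 / 27, 27), tolerance = 1e-12)
  # 2-state closed form pi1 = P21 / (P12 + P21)
  P2 <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  sol <- stationaryDistribution(P2)
  expect_equal(sol$pi, c(5 / 6, 1 / 6), tolerance = 1e-12)
  expect_lte(sol$residual, 1e-10)
  expect_equal(sum(sol$pi), 1, tolerance = 1e-12)
  # invalid input
  expect_error(stationaryDistribution(matrix(c(0.9, 0.2, 0.5, 0.5), 2, byrow = TRUE)),
               "rows must sum to 1")
})

test_that("power-iteration solver agrees with an eigendecomposition oracle", {
  set.seed(9)
  for (i in 1:100) {
    k <- sample(c(2:5, 27), 1)
    P <- randomStochastic(k)
    sol <- stationaryDistribution(P)
    expect_lt(max(abs(sol$pi - eigenStationary(P))), 1e-10)
    expect_lte(sol$residual, 1e-10)
  }
})

test_that("relabeling alphabet symbols permutes the stationary vector identically", {
  set.seed(10)
  s <- sample.int(27, 500, replace = TRUE)
  perm <- sample.int(27)
  pi1 <- stationaryDistribution(smoothTransitions(countTransitions(s), 0.01))$pi
  pi2 <- stationaryDistribution(smoothTransitions(countTransitions(perm[s]), 0.01))$pi
  expect_equal(unname(pi2[perm]), unname(pi1), tolerance = 1e-12)
})

test_that("estimated stationary vector converges to the generating chain's", {
  ch <- defaultBaseChain()
  piTrue <- stationaryDistribution(ch)$pi
  set.seed(1)
  l1 <- sapply(c(1e3, 1e4, 1e5), function(L) {
    s <- sampleTranscript(ch, L, pi = piTrue)
    P <- smoothTransitions(countTransitions(s), 0.01)
    sum(abs(stationaryDistribution(P)$pi - piTrue))
  })
  expect_true(all(diff(l1) < 0))  # error shrinks with length
  expect_lt(l1[3], 0.02)          # within L1 0.02 at length 1e5
})
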