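test_that("space-mass calibration hits its target and is monotone in the boost", {
  ch <- defaultBaseChain()
  # identity calibration: target equal to the current mass
  cur <- stationaryDistribution(ch)$pi[27]
  ident <- calibrateSpaceMass(ch, cur)
  expect_equal(ident$delta, 1)
  expect_equal(ident$chain, ch, tolerance = 1e-12)
  # calibrated chains hit the target within 1e-6, checked by the eigen oracle
  for (target in c(0.17, 0.19, 0.3)) {
    cal <- calibrateSpaceMass(ch, target)
    expect_lt(abs(eigenStationary(cal$chain)[27] - target), 1e-6)
    expect_lt(max(abs(rowSums(cal$chain) - 1)), 1e-12)
  }
  # boost monotone in the target
  expect_lt(calibrateSpaceMass(ch, 0.17)$delta,
            calibrateSpaceMass(ch, 0.19)$delta)
})

test_that("transcript sampling is seed-deterministic and obeys the chain's long-run law", {
  ch <- defaultBaseChain()
  piT <- stationaryDistribution(ch)$pi
  set.seed(61); s1 <- sampleTranscript(ch, 500)
  set.seed(61); s2 <- sampleTranscript(ch, 500)
  expect_identical(s1, s2)
  expect_length(s1, 500)
  expect_true(all(s1 %in% 1:27))
  # law of large numbers: empirical frequencies approach the stationary law
  set.seed(62)
  long <- sampleTranscript(ch, 1e5, pi = piT)
  expect_lt(sum(abs(tabulate(long, 27) / 1e5 - piT)), 0.02)
  # near-deterministic chain: symbol 'a' self-transition 0.999, every other
  # symbol falls back to 'a'; started from the (a-dominated) stationary law
  sticky <- matrix(0.01 / 26, 27, 27)
  sticky[, 1] <- 0.99
  sticky[1, ] <- 0.001 / 26
  sticky[1, 1] <- 0.999
  sticky <- sticky / rowSums(sticky)
  set.seed(63)
  s <- sampleTranscript(sticky, 1e4)
  expect_gte(mean(s == 1L), 0.99)
})

test_that("generated corpora are reproducible and emit only vocabulary symbols", {
  spec <- list(groupSpec("dementia", 5, targetSpaceMass = 0.19,
                         lengthRange = c(100, 200)),
               groupSpec("control", 5, targetSpaceMass = 0.17,
                         lengthRange = c(100, 200)))
  a <- generateCorpus(spec, seed = 64)
  b <- generateCorpus(spec, seed = 64)
  expect_identical(a$manifest, b$manifest)
  expect_identical(nrow(a$manifest), 10L)
  # exact identity under normalization without collapsing: only vocabulary
  # symbols are emitted
  expect_identical(normalizeText(a$manifest$text, collapseSpaces = FALSE),
                   a$manifest$text)
  # ground truth records true chains and stationary vectors per transcript
  gt <- a$groundTruth$transcripts[[a$manifest$transcript_id[1]]]
  expect_equal(sum(gt$pi), 1, tolerance = 1e-10)
  expect_lt(max(abs(rowSums(gt$chain) - 1)), 1e-10)
})

test_that("smaller corpora are prefixes of larger ones at the same seed", {
  small <- generateCorpus(list(groupSpec("dementia", 3, lengthRange = c(50, 80)),
                               groupSpec("control", 3, lengthRange = c(50, 80))),
                          seed = 65)
  large <- generateCorpus(list(groupSpec("dementia", 6, lengthRange = c(50, 80)),
                               groupSpec("control", 6, lengthRange = c(50, 80))),
                          seed = 65)
  for (g in c("dementia", "control")) {
    sm <- small$manifest$text[small$manifest$group == g]
    lg <- large$manifest$text[large$manifest$group == g]
    expect_identical(sm, lg[seq_along(sm)])
  }
})

test_that("per-transcript fingerprints recover the perturbed generating chains", {
  corpus <- generateCorpus(list(
    groupSpec("dementia", 4, targetSpaceMass = 0.19,
              lengthRange = c(1e5, 1e5))), seed = 66)
  built <- buildFingerprints(corpus$manifest, collapseSpaces = FALSE)
  X <- fingerprintMatrix(built$fingerprints)
  for (i in seq_len(nrow(X))) {
    truth <- corpus$groundTruth$transcripts[[corpus$manifest$transcript_id[i]]]
    expect_lt(sum(abs(X[i, ] - truth$pi)), 0.02)
  }
})

test_that("end-to-end group means of the space mass track the calibration targets", {
  corpus <- shiftCorpus(nPer = 20, len = c(2000, 2500), seed = 67)
  fp <- buildFingerprints(corpus$manifest)$fingerprints
  X <- fingerprintMatrix(fp)
  g <- groupLabels(fp)
  expect_lt(abs(mean(X[g == "dementia", "space"]) - 0.19), 0.005)
  expect_lt(abs(mean(X[g == "control", "space"]) - 0.17), 0.005)
})

test_that("screen power increases with group size under common random numbers", {
  powers <- sapply(c(15, 30, 60), function(n) {
    pa <- powerAnalysis(
      groupSpec("dementia", n, targetSpaceMass = 0.19, lengthRange = c(500, 500)),
      groupSpec("control", n, targetSpaceMass = 0.17, lengthRange = c(500, 500)),
      nReplicates = 30, seed = 68)
    pa$flagRate[["space"]]
  })
  expect_true(all(diff(powers) >= 0))
  expect_gt(powers[3], powers[1])
})
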