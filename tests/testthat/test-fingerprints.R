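test_that("single-transcript fingerprint reflects the symmetry of its counts", {
  # a <-> b relabeling symmetry of "ababa"
  pi <- transcriptSteadyState("ababa")
  expect_equal(unname(pi["a"]), unname(pi["b"]), tolerance = 1e-12)
  expect_true(all(pi["a"] > pi[setdiff(alphabetLabels(), c("a", "b"))]))
  # "aa": a dominates every other symbol
  pi2 <- transcriptSteadyState("aa")
  expect_identical(names(which.max(pi2)), "a")
  expect_equal(sum(pi2), 1, tolerance = 1e-12)
  expect_true(all(pi2 >= 0))
})

test_that("TransitionModel objects are valid and self-consistent", {
  m <- transcriptModel("the boy took the cookie", "t1", "control")
  expect_s4_class(m, "TransitionModel")
  expect_true(validObject(m))
  expect_equal(sum(transitionCounts(m)),
               nchar(normalizeText("the boy took the cookie")) - 1L)
  expect_lte(m@residual, 1e-10)
  # steady state equals the stationary vector of the stored smoothed matrix
  expect_equal(unname(steadyState(m)),
               unname(stationaryDistribution(transitionProbs(m))$pi),
               tolerance = 1e-10)
})

test_that("feature matrix stacks one unit-sum row per transcript in manifest order", {
  res <- buildFingerprints(tinyManifest())
  fp <- res$fingerprints
  expect_s4_class(fp, "CharFingerprints")
  X <- fingerprintMatrix(fp)
  expect_identical(dim(X), c(4L, 27L))
  expect_identical(colnames(X), alphabetLabels())
  expect_lt(max(abs(rowSums(X) - 1)), 1e-10)
  expect_identical(transcriptIds(fp), tinyManifest()$transcript_id)
  expect_identical(groupLabels(fp), tinyManifest()$group)
  expect_identical(res$report$n_processed, 4L)
  expect_identical(res$report$n_skipped, 0L)
})

test_that("skip policy accounts for every manifest row; abort is the default", {
  man <- tinyManifest()
  man$text[2] <- "!!!"   # normalizes to empty
  expect_error(buildFingerprints(man), "d2")
  res <- buildFingerprints(man, skipPolicy = "skip")
  expect_identical(res$report$n_skipped, 1L)
  expect_identical(res$report$skip_reasons$reason, "too-short")
  expect_identical(res$report$n_processed + res$report$n_skipped, nrow(man))
  # remaining rows keep manifest order
  expect_identical(transcriptIds(res$fingerprints), c("d1", "c1", "c2"))
})

test_that("manifests read from disk resolve paths and reject duplicates", {
  dir <- withr::local_tempdir()
  writeLines("the boy took a cookie", file.path(dir, "t1.txt"))
  writeLines("the girl asked for milk", file.path(dir, "t2.txt"))
  man <- data.frame(transcript_id = c("t1", "t2"),
                    path = c("t1.txt", "t2.txt"),
                    group = c("dementia", "control"))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  m <- readManifest(file.path(dir, "manifest.csv"))
  expect_true(all(file.exists(m$path)))
  res <- buildFingerprints(m)
  expect_identical(nrow(fingerprintMatrix(res$fingerprints)), 2L)
  man$transcript_id <- c("t1", "t1")
  write.csv(man, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(readManifest(file.path(dir, "dup.csv")), "duplicate")
})

test_that("CharFingerprints validity rejects malformed containers", {
  v <- matrix(1 / 27, 2, 27)
  expect_error(CharFingerprints(v, c("t1", "t1"), c("dementia", "control")),
               "unique")
  vbad <- v; vbad[1, 1] <- 0.5
  expect_error(CharFingerprints(vbad, c("t1", "t2"), c("dementia", "control")),
               "sum to 1")
  expect_error(CharFingerprints(v, c("t1", "t2"), c("dementia", "cases")),
               "group")
})
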