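test_that("raw-count networks retain exactly the observed transitions", {
  g <- buildTransitionNetwork(countTransitions(encodeTranscript("aaaa")))
  expect_equal(igraph::vcount(g), 1)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 3)  # L - 1 self-loop events
  g2 <- buildTransitionNetwork(countTransitions(encodeTranscript("abc")))
  el <- igraph::as_data_frame(g2)
  expect_setequal(paste(el$from, el$to), c("a b", "b c"))
  expect_equal(el$weight, c(1, 1))
  expect_false(any(el$from == el$to))
  expect_error(buildTransitionNetwork(countTransitions(1:3), edgeThreshold = -1),
               ">= 0")
})

test_that("smoothed-probability networks drop sub-threshold smoothing edges", {
  # "abab": P_ab = 2.01/2.27 ~ 0.885 and P_ba = 1.01/1.27 ~ 0.795; both
  # exceed 0.5, every other smoothed entry is far below it
  m <- transcriptModel("abab")
  g <- buildTransitionNetwork(m, weightKind = "smoothed_prob",
                              edgeThreshold = 0.5)
  el <- igraph::as_data_frame(g)
  el <- el[order(el$from), ]
  expect_identical(paste(el$from, el$to), c("a b", "b a"))
  expect_equal(el$weight, c(2.01 / 2.27, 1.01 / 1.27), tolerance = 1e-12)
  g9 <- buildTransitionNetwork(m, weightKind = "smoothed_prob",
                               edgeThreshold = 0.8)
  el9 <- igraph::as_data_frame(g9)
  expect_identical(paste(el9$from, el9$to), "a b")
  # default 0.01 threshold keeps observed edges, suppresses pure smoothing
  gd <- buildTransitionNetwork(m, weightKind = "smoothed_prob")
  eld <- igraph::as_data_frame(gd)
  expect_true(all(c("a b", "b a") %in% paste(eld$from, eld$to)))
  expect_true(all(eld$weight > 0.01))
})

test_that("network summaries capture self-loop mass and outgoing entropy", {
  s <- summarizeTransitions(countTransitions(encodeTranscript("aaaa")))
  expect_equal(s$self_loop_mass, 1)
  expect_equal(s$mean_out_entropy, 0)
  expect_identical(s$n_nodes, 1L)
  # a uniform conditional row has entropy log2(27)
  cts <- matrix(0L, 27, 27)
  cts[1, ] <- 1L
  expect_equal(summarizeTransitions(cts)$mean_out_entropy, log2(27),
               tolerance = 1e-12)
  # bounds and exact off-diagonal complement
  set.seed(51)
  for (i in 1:20) {
    cc <- countTransitions(sample.int(27, 300, replace = TRUE))
    ss <- summarizeTransitions(cc)
    off <- (sum(cc) - sum(diag(cc))) / sum(cc)
    expect_equal(ss$self_loop_mass + off, 1, tolerance = 1e-14)
    expect_gte(ss$mean_out_entropy, 0)
    expect_lte(ss$mean_out_entropy, log2(27))
    expect_lte(ss$n_edges, sum(cc > 0))
  }
  expect_error(summarizeTransitions(matrix(0L, 27, 27)), "zero transition")
})

test_that("rigid corpora show higher self-loop mass and lower entropy than flexible ones", {
  # rigid: strong self-transitions; flexible: near-uniform chain
  rigid <- 0.05 * matrix(1 / 27, 27, 27) + 0.95 * diag(27)
  rigid <- rigid / rowSums(rigid)
  flexible <- matrix(stats::runif(729, 0.8, 1.2), 27)
  flexible <- flexible / rowSums(flexible)
  set.seed(52)
  stat <- function(chain) {
    reps <- replicate(10, {
      s <- sampleTranscript(chain, 400)
      u <- summarizeTransitions(countTransitions(s))
      c(u$self_loop_mass, u$mean_out_entropy)
    })
    rowMeans(reps)
  }
  r <- stat(rigid); f <- stat(flexible)
  expect_gt(r[1], f[1])  # more self-loops when rigid
  expect_lt(r[2], f[2])  # less transition diversity when rigid
})

test_that("GraphML export round-trips node symbols and edge weights", {
  dir <- withr::local_tempdir()
  g <- buildTransitionNetwork(countTransitions(encodeTranscript("the boy")))
  path <- file.path(dir, "net.graphml")
  exportGraphML(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_identical(sort(igraph::V(back)$symbol), sort(igraph::V(g)$symbol))
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(g)$weight))
})

test_that("summary table carries one row per transcript with its labels", {
  res <- buildFingerprints(tinyManifest())
  tab <- networkSummaryTable(res$models)
  expect_identical(tab$transcript_id, tinyManifest()$transcript_id)
  expect_identical(tab$group, tinyManifest()$group)
  expect_true(all(tab$self_loop_mass >= 0 & tab$self_loop_mass <= 1))
  expect_true(all(tab$edge_density > 0 & tab$edge_density <= 1))
})
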