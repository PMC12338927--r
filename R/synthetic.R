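#' Default ground-truth base chain for simulation
#'
#' A fixed, strictly positive 27x27 row-stochastic matrix used as the
#' ground-truth chain of the synthetic corpus generator.  Rows are Dirichlet
#' draws (from a fixed internal seed, so the chain is a constant of the
#' package) with a mild self-transition boost and an inflated space column,
#' giving a baseline stationary space mass in a realistic range for
#' transcribed speech while remaining deliberately language-agnostic: no
#' English letter-frequency structure is assumed.
#'
#' @return A 27x27 row-stochastic matrix with dimnames [alphabetLabels()].
#' @export
defaultBaseChain <- function() {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(20250701L)
  G <- matrix(stats::rgamma(.K * .K, shape = 0.8), nrow = .K)
  diag(G) <- diag(G) + 1.5          # mild self-transition boost
  G[, .SPACE_INDEX] <- G[, .SPACE_INDEX] + 4  # speech-like pause mass
  # space acts as a word separator: space-after-space is structurally rare
  # (kept strictly positive so the chain stays Perron-Frobenius regular)
  G[.SPACE_INDEX, .SPACE_INDEX] <- 0.01
  P <- G / rowSums(G)
  dimnames(P) <- list(alphabetLabels(), alphabetLabels())
  P
}

#' Specification of one synthetic group
#'
#' Bundles the parameters of one simulated cohort: the ground-truth chain,
#' the desired stationary probability of the space character (the
#' controllable group effect), the between-transcript variability, the
#' transcript length range and the group size.
#'
#' @param name Group label (\code{"dementia"}, \code{"control"} or
#'   \code{"unlabeled"}).
#' @param nTranscripts Number of transcripts to generate, >= 1.
#' @param targetSpaceMass Desired stationary space probability in (0, 1);
#'   \code{NULL} leaves the base chain uncalibrated.
#' @param baseChain Strictly positive row-stochastic 27x27 matrix (default
#'   [defaultBaseChain()]).
#' @param subjectVariability Dirichlet concentration tau > 0 for the
#'   per-transcript row perturbation; larger tau = less between-transcript
#'   variability.  Default 2000 keeps chain wobble small relative to the
#'   within-transcript sampling noise of Cookie-Theft-scale transcripts.
#' @param lengthRange Integer (min, max) transcript lengths, min >= 2;
#'   default \code{c(300, 800)}, bracketing a picture-description scale.
#' @return A validated list of class \code{"GroupSpec"}.
#' @export
groupSpec <- function(name, nTranscripts, targetSpaceMass = NULL,
                      baseChain = defaultBaseChain(),
                      subjectVariability = 2000,
                      lengthRange = c(300L, 800L)) {
  stopifnot(is.character(name), length(name) == 1L,
            name %in% .GROUP_LEVELS)
  nTranscripts <- as.integer(nTranscripts)
  stopifnot(nTranscripts >= 1L)
  baseChain <- as.matrix(baseChain)
  if (!all(dim(baseChain) == .K) || any(baseChain <= 0) ||
      any(abs(rowSums(baseChain) - 1) > 1e-8)) {
    stop("baseChain must be a strictly positive row-stochastic 27x27 matrix")
  }
  if (!is.null(targetSpaceMass)) {
    stopifnot(is.numeric(targetSpaceMass), length(targetSpaceMass) == 1L,
              targetSpaceMass > 0, targetSpaceMass < 1)
  }
  stopifnot(subjectVariability > 0)
  lengthRange <- as.integer(lengthRange)
  stopifnot(length(lengthRange) == 2L, lengthRange[1L] >= 2L,
            lengthRange[2L] >= lengthRange[1L])
  structure(list(name = name, nTranscripts = nTranscripts,
                 targetSpaceMass = targetSpaceMass, baseChain = baseChain,
                 subjectVariability = subjectVariability,
                 lengthRange = lengthRange),
            class = "GroupSpec")
}

.spaceMass <- function(chain) {
  stationaryDistribution(chain)$pi[.SPACE_INDEX]
}

.boostSpace <- function(chain, delta) {
  chain[, .SPACE_INDEX] <- chain[, .SPACE_INDEX] * delta
  chain / rowSums(chain)
}

#' Calibrate a chain's stationary space probability
#'
#' Applies a multiplicative boost delta to every row's transition
#' probability into the space state (renormalizing rows) and bisects on
#' delta until the stationary probability of the space symbol matches the
#' target within 1e-6.  The stationary space mass is monotone increasing in
#' delta, so bisection over an expanding bracket converges; failure to
#' reach the tolerance within the iteration cap is an error reporting the
#' best achieved mass.
#'
#' @param chain Strictly positive row-stochastic 27x27 matrix.
#' @param targetSpaceMass Target stationary space probability in (0, 1).
#' @param tol Calibration tolerance (default 1e-6).
#' @param maxIter Bisection cap (default 200).
#' @return A list: \code{chain} (calibrated matrix), \code{delta} (the
#'   boost applied; 1 when the chain already met the target),
#'   \code{spaceMass} (achieved stationary space probability).
#' @export
calibrateSpaceMass <- function(chain, targetSpaceMass, tol = 1e-6,
                               maxIter = 200L) {
  chain <- as.matrix(chain)
  if (!all(dim(chain) == .K) || any(chain <= 0) ||
      any(abs(rowSums(chain) - 1) > 1e-8)) {
    stop("chain must be a strictly positive row-stochastic 27x27 matrix")
  }
  stopifnot(targetSpaceMass > 0, targetSpaceMass < 1)
  current <- .spaceMass(chain)
  if (abs(current - targetSpaceMass) <= 1e-12) {
    return(list(chain = chain, delta = 1, spaceMass = current))
  }
  lo <- hi <- 1
  for (i in seq_len(60L)) {
    if (.spaceMass(.boostSpace(chain, lo)) <= targetSpaceMass) break
    lo <- lo / 2
  }
  for (i in seq_len(60L)) {
    if (.spaceMass(.boostSpace(chain, hi)) >= targetSpaceMass) break
    hi <- hi * 2
  }
  delta <- 1
  mass <- current
  for (i in seq_len(maxIter)) {
    delta <- sqrt(lo * hi)  # bisect in log space
    mass <- .spaceMass(.boostSpace(chain, delta))
    if (abs(mass - targetSpaceMass) <= tol) {
      return(list(chain = .boostSpace(chain, delta), delta = delta,
                  spaceMass = mass))
    }
    if (mass < targetSpaceMass) lo <- delta else hi <- delta
  }
  stop("space-mass calibration did not converge: best achieved mass ",
       format(mass, digits = 8), " for target ", targetSpaceMass)
}

#' Sample one transcript from a Markov chain
#'
#' Draws the initial symbol from the chain's stationary distribution and
#' each subsequent symbol from the current row, using uniforms taken from
#' R's RNG (so \code{set.seed} makes the draw reproducible).
#'
#' @param chain Row-stochastic 27x27 matrix.
#' @param length Sequence length, >= 2.
#' @param pi Optional precomputed stationary distribution of \code{chain}
#'   (saves a solve in tight loops).
#' @return Integer index sequence of exactly \code{length} symbols in
#'   \code{1:27}.
#' @export
sampleTranscript <- function(chain, length, pi = NULL) {
  chain <- as.matrix(chain)
  length <- as.integer(length)
  if (is.na(length) || length < 2L) stop("length must be >= 2")
  if (!all(dim(chain) == .K) || any(chain < 0) ||
      any(abs(rowSums(chain) - 1) > 1e-8)) {
    stop("chain must be a row-stochastic 27x27 matrix")
  }
  if (is.null(pi)) pi <- stationaryDistribution(chain)$pi
  u <- stats::runif(length)
  init <- min(findInterval(u[1L], cumsum(pi)) + 1L, .K)
  cum <- t(apply(chain, 1L, cumsum))
  cum[, .K] <- 1  # guard against rounding drift at the right edge
  .sample_chain_cpp(cum, init, length, u)
}

# Deterministic per-transcript seed derived only from (corpus seed, group
# index, transcript index) -- never from group sizes -- so a smaller corpus
# at the same seed is a strict prefix of a larger one (common random
# numbers across sample-size comparisons).
.transcriptSeed <- function(seed, g, t) {
  as.integer((abs(seed) + g * 1299721 + t * 7919) %% 2147483647)
}

# Dirichlet(tau * row) perturbation of every row of a chain.
.perturbChain <- function(chain, tau) {
  w <- matrix(stats::rgamma(.K * .K, shape = as.vector(t(chain)) * tau),
              nrow = .K, byrow = TRUE)
  w[!is.finite(w) | w <= 0] <- .Machine$double.xmin
  w / rowSums(w)
}

#' Generate a two-group synthetic transcript corpus
#'
#' For each group: the base chain is calibrated to its target stationary
#' space probability (see [calibrateSpaceMass()]); then for each transcript
#' the rows of the calibrated chain are perturbed by a Dirichlet draw with
#' concentration tau * row (between-transcript variability), a length is
#' drawn uniformly from the group's length range, and a character sequence
#' is sampled from the perturbed chain and decoded to text.  All randomness
#' flows from \code{seed} through a per-transcript splitting scheme keyed
#' by (group index, transcript index), so any subset of the corpus is
#' reproducible independently of the rest.
#'
#' @param groups List of [groupSpec()] objects with distinct names.
#' @param seed Integer master seed.
#' @param returnGroundTruth Keep the per-transcript true chains and
#'   stationary vectors (default `TRUE`; disable in tight Monte-Carlo
#'   loops to save memory).
#' @return A list: \code{manifest} (data.frame \code{transcript_id},
#'   \code{group}, \code{text}, in generation order) and
#'   \code{groundTruth} (per group: calibrated chain, boost delta,
#'   achieved space mass, tau; per transcript: true perturbed chain and its
#'   stationary vector), plus \code{seed}.
#' @examples
#' cs <- generateCorpus(list(
#'   groupSpec("dementia", 3, targetSpaceMass = 0.19, lengthRange = c(50, 60)),
#'   groupSpec("control", 3, targetSpaceMass = 0.17, lengthRange = c(50, 60))
#' ), seed = 1)
#' cs$manifest$transcript_id
#' @export
generateCorpus <- function(groups, seed, returnGroundTruth = TRUE) {
  if (inherits(groups, "GroupSpec")) groups <- list(groups)
  stopifnot(length(groups) >= 1L,
            all(vapply(groups, inherits, logical(1), "GroupSpec")))
  nm <- vapply(groups, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("group names must be distinct")
  seed <- as.integer(seed)
  calibrated <- lapply(groups, function(sp) {
    if (is.null(sp$targetSpaceMass)) {
      list(chain = sp$baseChain, delta = 1, spaceMass = .spaceMass(sp$baseChain))
    } else {
      calibrateSpaceMass(sp$baseChain, sp$targetSpaceMass)
    }
  })
  .generateFromCalibrated(groups, calibrated, seed, returnGroundTruth)
}

.generateFromCalibrated <- function(groups, calibrated, seed,
                                    returnGroundTruth = TRUE,
                                    decodeText = TRUE) {
  rows <- list()
  truth <- list()
  for (g in seq_along(groups)) {
    sp <- groups[[g]]
    cal <- calibrated[[g]]
    calPi <- stationaryDistribution(cal$chain)$pi
    for (t in seq_len(sp$nTranscripts)) {
      set.seed(.transcriptSeed(seed, g, t))
      L <- sp$lengthRange[1L] +
        floor(stats::runif(1) * (sp$lengthRange[2L] - sp$lengthRange[1L] + 1L))
      chain <- .perturbChain(cal$chain, sp$subjectVariability)
      idx <- sampleTranscript(chain, L, pi = calPi)
      id <- sprintf("%s_%04d", sp$name, t)
      rows[[length(rows) + 1L]] <- list(
        transcript_id = id, group = sp$name,
        text = if (decodeText) decodeIndices(idx) else NA_character_,
        indices = idx
      )
      if (returnGroundTruth) {
        truth[[id]] <- list(chain = chain,
                            pi = stationaryDistribution(chain)$pi)
      }
    }
  }
  manifest <- data.frame(
    transcript_id = vapply(rows, `[[`, character(1), "transcript_id"),
    group = vapply(rows, `[[`, character(1), "group"),
    text = vapply(rows, `[[`, character(1), "text"),
    stringsAsFactors = FALSE
  )
  gt <- list(
    groups = stats::setNames(lapply(seq_along(groups), function(g) {
      list(calibrated_chain = calibrated[[g]]$chain,
           delta = calibrated[[g]]$delta,
           space_mass = calibrated[[g]]$spaceMass,
           target_space_mass = groups[[g]]$targetSpaceMass,
           subject_variability = groups[[g]]$subjectVariability)
    }), vapply(groups, `[[`, character(1), "name")),
    transcripts = if (returnGroundTruth) truth else NULL
  )
  list(manifest = manifest, groundTruth = gt, seed = seed)
}

#' Write a synthetic corpus to disk
#'
#' Writes one UTF-8 \code{.txt} file per transcript plus a
#' \code{manifest.csv} (\code{transcript_id,path,group}) and a
#' \code{ground_truth.json} holding the calibrated group chains and
#' targets.
#'
#' @param corpus Result of [generateCorpus()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
writeCorpus <- function(corpus, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, paste0(corpus$manifest$transcript_id, ".txt"))
  for (i in seq_len(nrow(corpus$manifest))) {
    writeLines(corpus$manifest$text[i], paths[i], useBytes = TRUE)
  }
  man <- data.frame(transcript_id = corpus$manifest$transcript_id,
                    path = basename(paths),
                    group = corpus$manifest$group,
                    stringsAsFactors = FALSE)
  manPath <- file.path(outdir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  gt <- corpus$groundTruth$groups
  gt <- lapply(gt, function(g) {
    g$calibrated_chain <- unclass(g$calibrated_chain)
    g
  })
  jsonlite::write_json(list(seed = corpus$seed, groups = gt),
                       file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manPath)
}

#' Monte-Carlo power analysis of the character screen
#'
#' Repeatedly generates a two-group corpus from the given specifications,
#' runs feature extraction and the Bonferroni KS screen, and records which
#' characters are flagged.  With identical group specifications this
#' estimates the family-wise false-positive rate of the screen; with a
#' calibrated space-mass shift it estimates per-character power.
#'
#' @param group1,group2 [groupSpec()] objects (distinct names).
#' @param nReplicates Number of replicates, >= 1.
#' @param seed Integer master seed; replicate r uses corpus seed
#'   \code{seed + r}.
#' @param significanceAlpha Family-wise level of the screen (default 0.05).
#' @param alpha Laplace smoothing constant for estimation (default 0.01).
#' @return A list: \code{flagRate} (named length-27 vector of per-character
#'   flag frequencies), \code{familywiseRate} (fraction of replicates
#'   flagging at least one character), \code{flags} (27 x nReplicates
#'   logical matrix), \code{nReplicates}.
#' @export
powerAnalysis <- function(group1, group2, nReplicates, seed,
                          significanceAlpha = 0.05, alpha = 0.01) {
  stopifnot(inherits(group1, "GroupSpec"), inherits(group2, "GroupSpec"),
            nReplicates >= 1L)
  groups <- list(group1, group2)
  calibrated <- lapply(groups, function(sp) {
    if (is.null(sp$targetSpaceMass)) {
      list(chain = sp$baseChain, delta = 1, spaceMass = .spaceMass(sp$baseChain))
    } else {
      calibrateSpaceMass(sp$baseChain, sp$targetSpaceMass)
    }
  })
  flags <- matrix(FALSE, .K, nReplicates,
                  dimnames = list(alphabetLabels(), NULL))
  for (r in seq_len(nReplicates)) {
    corpus <- .generateFromCalibrated(groups, calibrated, seed + r,
                                      returnGroundTruth = FALSE)
    built <- buildFingerprints(corpus$manifest, alpha = alpha)
    screen <- screenCharacters(built$fingerprints,
                               significanceAlpha = significanceAlpha)
    flags[screen$character, r] <- screen$significant
  }
  list(flagRate = rowMeans(flags),
       familywiseRate = mean(colSums(flags) > 0),
       flags = flags,
       nReplicates = as.integer(nReplicates))
}
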