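.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full fingerprinting and screening pipeline
#'
#' End-to-end orchestration over a manifest of transcripts, in the order
#' preprocessing, Markov modelling, feature assembly, KS screening, rolling
#' space-probability profiles, clustering + PCA, lasso classification and
#' transition-network summaries.  Every artifact is written atomically to
#' \code{outdir} and an output manifest with MD5 checksums is written last;
#' the run report echoes the complete resolved configuration (including
#' defaults and any clamped effective values) so a run can be replayed
#' exactly.
#'
#' Files written: \code{features.csv}, \code{stats.csv}, \code{rolling.csv},
#' \code{clusters.csv}, \code{silhouette.csv}, \code{projection.csv},
#' \code{loadings.csv}, \code{classifier_report.json}, \code{roc.csv},
#' \code{networks_summary.csv}, \code{run_report.json},
#' \code{output_manifest.csv}.
#'
#' Two effective-parameter clamps keep small corpora runnable and are
#' echoed in the run report: the rolling window is capped at the smallest
#' group size, and candidate k values with too few points are dropped.
#'
#' @param manifest Data.frame with columns \code{transcript_id},
#'   \code{group} and \code{text} or \code{path} (see [readManifest()]),
#'   or the path of a manifest CSV.
#' @param config A [validateConfig()] result (or a raw list passed to it).
#' @param outdir Output directory; overrides \code{config$outdir}.
#' @param skipPolicy Passed to [buildFingerprints()].
#' @return Invisibly, a list bundle with every computed artifact
#'   (\code{fingerprints}, \code{models}, \code{screen}, \code{rolling},
#'   \code{clusters}, \code{projection}, \code{classifier},
#'   \code{networks}, \code{report}, \code{files}).
#' @export
runPipeline <- function(manifest, config = validateConfig(), outdir = NULL,
                        skipPolicy = c("abort", "skip")) {
  if (!inherits(config, "PipelineConfig")) config <- validateConfig(config)
  skipPolicy <- match.arg(skipPolicy)
  if (is.character(manifest)) manifest <- readManifest(manifest)
  outdir <- if (is.null(outdir)) config$outdir else outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  t0 <- proc.time()[["elapsed"]]
  built <- .stage("features", buildFingerprints(
    manifest, alpha = config$alpha_smooth,
    collapseSpaces = config$collapse_spaces, skipPolicy = skipPolicy))
  fp <- built$fingerprints
  g <- groupLabels(fp)
  twoGroups <- all(c("dementia", "control") %in% g) &&
    min(table(factor(g, c("dementia", "control")))) >= 2L

  screen <- .stage("stats", {
    if (!twoGroups) stop("KS screen needs both dementia and control groups")
    screenCharacters(fp, significanceAlpha = config$significance_alpha)
  })

  rolling <- .stage("rolling", {
    X <- fingerprintMatrix(fp)
    effWindow <- min(config$rolling_window, min(table(g)))
    do.call(rbind, lapply(unique(g), function(grp) {
      prof <- rollingProfile(X[g == grp, "space"], window = effWindow)
      cbind(data.frame(group = grp, stringsAsFactors = FALSE), prof)
    }))
  })

  clusters <- .stage("cluster", {
    kr <- config$k_range[config$k_range < ncol(fp)]
    if (!length(kr)) stop("no candidate k is smaller than the corpus size")
    clusterFingerprints(fp, kRange = kr, seed = config$seed)
  })
  projection <- .stage("cluster", pcaProject(fp))

  classifier <- .stage("classify", lassoClassifier(
    fp, nFolds = config$cv_folds, seed = config$seed))
  roc <- rocCurvePoints(classifier$oofScores, classifier$labels)

  networks <- .stage("network", networkSummaryTable(built$models))

  report <- list(
    n_processed = built$report$n_processed,
    n_skipped = built$report$n_skipped,
    skip_reasons = built$report$skip_reasons,
    config_echo = c(unclass(config),
                    list(effective_rolling_window = rolling$window[1L],
                         effective_k_range = as.integer(names(clusters$silhouetteByK)),
                         skip_policy = skipPolicy))
  )
  # timing goes to the console, never into the (deterministic) data files
  message(sprintf("pipeline: %d transcripts in %.1fs",
                  report$n_processed, proc.time()[["elapsed"]] - t0))

  files <- .stage("write", .writePipelineOutputs(
    outdir, fp, screen, rolling, clusters, projection, classifier, roc,
    networks, report))

  invisible(list(fingerprints = fp, models = built$models, screen = screen,
                 rolling = rolling, clusters = clusters,
                 projection = projection, classifier = classifier,
                 networks = networks, report = report, files = files))
}

.writePipelineOutputs <- function(outdir, fp, screen, rolling, clusters,
                                  projection, classifier, roc, networks,
                                  report) {
  p <- function(f) file.path(outdir, f)
  writeCsvAtomic(.featuresTable(fp), p("features.csv"))
  writeCsvAtomic(screen, p("stats.csv"))
  writeCsvAtomic(rolling[, c("index", "group", "rolling_mean", "rolling_sd",
                             "window")], p("rolling.csv"))
  writeCsvAtomic(data.frame(transcript_id = transcriptIds(fp),
                            group = groupLabels(fp),
                            cluster = clusters$assignments,
                            stringsAsFactors = FALSE), p("clusters.csv"))
  writeCsvAtomic(data.frame(k = as.integer(names(clusters$silhouetteByK)),
                            mean_silhouette = unname(clusters$silhouetteByK)),
                 p("silhouette.csv"))
  writeCsvAtomic(data.frame(transcript_id = transcriptIds(fp),
                            group = groupLabels(fp),
                            pc1 = projection$coords[, 1L],
                            pc2 = projection$coords[, 2L],
                            stringsAsFactors = FALSE), p("projection.csv"))
  writeCsvAtomic(data.frame(character = alphabetLabels(),
                            pc1_loading = projection$loadings[, 1L],
                            pc2_loading = projection$loadings[, 2L],
                            stringsAsFactors = FALSE), p("loadings.csv"))
  writeJsonAtomic(classifier[c("cvAucMean", "cvAucPerFold",
                               "regularizationChosen", "nFolds", "seed")] |>
                    c(list(selectedFeatures = classifier$selectedFeatures)),
                  p("classifier_report.json"))
  writeCsvAtomic(roc$points, p("roc.csv"))
  writeCsvAtomic(networks, p("networks_summary.csv"))
  writeJsonAtomic(report, p("run_report.json"))
  written <- c("features.csv", "stats.csv", "rolling.csv", "clusters.csv",
               "silhouette.csv", "projection.csv", "loadings.csv",
               "classifier_report.json", "roc.csv", "networks_summary.csv",
               "run_report.json")
  sums <- tools::md5sum(file.path(outdir, written))
  writeCsvAtomic(data.frame(file = written, md5 = unname(sums),
                            stringsAsFactors = FALSE),
                 p("output_manifest.csv"))
  c(written, "output_manifest.csv")
}
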