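#' Read a transcript manifest CSV
#'
#' The manifest is a comma-separated file with header
#' \code{transcript_id,path,group} (an optional \code{participant_id}
#' column is accepted and passed through for users who want grouped
#' analyses).  Paths are resolved relative to the manifest's directory
#' unless absolute.
#'
#' @param path Path to the manifest CSV.
#' @return A data.frame with columns \code{transcript_id}, \code{path},
#'   \code{group} (plus \code{participant_id} when present), one row per
#'   transcript.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("transcript_id", "path", "group")
  missing <- setdiff(need, colnames(m))
  if (length(missing)) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!nrow(m)) stop("manifest is empty")
  if (anyDuplicated(m$transcript_id)) {
    stop("duplicate transcript_id in manifest: ",
         m$transcript_id[duplicated(m$transcript_id)][1L])
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

.readTranscriptFile <- function(path) {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  txt <- readChar(path, file.info(path)$size, useBytes = TRUE)
  Encoding(txt) <- "UTF-8"
  if (!validUTF8(txt)) stop("transcript file is not valid UTF-8: ", path)
  txt
}

#' Build the steady-state feature matrix for a corpus
#'
#' Runs the full per-transcript estimation
#' (normalize, encode, count, smooth, solve) over every row of a manifest
#' and stacks the resulting stationary distributions into a
#' [CharFingerprints-class] container (the n x 27 feature matrix with
#' aligned ids and group labels), keeping the per-transcript
#' [TransitionModel-class] objects for network analysis.
#'
#' The manifest may carry the text inline (column \code{text}) or point at
#' UTF-8 files (column \code{path}).  Transcripts that fail (too short
#' after normalization, unreadable file) abort the run by default; with
#' \code{skipPolicy = "skip"} they are dropped and accounted for in the
#' report, so that no transcript is ever lost silently.
#'
#' @param manifest Data.frame with columns \code{transcript_id},
#'   \code{group}, and either \code{text} or \code{path}.
#' @param alpha Laplace smoothing constant (default 0.01).
#' @param collapseSpaces Passed to [normalizeText()].
#' @param skipPolicy \code{"abort"} (default) or \code{"skip"}.
#' @return A list with elements \code{fingerprints}
#'   ([CharFingerprints-class]), \code{models} (list of
#'   [TransitionModel-class], one per processed transcript, in manifest
#'   order) and \code{report} (list: \code{n_processed}, \code{n_skipped},
#'   \code{skip_reasons} data.frame, \code{config_echo}).
#' @examples
#' man <- data.frame(
#'   transcript_id = c("t1", "t2"),
#'   group = c("dementia", "control"),
#'   text = c("the boy took a cookie", "the girl asked for one")
#' )
#' res <- buildFingerprints(man)
#' dim(fingerprintMatrix(res$fingerprints))  # 2 x 27
#' @export
buildFingerprints <- function(manifest, alpha = 0.01, collapseSpaces = TRUE,
                              skipPolicy = c("abort", "skip")) {
  skipPolicy <- match.arg(skipPolicy)
  if (!is.data.frame(manifest) || !nrow(manifest)) {
    stop("manifest must be a non-empty data.frame")
  }
  need <- c("transcript_id", "group")
  if (!all(need %in% colnames(manifest))) {
    stop("manifest needs columns transcript_id and group")
  }
  if (!any(c("text", "path") %in% colnames(manifest))) {
    stop("manifest needs a 'text' or 'path' column")
  }
  if (anyDuplicated(manifest$transcript_id)) {
    stop("duplicate transcript_id: ",
         manifest$transcript_id[duplicated(manifest$transcript_id)][1L])
  }
  n <- nrow(manifest)
  models <- vector("list", n)
  skipped <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      txt <- if ("text" %in% colnames(manifest) &&
                 !is.na(manifest$text[i])) {
        manifest$text[i]
      } else {
        .readTranscriptFile(manifest$path[i])
      }
      transcriptModel(txt,
                      transcriptId = manifest$transcript_id[i],
                      group = manifest$group[i],
                      alpha = alpha, collapseSpaces = collapseSpaces)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (skipPolicy == "abort") {
        stop("transcript '", manifest$transcript_id[i], "' failed: ",
             conditionMessage(res), call. = FALSE)
      }
      skipped[i] <- TRUE
      reasons[i] <- if (grepl("too short", conditionMessage(res))) "too-short"
                    else conditionMessage(res)
    } else {
      models[[i]] <- res
    }
  }
  keep <- !skipped
  if (!any(keep)) stop("every transcript was skipped; nothing to analyse")
  models <- models[keep]
  values <- do.call(rbind, lapply(models, function(m) m@pi))
  fp <- CharFingerprints(values,
                         transcriptIds = manifest$transcript_id[keep],
                         groups = manifest$group[keep])
  report <- list(
    n_processed = sum(keep),
    n_skipped = sum(skipped),
    skip_reasons = data.frame(
      transcript_id = manifest$transcript_id[skipped],
      reason = reasons[skipped],
      stringsAsFactors = FALSE
    ),
    config_echo = list(alpha_smooth = alpha, collapse_spaces = collapseSpaces,
                       skip_policy = skipPolicy)
  )
  list(fingerprints = fp, models = models, report = report)
}
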