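# Shared file writers.  Everything is written atomically (temp file in the
# destination directory, then rename) so an interrupted run never leaves a
# partially written artifact visible.  Numeric columns are serialized with
# %.17g so that reading a CSV back reproduces the in-memory doubles
# exactly; the dialect is fixed (comma, header, UTF-8, '.' decimal, no
# quoting of numerics), never locale-dependent.

#' Write a data.frame as CSV atomically at full float precision
#'
#' @param df A data.frame.
#' @param path Destination path.
#' @return Invisibly, the path.
#' @export
writeCsvAtomic <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(out, tmp, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Write an R object as JSON atomically
#'
#' @param x Object serializable by jsonlite.
#' @param path Destination path.
#' @return Invisibly, the path.
#' @export
writeJsonAtomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

# Feature table in the fixed column order transcript_id,group,a..z,space.
.featuresTable <- function(fingerprints) {
  X <- fingerprintMatrix(fingerprints)
  df <- data.frame(transcript_id = transcriptIds(fingerprints),
                   group = groupLabels(fingerprints),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(X, optional = TRUE))
}
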