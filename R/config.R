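.CONFIG_DEFAULTS <- list(
  alpha_smooth = 0.01,        # Laplace smoothing constant
  collapse_spaces = TRUE,
  significance_alpha = 0.05,  # family-wise level of the KS screen
  k_range = 2:8,
  cv_folds = 5L,
  rolling_window = 30L,
  edge_threshold = 0,
  seed = 1L,
  outdir = "."
)

#' Validate and complete a pipeline configuration
#'
#' Fills defaults, checks every constraint and rejects unknown keys (with a
#' suggestion when an unknown key resembles a known one).  Note the two
#' distinct alphas: \code{alpha_smooth} is the Laplace smoothing constant
#' (default 0.01) and \code{significance_alpha} the family-wise test level
#' (default 0.05); the bare key \code{"alpha"} is deliberately rejected as
#' ambiguous.
#'
#' @param raw Named list of configuration values (possibly empty), e.g.
#'   parsed from a YAML/flat key-value file or command-line flags.
#' @return A complete configuration list of class \code{"PipelineConfig"}.
#' @examples
#' cfg <- validateConfig(list(seed = 7))
#' cfg$alpha_smooth
#' @export
validateConfig <- function(raw = list()) {
  stopifnot(is.list(raw))
  if (length(raw) && (is.null(names(raw)) || any(!nzchar(names(raw))))) {
    stop("configuration entries must all be named")
  }
  known <- names(.CONFIG_DEFAULTS)
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    key <- unknown[1L]
    hits <- known[grepl(key, known, fixed = TRUE)]
    if (!length(hits)) {
      hits <- known[utils::adist(key, known) <= 3L]
    }
    hint <- if (length(hits)) paste0("; did you mean ",
                                     paste(sQuote(hits), collapse = " or "), "?")
            else ""
    stop("unknown configuration key ", sQuote(key), hint)
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, raw)
  if (!is.numeric(cfg$alpha_smooth) || cfg$alpha_smooth <= 0) {
    stop("constraint violated: alpha_smooth must be > 0")
  }
  if (!is.numeric(cfg$significance_alpha) || cfg$significance_alpha <= 0 ||
      cfg$significance_alpha >= 1) {
    stop("constraint violated: significance_alpha must lie in (0, 1)")
  }
  cfg$cv_folds <- as.integer(cfg$cv_folds)
  if (is.na(cfg$cv_folds) || cfg$cv_folds < 2L) {
    stop("constraint violated: cv_folds must be >= 2")
  }
  cfg$k_range <- as.integer(cfg$k_range)
  if (!length(cfg$k_range) || anyNA(cfg$k_range) || any(cfg$k_range < 2L)) {
    stop("constraint violated: k_range must be integers >= 2")
  }
  cfg$rolling_window <- as.integer(cfg$rolling_window)
  if (is.na(cfg$rolling_window) || cfg$rolling_window < 1L) {
    stop("constraint violated: rolling_window must be >= 1")
  }
  if (!is.numeric(cfg$edge_threshold) || cfg$edge_threshold < 0) {
    stop("constraint violated: edge_threshold must be >= 0")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("constraint violated: seed must be an integer")
  cfg$collapse_spaces <- isTRUE(cfg$collapse_spaces)
  structure(cfg, class = "PipelineConfig")
}
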