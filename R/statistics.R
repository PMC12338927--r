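#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes the two-sample KS statistic
#' \eqn{D = \sup_x |F_1(x) - F_2(x)|} (the maximal vertical gap between the
#' two empirical CDFs, attained at a pooled sample point) and the two-sided
#' asymptotic p-value based on the Kolmogorov distribution with effective
#' sample size \eqn{n_1 n_2 / (n_1 + n_2)}.  Ties are handled by evaluating
#' both ECDFs at the pooled points, the standard two-sample treatment.  The
#' degenerate all-identical case returns D = 0, p = 1.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact Use the exact small-sample p-value instead of the
#'   asymptotic one (default `FALSE`; group sizes in the hundreds are
#'   asymptotic-safe).
#' @return List with elements \code{D} and \code{p_value}.
#' @examples
#' ksTwoSample(c(0.1, 0.4, 0.7), c(0.2, 0.5))$D  # 1/3
#' @export
ksTwoSample <- function(x, y, exact = FALSE) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  if (length(unique(c(x, y))) == 1L) {
    return(list(D = 0, p_value = 1))
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Per-character KS screen with multiplicity correction
#'
#' Screens each of the 27 stationary character probabilities for a
#' distributional difference between the two groups: one two-sample KS test
#' per character, with Bonferroni correction across the 27 tests
#' (adjusted p = min(1, 27 p), equivalent to testing at
#' \code{significanceAlpha} / 27).  Benjamini-Hochberg is available behind
#' \code{method = "BH"} but Bonferroni is the default screen.
#'
#' @param fingerprints A [CharFingerprints-class] object containing both
#'   \code{"dementia"} and \code{"control"} transcripts, at least two of
#'   each.
#' @param significanceAlpha Family-wise significance level (default 0.05).
#' @param method \code{"bonferroni"} (default) or \code{"BH"}.
#' @param exact Passed to [ksTwoSample()].
#' @return A data.frame with one row per character, sorted by descending
#'   KS statistic: \code{character}, \code{ks_statistic}, \code{p_value},
#'   \code{p_adjusted}, \code{significant}, \code{n_dementia},
#'   \code{n_control}.
#' @export
screenCharacters <- function(fingerprints, significanceAlpha = 0.05,
                             method = c("bonferroni", "BH"), exact = FALSE) {
  method <- match.arg(method)
  stopifnot(is(fingerprints, "CharFingerprints"))
  if (!is.numeric(significanceAlpha) || significanceAlpha <= 0 ||
      significanceAlpha >= 1) {
    stop("significanceAlpha must lie strictly between 0 and 1")
  }
  X <- fingerprintMatrix(fingerprints)
  g <- groupLabels(fingerprints)
  n1 <- sum(g == "dementia")
  n2 <- sum(g == "control")
  if (n1 < 2L || n2 < 2L) {
    stop("screen needs both a dementia and a control group with >= 2 ",
         "transcripts each (got ", n1, " dementia, ", n2, " control)")
  }
  res <- lapply(seq_len(.K), function(j) {
    ksTwoSample(X[g == "dementia", j], X[g == "control", j], exact = exact)
  })
  p <- vapply(res, `[[`, numeric(1), "p_value")
  padj <- stats::p.adjust(p, method = if (method == "bonferroni") "bonferroni" else "BH")
  out <- data.frame(
    character = alphabetLabels(),
    ks_statistic = vapply(res, `[[`, numeric(1), "D"),
    p_value = p,
    p_adjusted = padj,
    significant = padj < significanceAlpha,
    n_dementia = n1,
    n_control = n2,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$ks_statistic, out$character), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "significance_alpha") <- significanceAlpha
  attr(out, "method") <- method
  out
}

#' Rolling mean and standard deviation of a series
#'
#' Trailing-window summary used to profile the space-character stationary
#' probability across transcript indices: position t (for t >= window)
#' holds the mean and sample standard deviation (n - 1 denominator; 0 when
#' window = 1) of the window ending at t.  The first window - 1 positions
#' are omitted.  Ordering of the series follows the manifest; the window is
#' configuration, not a constant.
#'
#' @param series Numeric vector.
#' @param window Window length, >= 1 and <= length(series).
#' @return Data.frame with columns \code{index} (window..length),
#'   \code{rolling_mean}, \code{rolling_sd}, \code{window}.
#' @examples
#' rollingProfile(c(0, 1, 0, 1, 0), window = 2)$rolling_mean  # all 0.5
#' @export
rollingProfile <- function(series, window = 30L) {
  if (!is.numeric(series) || anyNA(series)) stop("series must be numeric without NA")
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  if (window > length(series)) {
    stop("window (", window, ") exceeds series length (", length(series), ")")
  }
  m <- zoo::rollapply(series, width = window, FUN = mean, align = "right")
  s <- if (window == 1L) rep(0, length(series))
       else zoo::rollapply(series, width = window, FUN = stats::sd, align = "right")
  data.frame(index = seq.int(window, length(series)),
             rolling_mean = as.numeric(m),
             rolling_sd = as.numeric(s),
             window = window)
}
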