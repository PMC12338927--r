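#' The 27-symbol character alphabet
#'
#' The fixed, ordered vocabulary over which every transcript is modelled:
#' the lowercase letters \code{a}--\code{z} (positions 1--26) followed by the
#' space character (position 27).  The space symbol is retained because it
#' carries the pausing signal that character-level modelling of speech is
#' after; everything else (digits, punctuation, accented letters) is removed
#' during normalization.
#'
#' @return A character vector of length 27: \code{letters} followed by
#'   \code{" "}.
#' @seealso [alphabetLabels()] for file-friendly column names,
#'   [normalizeText()], [encodeTranscript()].
#' @examples
#' charAlphabet()
#' match(" ", charAlphabet())  # the space symbol sits at index 27
#' @export
charAlphabet <- function() c(letters, " ")

#' File-friendly labels for the 27 alphabet symbols
#'
#' Identical to [charAlphabet()] except that the space character is spelled
#' out as \code{"space"}, so the labels can be used as CSV headers, feature
#' names and graph node ids.
#'
#' @return A character vector of length 27.
#' @export
alphabetLabels <- function() c(letters, "space")

# internal constants
.K <- 27L
.SPACE_INDEX <- 27L

#' Normalize raw transcript text to the 27-symbol vocabulary
#'
#' Lowercases the input, removes every character outside \code{a}--\code{z}
#' and space, and (by default) collapses each maximal run of spaces and/or
#' removed characters that separated retained letters into a single space,
#' trimming the ends.  With collapsing on, the stationary probability of the
#' space symbol measures pause \emph{events} rather than raw whitespace
#' counts; set \code{collapseSpaces = FALSE} to keep every surviving space.
#'
#' Unicode letters outside \code{a}--\code{z} (e.g. \code{"é"}) are
#' removed, not transliterated: the vocabulary is strictly the 26 ASCII
#' letters plus space.
#'
#' @param text Character vector of raw transcript text (UTF-8).
#' @param collapseSpaces Collapse space runs and trim ends (default `TRUE`).
#' @return Character vector of the same length containing only vocabulary
#'   symbols; possibly empty strings.
#' @examples
#' normalizeText("The boy, 3 cookies!")  # "the boy cookies"
#' normalizeText("!!! 123 ???")          # ""
#' @export
normalizeText <- function(text, collapseSpaces = TRUE) {
  stopifnot(is.character(text))
  bad <- !is.na(text) & !validUTF8(text)
  if (any(bad)) {
    stop("transcript text is not valid UTF-8 (element ",
         which(bad)[1L], ")")
  }
  out <- tolower(text)
  # every non-vocabulary character becomes a space, so that removed
  # punctuation acts as a word separator rather than gluing words together
  out <- gsub("[^a-z ]", " ", out)
  if (collapseSpaces) {
    out <- gsub(" +", " ", out)
    out <- gsub("^ | $", "", out)
  }
  out
}

#' Encode normalized text as an alphabet index sequence
#'
#' Maps each character of a normalized string to its position in
#' [charAlphabet()]: \code{a} = 1, ..., \code{z} = 26, space = 27.  The input
#' must already be normalized; any out-of-vocabulary character is an error
#' (naming the character and its position), as is a string shorter than two
#' characters, since a transcript must contain at least one transition event.
#'
#' @param text A single normalized string (see [normalizeText()]).
#' @return Integer vector of indices in \code{1:27}, one per character.
#' @examples
#' encodeTranscript("ab c")  # 1 2 27 3
#' @export
encodeTranscript <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (nchar(text) < 2L) {
    stop("transcript too short after normalization (need length >= 2, got ",
         nchar(text), ")")
  }
  code <- utf8ToInt(text)
  idx <- integer(length(code))
  isLetter <- code >= 97L & code <= 122L
  isSpace <- code == 32L
  offending <- which(!isLetter & !isSpace)
  if (length(offending)) {
    p <- offending[1L]
    stop(sprintf("invalid symbol '%s' at position %d (not in the 27-symbol vocabulary)",
                 intToUtf8(code[p]), p))
  }
  idx[isLetter] <- code[isLetter] - 96L
  idx[isSpace] <- .SPACE_INDEX
  idx
}

#' Decode an index sequence back to text
#'
#' Inverse of [encodeTranscript()]: turns indices in \code{1:27} back into
#' the corresponding string over the 27-symbol vocabulary.
#'
#' @param indices Integer vector with values in \code{1:27}.
#' @return A single string.
#' @export
decodeIndices <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) && (anyNA(indices) || any(indices < 1L | indices > .K))) {
    stop("indices must all lie in 1:27")
  }
  paste(charAlphabet()[indices], collapse = "")
}
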