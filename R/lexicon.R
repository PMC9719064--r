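# Word-frequency lexicons on the Zipf scale (log10 occurrences per 1e9
# words; ~7 for "the", ~1 for very rare terms).

#' Create a frequency lexicon
#'
#' A lexicon maps lowercase words to Zipf frequencies. Unknown words get
#' `oov_zipf`, by default 0 ("below measurable frequency"), treating
#' out-of-vocabulary words as maximally rare.
#'
#' @param words Character vector of words.
#' @param zipf Numeric vector of Zipf frequencies, all >= 0.
#' @param oov_zipf Value returned for unknown words (default 0).
#' @return An object of class `freq_lexicon`.
#' @export
freq_lexicon <- function(words, zipf, oov_zipf = 0) {
  stopifnot(length(words) == length(zipf), all(zipf >= 0), oov_zipf >= 0)
  words <- tolower(words)
  if (anyDuplicated(words)) {
    stop("freq_lexicon(): duplicate words in lexicon", call. = FALSE)
  }
  out <- list(table = stats::setNames(as.numeric(zipf), words),
              oov_zipf = oov_zipf)
  class(out) <- "freq_lexicon"
  out
}

#' Look up Zipf frequencies
#'
#' @param lexicon A `freq_lexicon`.
#' @param words Character vector of words (lowercased internally).
#' @return Numeric vector of Zipf frequencies, `oov_zipf` for unknowns.
#' @export
zipf_frequency <- function(lexicon, words) {
  stopifnot(inherits(lexicon, "freq_lexicon"))
  if (length(words) == 0L) return(numeric(0))
  z <- unname(lexicon$table[tolower(words)])
  z[is.na(z)] <- lexicon$oov_zipf
  z
}

#' Read a lexicon from a two-column table
#'
#' Plain-text file with one `word<whitespace>zipf` pair per line; lines
#' starting with `#` are comments.
#'
#' @param path File path.
#' @param oov_zipf Out-of-vocabulary default, passed to [freq_lexicon()].
#' @return A `freq_lexicon`.
#' @export
read_lexicon <- function(path, oov_zipf = 0) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("word", "zipf"),
                           colClasses = c("character", "numeric"))
  freq_lexicon(tab$word, tab$zipf, oov_zipf = oov_zipf)
}

#' @export
print.freq_lexicon <- function(x, ...) {
  cat(sprintf("freq_lexicon: %d words, oov_zipf = %g\n",
              length(x$table), x$oov_zipf))
  invisible(x)
}
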