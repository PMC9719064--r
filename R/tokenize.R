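# Canonical tokenizer shared by every metric and reward in the package.
# Reproducibility matters more than linguistic finesse here: all published
# readability formulas are sensitive to tokenization, so one pinned,
# dependency-free behavior is used throughout and documented precisely.

# Abbreviations whose trailing period must not end a sentence.
.abbrev_guard <- c(
  "e.g.", "i.e.", "et al.", "etc.", "vs.", "cf.", "fig.", "dr.", "mr.",
  "mrs.", "ms.", "no.", "approx.", "ca."
)

#' Split text into sentences
#'
#' Sentences end at `.`, `!` or `?` followed by whitespace or end of string.
#' A small guard list of common abbreviations ("e.g.", "et al.", ...) keeps
#' their periods from terminating a sentence. Trailing text without a
#' terminator counts as one sentence.
#'
#' @param text A character scalar (UTF-8).
#' @return Character vector of sentences (possibly empty).
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  # fast path: no terminator anywhere means exactly one sentence
  if (!grepl("[.!?]", text)) return(trimws(text))
  shielded <- text
  # Shield guarded abbreviations: replace their periods with a placeholder
  # byte that no real text contains, split, then restore.
  for (ab in .abbrev_guard) {
    pat <- gsub(".", "\\.", ab, fixed = TRUE)
    repl <- gsub(".", "\x01", ab, fixed = TRUE)
    shielded <- gsub(pat, repl, shielded, ignore.case = TRUE)
  }
  parts <- strsplit(shielded, "[.!?]+(\\s+|$)")[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Tokenize text into lowercase word tokens
#'
#' Words are maximal runs of alphanumeric characters and apostrophes,
#' lowercased. Everything else is a separator.
#'
#' @param text A character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_words <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("[[:alnum:]']+", tolower(text))[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(tolower(text), list(m))[[1]]
  # strip bare apostrophes that matched on their own
  toks[grepl("[[:alnum:]]", toks)]
}

#' Unique lowercased word types of a text
#'
#' @param text A character scalar.
#' @return Character vector of unique tokens, in order of first appearance.
#' @export
word_types <- function(text) unique(tokenize_words(text))

# Irregular words the vowel-group heuristic gets wrong by more than one
# syllable, or that tests and examples rely on.
.syllable_exceptions <- c(
  every = 2L, people = 2L, business = 2L, evening = 2L, area = 3L,
  idea = 3L, science = 2L, being = 2L, quiet = 2L, create = 2L,
  medicine = 3L, family = 3L
)

#' Count syllables in a single word
#'
#' Heuristic counter: count groups of consecutive vowels (`aeiouy`),
#' subtract one for a trailing silent "e" unless it is the word's only
#' vowel group, floor at 1. A small exception table overrides common
#' irregulars. Tokens without vowels (numbers, initialisms) count 1.
#'
#' @param word A single non-empty token (lowercased internally).
#' @return Integer syllable count, always >= 1.
#' @export
#' @examples
#' count_syllables("medical") # 3
#' count_syllables("rate")    # 1
count_syllables <- function(word) {
  stopifnot(is.character(word), length(word) == 1L)
  if (is.na(word) || !nzchar(word)) {
    stop("count_syllables(): empty token is not a word", call. = FALSE)
  }
  w <- tolower(word)
  if (w %in% names(.syllable_exceptions)) {
    return(unname(.syllable_exceptions[[w]]))
  }
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  if (groups[1] == -1L) return(1L)
  n <- length(groups)
  # trailing silent e: word ends in "e" (not "le" after a consonant is kept
  # simple: any terminal lone "e" group is dropped) and has another group
  if (n > 1L && grepl("[^aeiouy]e$", w)) n <- n - 1L
  max(n, 1L)
}

# Memo for per-word syllable counts: word surfaces recur constantly in
# corpus statistics and reward scoring, and the count is pure.
.syllable_memo <- new.env(parent = emptyenv())

#' Count syllables for a vector of tokens
#' @param words Character vector of tokens.
#' @return Integer vector of per-token syllable counts.
#' @export
count_syllables_vec <- function(words) {
  if (length(words) == 0L) return(integer(0))
  vapply(words, function(w) {
    memo <- .syllable_memo[[w]]
    if (!is.null(memo)) return(memo)
    n <- count_syllables(w)
    .syllable_memo[[w]] <- n
    n
  }, integer(1), USE.NAMES = FALSE)
}
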