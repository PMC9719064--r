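# Readability statistics and automatic simplification metrics.

#' Summary statistics of a text
#'
#' Computes the word, sentence, syllable, and character counts that underlie
#' the readability formulas, using the package's canonical tokenizer
#' ([tokenize_words()], [split_sentences()], [count_syllables()]).
#' Characters are the alphanumeric characters inside word tokens.
#'
#' @param text A character scalar; may be empty.
#' @return An object of class `text_stats`: a list with counts
#'   `n_sentences`, `n_words`, `n_syllables`, `n_characters` and ratios
#'   `words_per_sentence`, `syllables_per_word`, `characters_per_word`
#'   (ratios are `NA` when their denominator is zero).
#' @export
#' @examples
#' analyze_text("The cat sat.")
analyze_text <- function(text) {
  words <- tokenize_words(text)
  sents <- split_sentences(text)
  n_words <- length(words)
  n_sent <- length(sents)
  n_syll <- if (n_words) sum(count_syllables_vec(words)) else 0L
  n_char <- if (n_words) sum(nchar(gsub("[^[:alnum:]]", "", words))) else 0L
  out <- list(
    n_sentences = n_sent,
    n_words = n_words,
    n_syllables = as.integer(n_syll),
    n_characters = as.integer(n_char),
    words_per_sentence = if (n_sent > 0L) n_words / n_sent else NA_real_,
    syllables_per_word = if (n_words > 0L) n_syll / n_words else NA_real_,
    characters_per_word = if (n_words > 0L) n_char / n_words else NA_real_
  )
  class(out) <- "text_stats"
  out
}

#' @export
print.text_stats <- function(x, ...) {
  cat(sprintf(
    "text_stats: %d sentence(s), %d word(s), %d syllable(s), %d character(s)\n",
    x$n_sentences, x$n_words, x$n_syllables, x$n_characters
  ))
  invisible(x)
}

#' Construct text statistics from raw counts
#'
#' Mostly for tests and worked examples where the counts are stated
#' directly rather than derived from a text.
#'
#' @param n_sentences,n_words,n_syllables,n_characters Non-negative counts.
#' @return A `text_stats` object.
#' @export
text_stats <- function(n_sentences, n_words, n_syllables, n_characters = 0L) {
  stopifnot(
    n_sentences >= 0, n_words >= 0, n_syllables >= 0, n_characters >= 0
  )
  out <- list(
    n_sentences = as.integer(n_sentences),
    n_words = as.integer(n_words),
    n_syllables = as.integer(n_syllables),
    n_characters = as.integer(n_characters),
    words_per_sentence = if (n_sentences > 0) n_words / n_sentences else NA_real_,
    syllables_per_word = if (n_words > 0) n_syllables / n_words else NA_real_,
    characters_per_word = if (n_words > 0) n_characters / n_words else NA_real_
  )
  class(out) <- "text_stats"
  out
}

#' Flesch-Kincaid Grade Level coefficient presets
#'
#' Two named triples `(a, b, c)` for
#' `FKGL = a * words/sentence + b * syllables/word - c`:
#' `"standard"` = (0.39, 11.8, 15.59), the widely used Flesch-Kincaid
#' grade formula, and `"paper"` = (0.38, 1.8, 15.59), an alternative
#' printed in parts of the medical-simplification literature. The
#' standard preset is the default for corpus reports; results from the
#' two are not comparable.
#'
#' @param preset `"standard"` or `"paper"`, or a numeric triple passed
#'   through unchanged.
#' @return Named numeric vector `c(a=, b=, c=)`.
#' @export
fkgl_coefficients <- function(preset = c("standard", "paper")) {
  if (is.numeric(preset)) {
    stopifnot(length(preset) == 3L)
    return(c(a = preset[[1]], b = preset[[2]], c = preset[[3]]))
  }
  preset <- match.arg(preset)
  switch(preset,
    standard = c(a = 0.39, b = 11.8, c = 15.59),
    paper    = c(a = 0.38, b = 1.8,  c = 15.59)
  )
}

#' Flesch-Kincaid Grade Level
#'
#' `a * words_per_sentence + b * syllables_per_word - c` for the chosen
#' coefficient triple. Lower grades indicate simpler text; the value can
#' be negative for very short, monosyllabic text.
#'
#' @param stats A `text_stats` object (or a text string, analyzed first).
#' @param coefficients Preset name or numeric triple; see
#'   [fkgl_coefficients()].
#' @return Grade level (numeric scalar).
#' @export
#' @examples
#' fkgl(text_stats(1, 3, 3, 9))                        # standard preset
#' fkgl(text_stats(1, 3, 3, 9), coefficients = "paper")
fkgl <- function(stats, coefficients = "standard") {
  if (is.character(stats) && !inherits(stats, "text_stats")) {
    stats <- analyze_text(stats)
  }
  if (stats$n_words == 0L || stats$n_sentences == 0L) {
    stop("fkgl(): readability undefined for text with zero words or sentences",
         call. = FALSE)
  }
  k <- fkgl_coefficients(coefficients)
  unname(k["a"] * stats$words_per_sentence +
         k["b"] * stats$syllables_per_word - k["c"])
}

#' Automated Readability Index
#'
#' `4.71 * characters_per_word + 0.5 * words_per_sentence - 21.43`,
#' the standard ARI constants. Characters are alphanumeric characters
#' inside word tokens.
#'
#' @inheritParams fkgl
#' @return Grade level (numeric scalar).
#' @export
ari <- function(stats) {
  if (is.character(stats) && !inherits(stats, "text_stats")) {
    stats <- analyze_text(stats)
  }
  if (stats$n_words == 0L || stats$n_sentences == 0L) {
    stop("ari(): readability undefined for text with zero words or sentences",
         call. = FALSE)
  }
  4.71 * stats$characters_per_word + 0.5 * stats$words_per_sentence - 21.43
}

# n-gram utilities ---------------------------------------------------------

# Multiset of n-grams as a named count table ("a b" -> 2L).
.ngram_counts <- function(tokens, n) {
  if (length(tokens) < n) return(integer(0))
  grams <- vapply(
    seq_len(length(tokens) - n + 1L),
    function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
    character(1)
  )
  tab <- table(grams)
  stats::setNames(as.integer(tab), names(tab))
}

# Unique n-grams as a character set.
.ngram_set <- function(tokens, n) names(.ngram_counts(tokens, n))

#' ROUGE-n precision, recall and F1
#'
#' Multiset (clipped-count) n-gram overlap between a candidate and a
#' reference text: precision over candidate n-grams, recall over reference
#' n-grams, and their harmonic mean. No stemming or stopword removal.
#' When neither text contains any n-gram of order `n`, all three scores
#' are 0.
#'
#' @param candidate,reference Character scalars.
#' @param n N-gram order, >= 1.
#' @return Named numeric vector `c(precision=, recall=, f1=)`, each in
#'   `[0, 1]`.
#' @export
#' @examples
#' rouge_n("a b c", "a b d", 1) # F1 = 2/3
rouge_n <- function(candidate, reference, n = 1L) {
  stopifnot(n >= 1L)
  cg <- .ngram_counts(tokenize_words(candidate), n)
  rg <- .ngram_counts(tokenize_words(reference), n)
  if (length(cg) == 0L && length(rg) == 0L) {
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  shared <- intersect(names(cg), names(rg))
  overlap <- if (length(shared)) sum(pmin(cg[shared], rg[shared])) else 0L
  p <- if (sum(cg) > 0L) overlap / sum(cg) else 0
  r <- if (sum(rg) > 0L) overlap / sum(rg) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

# Score one SARI operation for a single n: candidate-side set vs
# reference-side set. Both empty -> 1 (the operation was not required and
# was not performed); exactly one empty -> 0; otherwise F1 (add/keep) or
# precision (delete).
.sari_op_score <- function(cand_set, ref_set, mode = c("f1", "precision")) {
  mode <- match.arg(mode)
  if (length(cand_set) == 0L && length(ref_set) == 0L) return(1)
  if (length(cand_set) == 0L || length(ref_set) == 0L) return(0)
  inter <- length(intersect(cand_set, ref_set))
  p <- inter / length(cand_set)
  if (mode == "precision") return(p)
  r <- inter / length(ref_set)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' SARI simplification score
#'
#' Averages the F1 of n-gram additions and keeps and the precision of
#' n-gram deletions, judged against the source and the reference(s), for
#' n = 1..4 with equal weight. Operation sets use unique n-grams; for a
#' given operation and order, an empty candidate set scores 1 when the
#' reference set is also empty and 0 otherwise. With multiple references
#' the reference-side sets are unions over references.
#'
#' @param source Source (complex) text, non-empty.
#' @param candidate Candidate simplification.
#' @param references Character vector of reference simplifications
#'   (non-empty).
#' @return SARI score in `[0, 1]`.
#' @export
#' @examples
#' sari("a b c", "a b d", "a b d") # 1
sari <- function(source, candidate, references) {
  if (length(references) == 0L) {
    stop("sari(): at least one reference is required", call. = FALSE)
  }
  src_tok <- tokenize_words(source)
  if (length(src_tok) == 0L) {
    stop("sari(): source text has no tokens", call. = FALSE)
  }
  cand_tok <- tokenize_words(candidate)
  ref_toks <- lapply(references, tokenize_words)
  add <- keep <- del <- numeric(4)
  for (n in 1:4) {
    s <- .ngram_set(src_tok, n)
    c_ <- .ngram_set(cand_tok, n)
    r <- unique(unlist(lapply(ref_toks, .ngram_set, n = n)))
    add[n] <- .sari_op_score(setdiff(c_, s), setdiff(r, s), "f1")
    keep[n] <- .sari_op_score(intersect(c_, s), intersect(r, s), "f1")
    del[n] <- .sari_op_score(setdiff(s, c_), setdiff(s, r), "precision")
  }
  (mean(add) + mean(keep) + mean(del)) / 3
}
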