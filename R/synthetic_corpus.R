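# Synthetic paired-paragraph generator.
#
# The generator emulates exactly the statistical axes the rewards and
# metrics read: a readability gap (sentence length, syllables per word)
# and a Zipf-frequency shift between the word types deleted and inserted
# by the simplification. It makes no attempt at meaning, discourse or
# medical terminology; see the methods vignette for what that implies.

#' Synthetic vocabulary specification
#'
#' A deterministic pseudo-word vocabulary. Each word carries an assigned
#' syllable count and Zipf frequency; Zipf values cover a continuum
#' (default 0.5 to 7) and syllable counts correlate negatively with
#' frequency, as in natural language (common words are short). Surfaces
#' are built from consonant-vowel syllables so the package's heuristic
#' syllable counter sees approximately the assigned counts.
#'
#' @param n_words Vocabulary size (default 500).
#' @param seed Integer seed; the vocabulary is a pure function of
#'   `(n_words, seed, zipf_range)`.
#' @param zipf_range Numeric length-2 range of Zipf frequencies.
#' @return An object of class `vocab_spec`: list with `words` (data frame
#'   word / syllables / zipf), `end_token`, `seed`.
#' @export
vocab_spec <- function(n_words = 500L, seed = 42L, zipf_range = c(0.5, 7)) {
  stopifnot(n_words >= 10L, zipf_range[1] >= 0, zipf_range[2] > zipf_range[1])
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r",
                  "s", "t", "v", "z")
  vowels <- c("a", "i", "o", "u") # no "e": avoids the silent-e rule
  words <- with_preserved_rng({
    set.seed(seed)
    zipf <- sort(stats::runif(n_words, zipf_range[1], zipf_range[2]))
    # common words short, rare words polysyllabic
    syll <- pmin(pmax(round(5.2 - 0.62 * zipf + stats::rnorm(n_words, 0, 0.4)),
                      1L), 5L)
    surf <- character(n_words)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(n_words)) {
      repeat {
        k <- syll[i]
        parts <- paste0(sample(consonants, k, replace = TRUE),
                        sample(vowels, k, replace = TRUE))
        w <- paste(parts, collapse = "")
        if (k == 1L) w <- paste0(w, sample(consonants, 1)) # cvc monosyllable
        if (is.null(seen[[w]])) { seen[[w]] <- TRUE; surf[i] <- w; break }
      }
    }
    data.frame(word = surf, syllables = as.integer(syll), zipf = zipf,
               stringsAsFactors = FALSE)
  })
  structure(list(words = words, end_token = "</s>", seed = as.integer(seed)),
            class = "vocab_spec")
}

#' @export
print.vocab_spec <- function(x, ...) {
  cat(sprintf("vocab_spec: %d words, zipf %.2f..%.2f, seed %d\n",
              nrow(x$words), min(x$words$zipf), max(x$words$zipf), x$seed))
  invisible(x)
}

#' Frequency lexicon of a synthetic vocabulary
#'
#' @param vocab A `vocab_spec`.
#' @param oov_zipf Out-of-vocabulary default.
#' @return A `freq_lexicon` over the vocabulary's assigned Zipf values.
#' @export
vocab_lexicon <- function(vocab, oov_zipf = 0) {
  stopifnot(inherits(vocab, "vocab_spec"))
  freq_lexicon(vocab$words$word, vocab$words$zipf, oov_zipf = oov_zipf)
}

#' Paired-corpus specification
#'
#' Controls of the generator: how long and how rare-worded the complex
#' side is, how short and common-worded the simple side is, and the
#' target corpus-mean Zipf shift `delta_z` between inserted and deleted
#' word types. Defaults correspond to the analysis scale the package's
#' corpus reports use: complex paragraphs of 3-6 sentences around 25
#' words each drawn mostly from the rare end of the vocabulary, simple
#' paragraphs of 2-4 sentences around 8 words, and a target shift of
#' 0.4 (the shift typical of paired medical simplification data).
#'
#' @param n_pairs Number of pairs, >= 1.
#' @param complex_len_mean,complex_len_sd Sentence-length distribution of
#'   the complex side (truncated normal, floor 3 words).
#' @param simple_len_mean,simple_len_sd Same for the simple side.
#' @param complex_sentences,simple_sentences Length-2 integer ranges of
#'   sentences per paragraph.
#' @param complex_zipf_center Center of the Gaussian Zipf weighting used
#'   to draw complex-side words (low = rare-biased).
#' @param complex_zipf_sd Spread of that weighting.
#' @param keep_fraction Fraction of simple-side tokens reused from the
#'   complex side's word types.
#' @param target_delta_z Target corpus-mean Zipf shift between inserted
#'   and deleted types (default 0.4).
#' @param seed Integer seed; generation is a pure function of
#'   `(vocab, spec)`.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_pairs = 200L,
                        complex_len_mean = 25, complex_len_sd = 5,
                        simple_len_mean = 8, simple_len_sd = 2,
                        complex_sentences = c(3L, 6L),
                        simple_sentences = c(2L, 4L),
                        complex_zipf_center = 2.2,
                        complex_zipf_sd = 1.3,
                        keep_fraction = 0.3,
                        target_delta_z = 0.4,
                        seed = 1L) {
  stopifnot(n_pairs >= 1L, complex_len_mean > 0, simple_len_mean > 0,
            complex_len_sd >= 0, simple_len_sd >= 0,
            keep_fraction >= 0, keep_fraction < 1,
            length(complex_sentences) == 2L, length(simple_sentences) == 2L)
  structure(
    list(n_pairs = as.integer(n_pairs),
         complex_len_mean = complex_len_mean, complex_len_sd = complex_len_sd,
         simple_len_mean = simple_len_mean, simple_len_sd = simple_len_sd,
         complex_sentences = as.integer(complex_sentences),
         simple_sentences = as.integer(simple_sentences),
         complex_zipf_center = complex_zipf_center,
         complex_zipf_sd = complex_zipf_sd,
         keep_fraction = keep_fraction,
         target_delta_z = target_delta_z,
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Training-scale corpus specification
#'
#' Same generator, smaller paragraphs (1-2 complex sentences around 12
#' words, one simple sentence around 6), sized for desk-scale training
#' of the toy policy.
#'
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#' @param ... Overrides passed to [corpus_spec()].
#' @return A `corpus_spec`.
#' @export
training_corpus_spec <- function(n_pairs = 200L, seed = 1L, ...) {
  corpus_spec(
    n_pairs = n_pairs,
    complex_len_mean = 12, complex_len_sd = 3,
    simple_len_mean = 6, simple_len_sd = 1.5,
    complex_sentences = c(1L, 2L), simple_sentences = c(1L, 1L),
    seed = seed, ...
  )
}

.truncnorm_len <- function(n, mean, sd, floor = 3L) {
  pmax(round(stats::rnorm(n, mean, sd)), floor)
}

.as_sentence <- function(words) {
  s <- paste(words, collapse = " ")
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)), ".")
}

#' Generate a paired complex/simple corpus
#'
#' For each pair, a complex paragraph is drawn with long sentences and a
#' rare-biased word distribution. The simple paragraph reuses a fraction
#' of the complex paragraph's word types and fills the rest with words
#' whose Zipf frequency is matched to (mean deleted Zipf +
#' `target_delta_z`), so that the corpus-mean shift between inserted and
#' deleted types approximates the target. Fully determined by
#' `(vocab, spec)`.
#'
#' @param vocab A `vocab_spec`.
#' @param spec A `corpus_spec`.
#' @return List of `paragraph_pair` objects (id, source_text,
#'   reference_text, generated_text = NULL), with the spec attached as
#'   attribute `"spec"`.
#' @export
generate_corpus <- function(vocab, spec = corpus_spec()) {
  stopifnot(inherits(vocab, "vocab_spec"), inherits(spec, "corpus_spec"))
  tab <- vocab$words
  zr <- range(tab$zipf)
  if (spec$target_delta_z > (zr[2] - zr[1])) {
    stop("generate_corpus(): vocabulary's Zipf range cannot support ",
         "the requested target_delta_z", call. = FALSE)
  }
  cw <- stats::dnorm(tab$zipf, spec$complex_zipf_center, spec$complex_zipf_sd)
  if (sum(cw) <= 0) {
    stop("generate_corpus(): vocabulary has no words near the complex-side ",
         "Zipf center (no rare words?)", call. = FALSE)
  }
  pairs <- with_preserved_rng({
    set.seed(spec$seed)
    lapply(seq_len(spec$n_pairs), function(i) {
      # complex paragraph
      ns_c <- sample(spec$complex_sentences[1]:spec$complex_sentences[2], 1)
      lens_c <- .truncnorm_len(ns_c, spec$complex_len_mean,
                               spec$complex_len_sd)
      idx_c <- sample.int(nrow(tab), sum(lens_c), replace = TRUE, prob = cw)
      sents_c <- split(tab$word[idx_c], rep(seq_len(ns_c), lens_c))
      src <- paste(vapply(sents_c, .as_sentence, character(1)),
                   collapse = " ")
      types_c <- unique(idx_c)

      # simple paragraph: kept types + zipf-matched insertions
      ns_s <- sample(spec$simple_sentences[1]:spec$simple_sentences[2], 1)
      lens_s <- .truncnorm_len(ns_s, spec$simple_len_mean, spec$simple_len_sd)
      n_tok <- sum(lens_s)
      n_keep <- min(round(spec$keep_fraction * n_tok), length(types_c))
      kept <- if (n_keep > 0) sample(types_c, n_keep) else integer(0)
      deleted <- setdiff(types_c, kept)
      z_del <- if (length(deleted)) mean(tab$zipf[deleted]) else 0
      z_want <- z_del + spec$target_delta_z
      if (z_want > zr[2] + 0.5 || z_want < zr[1] - 0.5) {
        stop("generate_corpus(): required insertion Zipf ", round(z_want, 2),
             " is outside the vocabulary's range; spec is infeasible",
             call. = FALSE)
      }
      cand <- setdiff(seq_len(nrow(tab)), types_c)
      iw <- stats::dnorm(tab$zipf[cand], z_want, 0.25)
      if (sum(iw) <= 0) iw <- rep(1, length(cand))
      n_ins_types <- max(3L, min(round(0.6 * (n_tok - n_keep)), length(cand)))
      ins <- cand[sample.int(length(cand), n_ins_types, prob = iw)]
      # The complex text depletes candidates just below z_want, biasing the
      # drawn mean upward; swap members until the mean matches the target.
      zi <- tab$zipf
      err <- mean(zi[ins]) - z_want
      for (it in 1:25) {
        if (abs(err) < 0.03) break
        drop_i <- if (err > 0) which.max(zi[ins]) else which.min(zi[ins])
        rest <- setdiff(cand, ins)
        if (length(rest) == 0L) break
        want_v <- z_want * length(ins) - sum(zi[ins]) + zi[ins[drop_i]]
        add <- rest[which.min(abs(zi[rest] - want_v))]
        new_ins <- ins
        new_ins[drop_i] <- add
        if (abs(mean(zi[new_ins]) - z_want) >= abs(err)) break
        ins <- new_ins
        err <- mean(zi[ins]) - z_want
      }
      pool <- c(rep(kept, 2L), ins) # kept types appear, insertions dominate
      toks_s <- sample(c(ins, sample(pool, max(n_tok - n_ins_types, 0),
                                     replace = TRUE)))
      sents_s <- split(tab$word[toks_s], rep(seq_len(ns_s), lens_s))
      ref <- paste(vapply(sents_s, .as_sentence, character(1)),
                   collapse = " ")
      paragraph_pair(sprintf("pair-%04d", i), src, ref)
    })
  })
  attr(pairs, "spec") <- spec
  pairs
}

#' Construct a paragraph pair
#'
#' @param id Identifier string.
#' @param source_text Complex source text (non-empty).
#' @param reference_text Simple reference text (non-empty).
#' @param generated_text Optional generated simplification.
#' @return An object of class `paragraph_pair`.
#' @export
paragraph_pair <- function(id, source_text, reference_text,
                           generated_text = NULL) {
  stopifnot(nzchar(source_text), nzchar(reference_text))
  structure(
    list(id = as.character(id), source_text = source_text,
         reference_text = reference_text, generated_text = generated_text),
    class = "paragraph_pair"
  )
}

#' Corpus-level statistics of a paired corpus
#'
#' Per-side mean FKGL and ARI, the distribution of the Zipf shift
#' `delta_z` between each pair's source and reference, and the fraction
#' of pairs whose shift falls in the `band` (default `[0.3, 0.5]`,
#' operationalizing "approximately 0.4").
#'
#' @param pairs Non-empty list of `paragraph_pair`s.
#' @param lexicon A `freq_lexicon`.
#' @param coefficients FKGL preset; see [fkgl_coefficients()].
#' @param band Length-2 numeric inclusive band for the delta-z fraction.
#' @return An object of class `corpus_stats`: list with `n`,
#'   `mean_fkgl_complex`, `mean_fkgl_simple`, `mean_ari_complex`,
#'   `mean_ari_simple`, `mean_delta_z`, `sd_delta_z`, `delta_z` (vector),
#'   `band`, `band_fraction`.
#' @export
corpus_stats <- function(pairs, lexicon, coefficients = "standard",
                         band = c(0.3, 0.5)) {
  if (length(pairs) == 0L) {
    stop("corpus_stats(): empty corpus", call. = FALSE)
  }
  stopifnot(inherits(lexicon, "freq_lexicon"), length(band) == 2L)
  fk_c <- fk_s <- ar_c <- ar_s <- dz <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    sc <- analyze_text(p$source_text)
    ss <- analyze_text(p$reference_text)
    fk_c[i] <- fkgl(sc, coefficients)
    fk_s[i] <- fkgl(ss, coefficients)
    ar_c[i] <- ari(sc)
    ar_s[i] <- ari(ss)
    dz[i] <- lexical_stats(p$source_text, p$reference_text, lexicon)$delta_z
  }
  structure(
    list(n = length(pairs),
         mean_fkgl_complex = mean(fk_c), mean_fkgl_simple = mean(fk_s),
         mean_ari_complex = mean(ar_c), mean_ari_simple = mean(ar_s),
         mean_delta_z = mean(dz), sd_delta_z = stats::sd(dz),
         delta_z = dz, band = band,
         band_fraction = mean(dz >= band[1] & dz <= band[2])),
    class = "corpus_stats"
  )
}

#' @export
print.corpus_stats <- function(x, ...) {
  cat(sprintf(
    paste0("corpus_stats over %d pairs\n",
           "  FKGL  complex %.2f | simple %.2f\n",
           "  ARI   complex %.2f | simple %.2f\n",
           "  delta_z mean %.3f (sd %.3f), fraction in [%.2f, %.2f]: %.2f\n"),
    x$n, x$mean_fkgl_complex, x$mean_fkgl_simple,
    x$mean_ari_complex, x$mean_ari_simple,
    x$mean_delta_z, x$sd_delta_z, x$band[1], x$band[2], x$band_fraction
  ))
  invisible(x)
}

#' Convert paragraph pairs to token-id sequence pairs
#'
#' Tokenizes both sides with the canonical tokenizer and maps tokens to
#' the policy vocabulary; tokens outside the vocabulary are dropped (the
#' toy policy can only model its own vocabulary).
#'
#' @param pairs List of `paragraph_pair`s.
#' @param model A `toy_policy` supplying the vocabulary.
#' @return List of `sequence_pair`s; pairs whose source or target end up
#'   empty after vocabulary filtering are dropped.
#' @export
pairs_to_sequences <- function(pairs, model) {
  stopifnot(inherits(model, "toy_policy"))
  out <- lapply(pairs, function(p) {
    s <- match(tokenize_words(p$source_text), model$vocab)
    y <- match(tokenize_words(p$reference_text), model$vocab)
    s <- s[!is.na(s)]
    y <- y[!is.na(y)]
    if (length(s) == 0L || length(y) == 0L) return(NULL)
    sequence_pair(s, y, source_text = p$source_text,
                  reference_text = p$reference_text)
  })
  out[!vapply(out, is.null, logical(1))]
}
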