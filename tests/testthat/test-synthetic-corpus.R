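test_that("vocabulary generation is deterministic with valid structure", {
  v1 <- vocab_spec(100, seed = 5)
  v2 <- vocab_spec(100, seed = 5)
  expect_identical(v1, v2)
  expect_equal(nrow(v1$words), 100L)
  expect_false(anyDuplicated(v1$words$word) > 0)
  expect_true(all(v1$words$syllables >= 1))
  expect_true(all(v1$words$zipf >= 0))
  # common words are shorter than rare words on average
  med <- median(v1$words$zipf)
  expect_lt(mean(v1$words$syllables[v1$words$zipf > med]),
            mean(v1$words$syllables[v1$words$zipf <= med]))
})

test_that("generate_corpus honors the count contract and is pure", {
  v <- vocab_spec(150, seed = 42)
  spec <- corpus_spec(n_pairs = 25, seed = 9)
  p1 <- generate_corpus(v, spec)
  p2 <- generate_corpus(v, spec)
  expect_length(p1, 25L)
  expect_identical(p1, p2)
  for (p in p1[1:5]) {
    expect_s3_class(p, "paragraph_pair")
    expect_true(nzchar(p$source_text))
    expect_true(nzchar(p$reference_text))
  }
})

test_that("an infeasible Zipf target is rejected", {
  flat <- vocab_spec(100, seed = 1, zipf_range = c(3, 4))
  expect_error(
    generate_corpus(flat, corpus_spec(n_pairs = 5, target_delta_z = 2,
                                      seed = 1)),
    "target_delta_z|infeasible"
  )
})

test_that("complex side reads harder and the readability gap tracks sentence length", {
  v <- vocab_spec(300, seed = 42)
  lex <- vocab_lexicon(v)
  gaps_short <- gaps_long <- numeric(4)
  for (i in 1:4) {
    short <- corpus_stats(
      generate_corpus(v, corpus_spec(n_pairs = 40, complex_len_mean = 15,
                                     seed = i)), lex)
    long <- corpus_stats(
      generate_corpus(v, corpus_spec(n_pairs = 40, complex_len_mean = 30,
                                     seed = i)), lex)
    gaps_short[i] <- short$mean_fkgl_complex
    gaps_long[i] <- long$mean_fkgl_complex
    expect_gt(short$mean_fkgl_complex, short$mean_fkgl_simple)
  }
  # longer complex sentences push complex FKGL up, every seed
  expect_true(all(gaps_long > gaps_short))
})

test_that("corpus statistics recover the target Zipf shift", {
  v <- vocab_spec(500, seed = 42)
  lex <- vocab_lexicon(v)
  st <- corpus_stats(generate_corpus(
    v, corpus_spec(n_pairs = 200, target_delta_z = 0.4, seed = 13)), lex)
  expect_lt(abs(st$mean_delta_z - 0.4), 0.15)
  expect_gt(st$band_fraction, 0.5)
  # a different target moves the recovered mean accordingly
  st2 <- corpus_stats(generate_corpus(
    v, corpus_spec(n_pairs = 100, target_delta_z = 1.2, seed = 13)), lex)
  expect_lt(abs(st2$mean_delta_z - 1.2), 0.2)
})

test_that("corpus_stats matches hand-computed values on tiny corpora", {
  lex <- tiny_lexicon()
  # identical sides: no shift, equal readability
  same <- paragraph_pair("p1", "The cat sat.", "The cat sat.")
  st <- corpus_stats(list(same), lex)
  expect_equal(st$mean_delta_z, 0)
  expect_equal(st$band_fraction, 0)
  expect_equal(st$mean_fkgl_complex, st$mean_fkgl_simple)

  # two pairs: report means equal hand averages of per-pair fkgl
  p1 <- paragraph_pair("a", "The cat sat.", "We use the cat.")
  p2 <- paragraph_pair("b", "We utilize the cat.", "Go on.")
  st2 <- corpus_stats(list(p1, p2), lex)
  hand_complex <- mean(c(fkgl(analyze_text("The cat sat.")),
                         fkgl(analyze_text("We utilize the cat."))))
  hand_simple <- mean(c(fkgl(analyze_text("We use the cat.")),
                        fkgl(analyze_text("Go on."))))
  expect_equal(st2$mean_fkgl_complex, hand_complex, tolerance = 1e-12)
  expect_equal(st2$mean_fkgl_simple, hand_simple, tolerance = 1e-12)
  expect_error(corpus_stats(list(), lex), "empty")
})

test_that("paragraph pairs convert to in-vocabulary token sequences", {
  v <- vocab_spec(80, seed = 7)
  pairs <- generate_corpus(v, training_corpus_spec(n_pairs = 10, seed = 2))
  model <- make_toy_policy(v$words$word, seed = 1, end_token = v$end_token)
  seqs <- pairs_to_sequences(pairs, model)
  expect_length(seqs, 10L)
  for (sq in seqs[1:3]) {
    expect_true(all(sq$source_ids >= 1 & sq$source_ids <= model$v))
    expect_true(all(sq$target_ids >= 1 & sq$target_ids <= model$v))
    # detokenized ids reproduce the tokenized text
    expect_equal(model$vocab[sq$source_ids],
                 tokenize_words(sq$source_text))
  }
})
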