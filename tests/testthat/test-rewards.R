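test_that("relevance reward is 1 on identical text and follows cosine", {
  expect_equal(relevance_reward("aspirin reduces pain",
                                "aspirin reduces pain"), 1)
  emb <- fixed_embedder(list(t1 = c(1, 0), t2 = c(0, 1), t3 = c(1, 1)))
  expect_equal(relevance_reward("t1", "t2", emb), 0) # orthogonal, clipped
  expect_equal(relevance_reward("t1", "t3", emb), 1 / sqrt(2),
               tolerance = 1e-6)
  # symmetric in which argument is target
  expect_equal(relevance_reward("t1", "t3", emb),
               relevance_reward("t3", "t1", emb))
  # negative cosine clips to zero
  embn <- fixed_embedder(list(p = c(1, 0), q = c(-1, 0)))
  expect_equal(relevance_reward("p", "q", embn), 0)
  embz <- fixed_embedder(list(z = c(0, 0), t1 = c(1, 0)))
  expect_error(relevance_reward("z", "t1", embz), "zero-norm")
})

test_that("hashed bag-of-words embedder is deterministic with fixed dimension", {
  emb <- hashed_bow_embedder(dimension = 32)
  v1 <- embed_text(emb, "patients improved rapidly")
  v2 <- embed_text(emb, "patients improved rapidly")
  expect_identical(v1, v2)
  expect_length(v1, 32L)
  # more shared vocabulary, higher similarity
  hi <- relevance_reward("the drug reduced pain fast",
                         "the drug reduced pain slowly", emb)
  lo <- relevance_reward("the drug reduced pain fast",
                         "unrelated words entirely different topic", emb)
  expect_gt(hi, lo)
})

test_that("fkgl reward is the clipped relative grade difference", {
  expect_equal(fkgl_reward_from_grades(12, 12), 0)
  expect_equal(fkgl_reward_from_grades(12, 6), 0.5)
  expect_equal(fkgl_reward_from_grades(12, 30), -1) # -1.5 clipped
  # sign flips when the simpler text changes role
  expect_gt(fkgl_reward_from_grades(12, 6), 0)
  expect_lt(fkgl_reward_from_grades(6, 12), 0)
  # end-to-end on texts: equal texts give zero
  expect_equal(fkgl_reward("Go on now.", "Go on now."), 0)
})

test_that("lexical stats use type-level set differences and the lexicon", {
  lex <- tiny_lexicon()
  same <- lexical_stats("we use", "we use", lex)
  expect_length(same$inserted_words, 0L)
  expect_length(same$deleted_words, 0L)
  expect_equal(same$delta_z, 0)

  st <- lexical_stats("we utilize", "we use", lex)
  expect_equal(st$inserted_words, "use")
  expect_equal(st$deleted_words, "utilize")
  expect_equal(st$z_inserted, 5)
  expect_equal(st$z_deleted, 2)
  expect_equal(st$delta_z, 3)

  # equal-frequency lexicon entries: insertions and deletions cancel
  eq <- lexical_stats("b c", "d sat", lex)
  expect_equal(eq$delta_z, 0, tolerance = 1e-12)
  # unknown words fall back to the oov default
  oov <- lexical_stats("we", "qqqxyzzy", lex)
  expect_equal(oov$z_inserted, 0)
})

test_that("lexical simplicity reward is a saturating ramp in delta_z", {
  expect_equal(lexical_simplicity_reward(0), 0)
  expect_equal(lexical_simplicity_reward(0.2), 0.5)
  expect_equal(lexical_simplicity_reward(0.4), 1)
  expect_equal(lexical_simplicity_reward(3), 1)
  expect_equal(lexical_simplicity_reward(-1), 0)
  # non-decreasing over a grid
  vals <- vapply(seq(-0.5, 1, by = 0.05), lexical_simplicity_reward,
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("combined reward is the weighted sum, linear in each weight", {
  expect_equal(combined_reward(0.5, 0.5, 0.5, reward_weights(0, 0, 0)), 0)
  expect_equal(combined_reward(0.8, -1, 1, reward_weights(1, 0, 0)), 0.8)
  expect_equal(combined_reward(0.6, 0.3, 0.9, reward_weights(1/3, 1/3, 1/3)),
               0.6, tolerance = 1e-12)
  expect_error(reward_weights(-0.1, 0.5, 0.5), "non-negative")
  # slope in alpha equals the cosine component
  r <- c(0.37, -0.2, 0.81)
  f <- function(a) combined_reward(r[1], r[2], r[3], reward_weights(a, 2, 3))
  expect_equal(f(1.5) - f(0.5), r[1], tolerance = 1e-12)
})

test_that("rewards are pure: identical inputs give identical outputs", {
  lex <- tiny_lexicon()
  b1 <- reward_breakdown("we utilize drugs", "we use drugs", "we use drugs",
                         lexicon = lex)
  b2 <- reward_breakdown("we utilize drugs", "we use drugs", "we use drugs",
                         lexicon = lex)
  expect_identical(b1, b2)
})

test_that("score_generation agrees with the pure reward_breakdown path", {
  lex <- tiny_lexicon()
  cfg <- reward_config(lex)
  set.seed(5)
  words <- c("use", "utilize", "we", "cat", "sat", "the")
  for (i in 1:10) {
    rnd <- function() paste(sample(words, sample(2:6, 1), replace = TRUE),
                            collapse = " ")
    s <- rnd(); t <- rnd(); g <- rnd()
    a <- score_generation(s, t, g, cfg)
    b <- reward_breakdown(s, t, g, lexicon = lex)
    expect_equal(a$r_cosine, b$r_cosine, tolerance = 1e-12)
    expect_equal(a$r_flesch, b$r_flesch, tolerance = 1e-12)
    expect_equal(a$r_lexical, b$r_lexical, tolerance = 1e-12)
    expect_equal(a$total, b$total, tolerance = 1e-12)
  }
  # empty generation: all-zero rewards by convention
  z <- score_generation("we utilize", "we use", "", cfg)
  expect_equal(z$total, 0)
})

test_that("lexicon round-trips through the two-column text format", {
  lex <- tiny_lexicon()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# word zipf", paste(names(lex$table), lex$table)), path)
  lex2 <- read_lexicon(path)
  expect_equal(zipf_frequency(lex2, c("use", "we", "missing")),
               c(5, 6, 0))
})
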