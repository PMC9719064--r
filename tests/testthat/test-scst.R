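test_that("token log-probabilities normalize at every step", {
  m <- tiny_policy()
  for (prefix in list(integer(0), 1L, c(2L, 3L))) {
    lp <- token_logprobs(m, c(1L, 2L), prefix)
    expect_equal(log(sum(exp(lp))), 0, tolerance = 1e-12)
  }
  expect_error(token_logprobs(m, c(1L, 99L)), "vocabulary")
})

test_that("mle_loss matches closed forms on degenerate models", {
  # zero parameters = uniform distribution over the vocabulary
  m <- tiny_policy()
  m <- policy_set_params(m, rep(0, length(policy_get_params(m))))
  v <- m$v # 5: four tokens plus the end token
  expect_equal(mle_loss(m, sequence_pair(1L, c(1L, 2L))), 2 * log(v),
               tolerance = 1e-12)
  expect_equal(mle_loss(m, sequence_pair(1L, 3L)), log(v),
               tolerance = 1e-12)
  # two-token vocabulary: uniform probability 1/2
  m2 <- make_toy_policy(c("a"), embedding_dim = 2, seed = 1)
  m2 <- policy_set_params(m2, rep(0, length(policy_get_params(m2))))
  expect_equal(mle_loss(m2, sequence_pair(1L, 1L)), log(2),
               tolerance = 1e-12)
  expect_error(mle_loss(m, sequence_pair(1L, 99L)), "vocabulary")
})

test_that("pg_loss sign convention promotes above-baseline samples", {
  ro <- structure(
    list(tokens = c(1L, 2L), per_token_logprob = c(-1, -1),
         mode = "sampled", seed = 1L, text = "a b", reward = 1,
         breakdown = NULL, weights = c(1, 1, 1) / 3),
    class = "rollout"
  )
  expect_equal(pg_loss(ro, baseline_reward = 1), 0)
  expect_equal(pg_loss(ro, baseline_reward = 0), 1) # -(-1) * 1
  ro$reward <- 0
  expect_equal(pg_loss(ro, baseline_reward = 1), -1) # -(-1) * (-1)
  ro$reward <- 0.4
  ro$per_token_logprob <- c(-0.5, -0.5)
  expect_equal(pg_loss(ro, baseline_reward = 0), 0.2)
  expect_equal(pg_loss(ro, baseline_reward = 0.8), -0.2)
})

test_that("scst_loss uses the greedy reward as baseline and checks weights", {
  mk <- function(reward, weights = c(1, 1, 1) / 3) {
    structure(
      list(tokens = 1L, per_token_logprob = -0.5, mode = "sampled",
           seed = 1L, text = "a", reward = reward, breakdown = NULL,
           weights = weights),
      class = "rollout"
    )
  }
  expect_equal(scst_loss(rollout_pair(mk(0.7), mk(0.7))), 0)
  expect_equal(scst_loss(rollout_pair(mk(0.9), mk(0.5))), 0.2)
  expect_equal(scst_loss(rollout_pair(mk(0.1), mk(0.5))), -0.2)
  expect_error(rollout_pair(mk(0.9), mk(0.5, weights = c(1, 0, 0))),
               "weights")
})

test_that("total_loss is the printed convex combination with endpoints", {
  expect_equal(total_loss(2, 4, 0), 4)
  expect_equal(total_loss(2, 4, 1), 2)
  expect_equal(total_loss(2, 4, 0.5), 3)
  set.seed(11)
  for (i in 1:20) {
    lpg <- rnorm(1); lml <- abs(rnorm(1)); g <- runif(1)
    expect_equal(total_loss(lpg, lml, g), g * lpg + (1 - g) * lml,
                 tolerance = 1e-12)
    expect_equal(total_loss(lpg, lml, 0), lml)
    expect_equal(total_loss(lpg, lml, 1), lpg)
  }
  expect_error(total_loss(1, 1, 1.2), "gamma")
  expect_error(total_loss(1, 1, -0.1), "gamma")
})

test_that("greedy decoding is deterministic and breaks ties at the lowest id", {
  m <- tiny_policy()
  r1 <- greedy_decode(m, c(1L, 2L), 10)
  r2 <- greedy_decode(m, c(1L, 2L), 10)
  expect_identical(r1$tokens, r2$tokens)
  expect_identical(r1$per_token_logprob, r2$per_token_logprob)
  expect_equal(length(r1$tokens), length(r1$per_token_logprob))
  # all-equal logits: every step is a tie, the lowest id must win;
  # token 1 is not the end token, so decoding runs to max_len
  mu <- policy_set_params(m, rep(0, length(policy_get_params(m))))
  ru <- greedy_decode(mu, 1L, 4)
  expect_equal(ru$tokens, rep(1L, 4))
})

test_that("sampled decoding is seed-reproducible and leaves the RNG alone", {
  m <- tiny_policy()
  s1 <- sample_decode(m, c(1L, 2L), 15, seed = 9)
  s2 <- sample_decode(m, c(1L, 2L), 15, seed = 9)
  expect_identical(s1$tokens, s2$tokens)
  expect_equal(s1$seed, 9)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(sample_decode(m, 1L, 10, seed = 4))
  expect_equal(runif(1), before) # caller RNG untouched
})

test_that("sampling frequencies match the model distribution", {
  # uniform two-token model: first draw should be ~Bernoulli(1/2)
  m <- make_toy_policy(c("a"), embedding_dim = 2, seed = 1)
  m <- policy_set_params(m, rep(0, length(policy_get_params(m))))
  firsts <- vapply(1:4000, function(s)
    sample_decode(m, 1L, 1, seed = s)$tokens[1], integer(1))
  frac <- mean(firsts == 1L)
  expect_gt(frac, 0.47)
  expect_lt(frac, 0.53)
})

test_that("analytic gradients match central finite differences", {
  m <- tiny_policy(seed = 4)
  pair <- sequence_pair(c(1L, 3L, 2L), c(2L, 1L, 4L, 2L))
  theta <- policy_get_params(m)
  set.seed(21)
  idx <- sample(length(theta), 6)

  # mle_loss
  ga <- flat_grad(.accumulate_nll_grad(m, .zero_grad(m), pair$source_ids,
                                       pair$target_ids, 1)$grad)
  fd <- fd_gradient(function(th) mle_loss(policy_set_params(m, th), pair),
                    theta, idx)
  expect_lt(max(abs(fd - ga[idx])), 1e-5)

  # scst surrogate: -mean logprob of a fixed sampled sequence x advantage
  sampled <- sample_decode(m, pair$source_ids, 8, seed = 3)
  adv <- 0.37
  n <- length(sampled$tokens)
  ga2 <- flat_grad(.accumulate_nll_grad(m, .zero_grad(m), pair$source_ids,
                                        sampled$tokens, adv / n)$grad)
  f2 <- function(th) {
    mm <- policy_set_params(m, th)
    lp <- .forced_pass(mm, pair$source_ids, sampled$tokens)$logp
    -mean(lp) * adv
  }
  fd2 <- fd_gradient(f2, theta, idx)
  expect_lt(max(abs(fd2 - ga2[idx])), 1e-5)
})

test_that("one SCST step raises the probability of a promoted sample", {
  lex <- tiny_lexicon()
  cfg <- reward_config(lex)
  m <- make_toy_policy(c("use", "utilize", "we", "cat", "sat"),
                       embedding_dim = 4, seed = 3)
  pair <- sequence_pair(c(2L, 3L), c(1L, 3L),
                        source_text = "we utilize",
                        reference_text = "we use")
  tc <- training_config(gamma = 1, rl_learning_rate = 1, seed = 1)
  checked <- 0L
  for (ep in 1:60) {
    internal_seed <- simplerl:::.rollout_seed(tc$seed, ep, 1L)
    gr <- score_rollout(greedy_decode(m, pair$source_ids, 10), m, pair, cfg)
    sm <- score_rollout(sample_decode(m, pair$source_ids, 10,
                                      seed = internal_seed), m, pair, cfg)
    adv <- sm$reward - gr$reward
    if (abs(adv) < 0.02) next
    before <- sum(.forced_pass(m, pair$source_ids, sm$tokens)$logp)
    st <- train_step(m, list(pair), cfg, tc, gamma = 1, epoch = ep)
    after <- sum(.forced_pass(st$model, pair$source_ids, sm$tokens)$logp)
    if (adv > 0) expect_gt(after, before) else expect_lt(after, before)
    checked <- checked + 1L
    if (checked >= 5L) break
  }
  expect_gte(checked, 3L)
})

test_that("degenerate training configs leave the model unchanged", {
  lex <- tiny_lexicon()
  cfg <- reward_config(lex)
  m <- tiny_policy(seed = 6)
  pair <- sequence_pair(c(1L, 2L), c(2L, 3L),
                        source_text = "a b", reference_text = "b c")

  # learning rate 0: no movement
  tc0 <- training_config(learning_rate = 0, rl_learning_rate = 0, seed = 1)
  st <- train_step(m, list(pair), cfg, tc0, gamma = 0.5, epoch = 1)
  expect_equal(policy_get_params(st$model), policy_get_params(m))

  # gamma 0 step equals a pure-MLE step on the same batch
  tc <- training_config(learning_rate = 0.3, seed = 1)
  a <- train_step(m, list(pair), cfg, tc, gamma = 0, epoch = 1)
  grad <- simplerl:::.accumulate_nll_grad(
    m, simplerl:::.zero_grad(m), pair$source_ids,
    c(pair$target_ids, m$end_id), 1
  )$grad
  manual <- simplerl:::.apply_grad(m, grad, 0.3)
  expect_equal(policy_get_params(a$model), policy_get_params(manual),
               tolerance = 1e-12)

  # epochs = 0: empty trace, untouched model
  fit <- train(m, list(pair), cfg,
               training_config(mle_epochs = 0, rl_epochs = 0, seed = 1))
  expect_equal(nrow(fit$trace), 0L)
  expect_equal(policy_get_params(fit$model), policy_get_params(m))
})

test_that("a zero-advantage pure-RL step applies zero gradient", {
  lex <- tiny_lexicon()
  cfg <- reward_config(lex)
  # near-deterministic policy: huge logits pin one path, so the sampled
  # rollout equals the greedy rollout and the advantage is exactly zero
  m <- make_toy_policy(c("use", "we"), embedding_dim = 2, seed = 1)
  th <- policy_get_params(m) * 0
  m <- policy_set_params(m, th)
  m$params$b <- c(50, 0, 0) # always emit "use", never end early
  pair <- sequence_pair(2L, 1L, source_text = "we", reference_text = "use")
  tc <- training_config(gamma = 1, rl_learning_rate = 5,
                        max_decode_length = 3, seed = 1)
  st <- train_step(m, list(pair), cfg, tc, gamma = 1, epoch = 1)
  expect_equal(policy_get_params(st$model), policy_get_params(m),
               tolerance = 1e-9)
})

test_that("train is bit-reproducible from its seed", {
  setup <- toy_training_setup(n_pairs = 8, seed = 3, vocab_size = 20)
  tc <- training_config(mle_epochs = 2, rl_epochs = 2, batch_size = 4,
                        seed = 3)
  f1 <- train(setup$model, setup$sequences, setup$reward_cfg, tc)
  f2 <- train(setup$model, setup$sequences, setup$reward_cfg, tc)
  expect_identical(f1$trace, f2$trace)
  expect_identical(policy_get_params(f1$model), policy_get_params(f2$model))
})

test_that("checkpoints round-trip parameters, vocabulary and seed", {
  m <- tiny_policy(seed = 8)
  path <- withr::local_tempfile(fileext = ".txt")
  write_checkpoint(m, path)
  m2 <- read_checkpoint(path)
  expect_identical(m2$vocab, m$vocab)
  expect_equal(policy_get_params(m2), policy_get_params(m),
               tolerance = 1e-15)
  expect_equal(m2$end_id, m$end_id)
  lp1 <- token_logprobs(m, c(1L, 2L), 3L)
  lp2 <- token_logprobs(m2, c(1L, 2L), 3L)
  expect_equal(lp1, lp2, tolerance = 1e-14)
})
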