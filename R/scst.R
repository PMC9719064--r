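# Training objective: maximum-likelihood loss, policy-gradient loss with
# a baseline, the self-critical instantiation (greedy-decode baseline),
# the mixed loss, and the two-phase training loop.

#' Construct a source/target token-id pair
#'
#' The unit of training data. Texts are optional; when absent they are
#' detokenized from the ids at reward-scoring time.
#'
#' @param source_ids,target_ids Non-empty integer token-id vectors.
#' @param source_text Complex source text S (optional).
#' @param reference_text Reference simple text T (optional).
#' @return An object of class `sequence_pair`.
#' @export
sequence_pair <- function(source_ids, target_ids,
                          source_text = NULL, reference_text = NULL) {
  stopifnot(length(source_ids) > 0L, length(target_ids) > 0L)
  structure(
    list(source_ids = as.integer(source_ids),
         target_ids = as.integer(target_ids),
         source_text = source_text, reference_text = reference_text),
    class = "sequence_pair"
  )
}

#' Reward-scoring configuration for training and evaluation
#'
#' Bundles everything needed to score a generated text against its
#' (source, target) pair: component weights, the embedding model for the
#' relevance reward, the frequency lexicon for the lexical reward, the
#' FKGL coefficient preset, and the lexical-ramp saturation.
#'
#' @param lexicon A `freq_lexicon`.
#' @param weights A `reward_weights`.
#' @param embedder An `embedding_model`.
#' @param coefficients FKGL preset; see [fkgl_coefficients()].
#' @param saturation Lexical-ramp saturation (default 0.4).
#' @return An object of class `reward_config`.
#' @export
reward_config <- function(lexicon, weights = reward_weights(),
                          embedder = hashed_bow_embedder(),
                          coefficients = "standard", saturation = 0.4) {
  stopifnot(inherits(lexicon, "freq_lexicon"),
            inherits(weights, "reward_weights"),
            inherits(embedder, "embedding_model"))
  structure(
    list(lexicon = lexicon, weights = weights, embedder = embedder,
         coefficients = coefficients, saturation = saturation,
         cache = new.env(parent = emptyenv())),
    class = "reward_config"
  )
}

# Memoize target/source-side quantities that are reused across the many
# scorings of one training run (pure values, keyed by text).
.cached <- function(cache, key, expr) {
  if (!is.null(cache[[key]])) return(cache[[key]])
  val <- expr
  cache[[key]] <- val
  val
}

#' Score one generated text against its pair
#'
#' Computes the three rewards of a generation G with target T and source
#' S under a `reward_config`. An empty generation receives all-zero
#' rewards (no reward without output).
#'
#' @param source_text,target_text,generated_text Character scalars.
#' @param config A `reward_config`.
#' @return A `reward_breakdown`.
#' @export
score_generation <- function(source_text, target_text, generated_text,
                             config) {
  stopifnot(inherits(config, "reward_config"))
  if (!nzchar(trimws(generated_text))) {
    out <- list(r_cosine = 0, r_flesch = 0, r_lexical = 0, total = 0,
                weights = config$weights)
    class(out) <- "reward_breakdown"
    return(out)
  }
  # Same math as reward_breakdown(), with two training-oriented
  # differences: target/source-side quantities are memoized across the
  # many scorings of a run, and a generation whose embedding has zero
  # norm (hash-sign cancellation) gets relevance 0 rather than an error
  # - training must be total.
  cache <- config$cache
  et <- .cached(cache, paste0("emb\x01", target_text),
                embed_text(config$embedder, target_text))
  eg <- embed_text(config$embedder, generated_text)
  nt <- sqrt(sum(et^2))
  ng <- sqrt(sum(eg^2))
  rc <- if (nt == 0 || ng == 0) 0 else {
    min(max(sum(et * eg) / (nt * ng), 0), 1)
  }
  rt <- .cached(cache, paste0("fk\x01", target_text),
                fkgl(analyze_text(target_text), config$coefficients))
  rf <- fkgl_reward_from_grades(
    rt, fkgl(analyze_text(generated_text), config$coefficients)
  )
  types_s <- .cached(cache, paste0("types\x01", source_text),
                     word_types(source_text))
  g <- word_types(generated_text)
  ins <- setdiff(g, types_s)
  del <- setdiff(types_s, g)
  z_ins <- if (length(ins)) mean(zipf_frequency(config$lexicon, ins)) else 0
  z_del <- if (length(del)) mean(zipf_frequency(config$lexicon, del)) else 0
  rl <- lexical_simplicity_reward(z_ins - z_del, config$saturation)
  out <- list(
    r_cosine = rc, r_flesch = rf, r_lexical = rl,
    total = combined_reward(rc, rf, rl, config$weights),
    weights = config$weights
  )
  class(out) <- "reward_breakdown"
  out
}

# Losses -------------------------------------------------------------------

#' Maximum-likelihood (negative log-likelihood) loss
#'
#' Negative sum over target positions of `log p(y_t | y_<t, x)` under the
#' model; always >= 0. The target is scored exactly as given (append the
#' end token yourself if the model should learn to stop).
#'
#' @param model A `toy_policy` (or any model honoring the same contract).
#' @param pair A `sequence_pair`.
#' @return Non-negative scalar loss in nats.
#' @export
mle_loss <- function(model, pair) {
  .validate_ids(model, pair$source_ids)
  .validate_ids(model, pair$target_ids)
  pass <- .forced_pass(model, pair$source_ids, pair$target_ids)
  -sum(pass$logp)
}

#' Policy-gradient loss with a baseline
#'
#' `-(mean per-token log-probability) * (reward - baseline)`. Minimizing
#' this increases the probability of sampled sequences whose reward
#' exceeds the baseline and suppresses those below it.
#'
#' @param sampled A scored `rollout` (see [sample_decode()] and
#'   [score_rollout()]).
#' @param baseline_reward Scalar baseline b.
#' @return Scalar loss.
#' @export
pg_loss <- function(sampled, baseline_reward) {
  stopifnot(inherits(sampled, "rollout"),
            length(sampled$per_token_logprob) > 0L,
            !is.null(sampled$reward))
  -mean(sampled$per_token_logprob) * (sampled$reward - baseline_reward)
}

#' Self-critical sequence-training loss
#'
#' The policy-gradient loss with the reward of the model's own greedy
#' decode as the baseline: the sampled rollout is promoted exactly when
#' it out-scores what the current policy would produce greedily.
#'
#' @param pair A `rollout_pair` (see [rollout_pair()]).
#' @return Scalar loss.
#' @export
scst_loss <- function(pair) {
  stopifnot(inherits(pair, "rollout_pair"))
  pg_loss(pair$sampled, baseline_reward = pair$greedy$reward)
}

#' Mixed training loss
#'
#' `gamma * lpg + (1 - gamma) * lml`: a convex combination of the
#' policy-gradient and maximum-likelihood losses.
#'
#' @param lpg,lml Scalar losses.
#' @param gamma Mixing scalar in `[0, 1]`.
#' @return Scalar loss.
#' @export
total_loss <- function(lpg, lml, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    stop("total_loss(): gamma must lie in [0, 1]", call. = FALSE)
  }
  gamma * lpg + (1 - gamma) * lml
}

# Decoding -----------------------------------------------------------------

.new_rollout <- function(model, tokens, logprobs, mode, seed = NULL) {
  structure(
    list(tokens = tokens, per_token_logprob = logprobs, mode = mode,
         seed = seed, text = policy_detokenize(model, tokens),
         reward = NULL, breakdown = NULL, weights = NULL),
    class = "rollout"
  )
}

#' Greedy decoding
#'
#' Emits the argmax token at every step (ties broken by the lowest token
#' id) until the end token or `max_len`; deterministic.
#'
#' @param model A `toy_policy`.
#' @param source_ids Integer source token ids.
#' @param max_len Maximum generated length, >= 1.
#' @return A `rollout` with `mode = "greedy"`.
#' @export
greedy_decode <- function(model, source_ids, max_len = 20L) {
  stopifnot(max_len >= 1L)
  .validate_ids(model, source_ids)
  base <- .logit_base(model, source_ids)
  tokens <- integer(0)
  logprobs <- numeric(0)
  prev <- model$v + 1L # start column
  for (t in seq_len(max_len)) {
    lp <- .log_softmax(base + model$params$U[, prev] +
                         model$params$Q[, min(t, model$p)])
    tok <- which.max(lp) # first maximum = lowest id on ties
    tokens <- c(tokens, tok)
    logprobs <- c(logprobs, lp[tok])
    if (tok == model$end_id) break
    prev <- tok
  }
  .new_rollout(model, tokens, logprobs, "greedy")
}

#' Multinomial sampling
#'
#' Draws each token from the model's predictive distribution at
#' temperature 1 (no truncation) until the end token or `max_len`. The
#' seed is recorded in the rollout; the caller's RNG state is untouched.
#'
#' @inheritParams greedy_decode
#' @param seed Integer seed; the same seed reproduces the same rollout.
#' @return A `rollout` with `mode = "sampled"`.
#' @export
sample_decode <- function(model, source_ids, max_len = 20L, seed = 1L) {
  stopifnot(max_len >= 1L)
  .validate_ids(model, source_ids)
  base <- .logit_base(model, source_ids)
  with_preserved_rng({
    set.seed(seed)
    tokens <- integer(0)
    logprobs <- numeric(0)
    prev <- model$v + 1L # start column
    for (t in seq_len(max_len)) {
      lp <- .log_softmax(base + model$params$U[, prev] +
                           model$params$Q[, min(t, model$p)])
      tok <- sample.int(model$v, 1L, prob = exp(lp))
      tokens <- c(tokens, tok)
      logprobs <- c(logprobs, lp[tok])
      if (tok == model$end_id) break
      prev <- tok
    }
    .new_rollout(model, tokens, logprobs, "sampled", seed = seed)
  })
}

#' Score a rollout's generated text
#'
#' Fills `reward`, `breakdown` and the weight vector used, against the
#' pair's source (S) and reference (T) texts.
#'
#' @param rollout A `rollout`.
#' @param model The `toy_policy` that produced it (for detokenization).
#' @param pair The `sequence_pair` it was generated for.
#' @param config A `reward_config`.
#' @return The scored `rollout`.
#' @export
score_rollout <- function(rollout, model, pair, config) {
  src <- pair$source_text %||% policy_detokenize(model, pair$source_ids)
  ref <- pair$reference_text %||% policy_detokenize(model, pair$target_ids)
  bd <- score_generation(src, ref, rollout$text, config)
  rollout$breakdown <- bd
  rollout$reward <- bd$total
  rollout$weights <- unlist(config$weights[c("alpha", "beta", "d")])
  rollout
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pair a sampled rollout with its greedy baseline
#'
#' @param sampled,greedy Scored `rollout`s from the same model, pair and
#'   reward configuration.
#' @return An object of class `rollout_pair` with the advantage
#'   `sampled$reward - greedy$reward`.
#' @export
rollout_pair <- function(sampled, greedy) {
  stopifnot(inherits(sampled, "rollout"), inherits(greedy, "rollout"))
  if (is.null(sampled$reward) || is.null(greedy$reward)) {
    stop("rollout_pair(): both rollouts must be scored first", call. = FALSE)
  }
  if (!isTRUE(all.equal(sampled$weights, greedy$weights))) {
    stop("rollout_pair(): rollouts were scored with different reward weights",
         call. = FALSE)
  }
  structure(
    list(sampled = sampled, greedy = greedy,
         advantage = sampled$reward - greedy$reward),
    class = "rollout_pair"
  )
}

# Training -----------------------------------------------------------------

#' Training configuration
#'
#' @param gamma Mixing scalar in `[0, 1]` for the RL phase (default
#'   0.98: mostly policy gradient with a small MLE anchor; gamma = 1
#'   maximizes reward fastest but collapses to content-free outputs,
#'   the failure mode the mixed loss exists to prevent).
#' @param learning_rate SGD step size of the pure-MLE phase (and of any
#'   `gamma = 0` run).
#' @param rl_learning_rate SGD step size of the mixed-loss phase. The
#'   policy-gradient signal is roughly an order of magnitude smaller
#'   than the MLE signal (advantages are fractions of a unit-scale
#'   reward, spread over the rollout's tokens), so the RL phase uses a
#'   correspondingly larger step.
#' @param mle_epochs Epochs of the pure maximum-likelihood phase.
#' @param rl_epochs Epochs of the mixed-loss phase.
#' @param batch_size Pairs per gradient update.
#' @param max_decode_length Rollout length cap.
#' @param seed Integer seed governing every random draw of the run.
#' @return An object of class `training_config`.
#' @export
training_config <- function(gamma = 0.98, learning_rate = 0.5,
                            rl_learning_rate = 10,
                            mle_epochs = 5L, rl_epochs = 100L,
                            batch_size = 8L, max_decode_length = 20L,
                            seed = 1L) {
  stopifnot(gamma >= 0, gamma <= 1, learning_rate >= 0,
            rl_learning_rate >= 0,
            mle_epochs >= 0, rl_epochs >= 0, batch_size >= 1,
            max_decode_length >= 1)
  structure(
    list(gamma = gamma, learning_rate = learning_rate,
         rl_learning_rate = rl_learning_rate,
         mle_epochs = as.integer(mle_epochs),
         rl_epochs = as.integer(rl_epochs),
         batch_size = as.integer(batch_size),
         max_decode_length = as.integer(max_decode_length),
         seed = as.integer(seed)),
    class = "training_config"
  )
}

# Deterministic per-rollout seed below 2^31.
.rollout_seed <- function(seed, epoch, index) {
  as.integer((as.numeric(seed) * 100003 + epoch * 10007 + index) %% 2147483629 + 1)
}

#' One gradient step on a batch
#'
#' Accumulates the gradient of `gamma * Lpg + (1 - gamma) * Lml` over the
#' batch (per-sample advantage, greedy self-critical baseline), averages
#' it, and applies one plain-SGD update.
#'
#' @param model A `toy_policy`.
#' @param batch List of `sequence_pair`s (non-empty).
#' @param reward_cfg A `reward_config`.
#' @param config A `training_config`; its `gamma` is used unless
#'   `gamma` is given.
#' @param gamma Optional override of the mixing scalar for this step.
#' @param epoch Epoch number, used only to derive sampling seeds.
#' @return List with `model` (updated), `lml`, `lpg` (batch means), and
#'   `rewards` (mean sampled-rollout component rewards under the
#'   pre-update policy, or zeros when `gamma = 0`).
#' @export
train_step <- function(model, batch, reward_cfg, config,
                       gamma = config$gamma, epoch = 1L) {
  stopifnot(length(batch) > 0L)
  grad <- .zero_grad(model)
  lml_sum <- 0
  lpg_sum <- 0
  rsum <- c(r_cosine = 0, r_flesch = 0, r_lexical = 0, total = 0)
  for (i in seq_along(batch)) {
    pair <- batch[[i]]
    y <- c(pair$target_ids, model$end_id)
    acc <- .accumulate_nll_grad(model, grad, pair$source_ids, y,
                                weights = 1 - gamma)
    grad <- acc$grad
    lml_sum <- lml_sum - sum(acc$logp)
    if (gamma > 0) {
      greedy <- greedy_decode(model, pair$source_ids,
                              config$max_decode_length)
      greedy <- score_rollout(greedy, model, pair, reward_cfg)
      sampled <- sample_decode(model, pair$source_ids,
                               config$max_decode_length,
                               seed = .rollout_seed(config$seed, epoch, i))
      sampled <- score_rollout(sampled, model, pair, reward_cfg)
      rp <- rollout_pair(sampled, greedy)
      lpg_i <- scst_loss(rp)
      lpg_sum <- lpg_sum + lpg_i
      n <- length(sampled$tokens)
      if (rp$advantage != 0) {
        acc2 <- .accumulate_nll_grad(model, grad, pair$source_ids,
                                     sampled$tokens,
                                     weights = gamma * rp$advantage / n)
        grad <- acc2$grad
      }
      bd <- sampled$breakdown
      rsum <- rsum + c(bd$r_cosine, bd$r_flesch, bd$r_lexical, bd$total)
    }
  }
  nb <- length(batch)
  lml <- lml_sum / nb
  lpg <- lpg_sum / nb
  if (!is.finite(lml) || !is.finite(lpg)) {
    stop(sprintf("train_step(): non-finite loss (lml = %g, lpg = %g)",
                 lml, lpg), call. = FALSE)
  }
  grad <- lapply(grad, function(g) g / nb)
  lr <- if (gamma > 0) config$rl_learning_rate else config$learning_rate
  model <- .apply_grad(model, grad, lr)
  list(model = model, lml = lml, lpg = lpg, rewards = rsum / nb)
}

#' Evaluate a policy over a corpus
#'
#' Decodes every pair (greedy, or one seeded sampled rollout per pair),
#' scores the generations, and returns mean component rewards plus the
#' mean MLE loss on the references. Greedy mode measures deployment
#' quality; sampled mode estimates the expected reward the policy
#' gradient maximizes.
#'
#' @param model A `toy_policy`.
#' @param corpus List of `sequence_pair`s.
#' @param reward_cfg A `reward_config`.
#' @param max_len Decode length cap.
#' @param mode `"greedy"` or `"sampled"`.
#' @param seed,epoch Seed material for sampled mode (per-pair seeds are
#'   derived from both, as in training).
#' @return Named list: `lml`, `r_cosine`, `r_flesch`, `r_lexical`,
#'   `total`.
#' @export
evaluate_policy <- function(model, corpus, reward_cfg, max_len = 20L,
                            mode = c("greedy", "sampled"),
                            seed = 1L, epoch = 0L) {
  stopifnot(length(corpus) > 0L)
  mode <- match.arg(mode)
  lml <- 0
  rsum <- c(r_cosine = 0, r_flesch = 0, r_lexical = 0, total = 0)
  for (i in seq_along(corpus)) {
    pair <- corpus[[i]]
    lml <- lml + mle_loss(model, sequence_pair(pair$source_ids,
                                               c(pair$target_ids, model$end_id)))
    g <- if (mode == "greedy") {
      greedy_decode(model, pair$source_ids, max_len)
    } else {
      sample_decode(model, pair$source_ids, max_len,
                    seed = .rollout_seed(seed, epoch, i))
    }
    g <- score_rollout(g, model, pair, reward_cfg)
    bd <- g$breakdown
    rsum <- rsum + c(bd$r_cosine, bd$r_flesch, bd$r_lexical, bd$total)
  }
  n <- length(corpus)
  c(list(lml = lml / n), as.list(rsum / n))
}

#' Two-phase training loop
#'
#' First `mle_epochs` epochs of pure maximum-likelihood training
#' (`gamma = 0`), then `rl_epochs` epochs of the mixed loss with the
#' configured `gamma` and the self-critical baseline. Fully reproducible
#' from `config$seed`. The trace records, per epoch, the batch-mean
#' losses; reward columns are the mean sampled-rollout rewards observed
#' during the epoch's RL steps (NA for pure-MLE epochs) - the running
#' estimate of the expected reward the policy gradient maximizes. Row
#' `epoch = 0` and the final row are seeded sampled evaluations of the
#' fixed initial and final policies, so the two are directly
#' comparable. Greedy (deployment) quality is available separately via
#' [evaluate_policy()].
#'
#' @param model A `toy_policy`.
#' @param corpus Non-empty list of `sequence_pair`s.
#' @param reward_cfg A `reward_config`.
#' @param config A `training_config`.
#' @return List with `model` (trained) and `trace` (data frame with
#'   columns epoch, phase, lml, lpg, r_cosine, r_flesch, r_lexical,
#'   total).
#' @export
train <- function(model, corpus, reward_cfg, config = training_config()) {
  stopifnot(length(corpus) > 0L)
  n_epochs <- config$mle_epochs + config$rl_epochs
  empty <- data.frame(
    epoch = integer(0), phase = character(0), lml = numeric(0),
    lpg = numeric(0), r_cosine = numeric(0), r_flesch = numeric(0),
    r_lexical = numeric(0), total = numeric(0)
  )
  if (n_epochs == 0L) return(list(model = model, trace = empty))
  bi <- ceiling(seq_along(corpus) / config$batch_size)
  batches <- split(corpus, factor(bi, levels = unique(bi)))
  ev0 <- evaluate_policy(model, corpus, reward_cfg,
                         config$max_decode_length, mode = "sampled",
                         seed = config$seed, epoch = 0L)
  rows <- list(data.frame(
    epoch = 0L, phase = "init", lml = ev0$lml, lpg = 0,
    r_cosine = ev0$r_cosine, r_flesch = ev0$r_flesch,
    r_lexical = ev0$r_lexical, total = ev0$total
  ))
  for (epoch in seq_len(n_epochs)) {
    in_mle_phase <- epoch <= config$mle_epochs
    gamma <- if (in_mle_phase) 0 else config$gamma
    lml_m <- 0
    lpg_m <- 0
    rw_m <- c(r_cosine = 0, r_flesch = 0, r_lexical = 0, total = 0)
    for (b in batches) {
      step <- train_step(model, b, reward_cfg, config,
                         gamma = gamma, epoch = epoch)
      model <- step$model
      lml_m <- lml_m + step$lml
      lpg_m <- lpg_m + step$lpg
      rw_m <- rw_m + step$rewards * length(b)
    }
    rw_m <- rw_m / length(corpus)
    if (gamma == 0) rw_m[] <- NA_real_
    if (epoch == n_epochs) {
      # evaluate the final model with the same estimator as epoch 0
      ev <- evaluate_policy(model, corpus, reward_cfg,
                            config$max_decode_length, mode = "sampled",
                            seed = config$seed, epoch = n_epochs + 1L)
      rw_m <- c(r_cosine = ev$r_cosine, r_flesch = ev$r_flesch,
                r_lexical = ev$r_lexical, total = ev$total)
    }
    rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, phase = if (in_mle_phase) "mle" else "rl",
      lml = lml_m / length(batches), lpg = lpg_m / length(batches),
      r_cosine = rw_m[["r_cosine"]], r_flesch = rw_m[["r_flesch"]],
      r_lexical = rw_m[["r_lexical"]], total = rw_m[["total"]]
    )
  }
  list(model = model, trace = do.call(rbind, rows))
}

#' Write a training trace as CSV
#'
#' @param trace Trace data frame from [train()].
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
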