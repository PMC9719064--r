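# A small parametric conditional generator with closed-form gradients.
#
# This is the desk-scale policy used to exercise the training objective:
# a per-step softmax over the vocabulary whose logits combine (i) a
# learned bias, (ii) a low-rank map of the source's bag-of-tokens
# features, and (iii) a previous-token transition term:
#
#   logits_t = b + A (B phi(x)) + U[, y_{t-1}] + Q[, min(t, P)]
#
# with phi(x) the L1-normalized bag-of-token counts of the source, a
# dedicated start column of U at the first step, and Q a per-position
# term (positions beyond slot P share the last column) that lets the
# policy learn where to stop. Any sequence model satisfying the
# same contract (token_logprobs / trainable parameters) can be trained by
# the same loop; a transformer attaches as an adapter, it is not
# implemented here.

#' Create a toy conditional generator
#'
#' @param vocab Character vector of unique token surface forms; must
#'   contain `end_token` and at least one other token.
#' @param embedding_dim Rank of the source-feature map (default 16).
#' @param position_slots Number of distinct decoding positions with
#'   their own logit column (default 12; later positions share the
#'   last).
#' @param seed Integer seed for the random initial parameters.
#' @param end_token Surface form of the end-of-sequence token (default
#'   `"</s>"`); appended to `vocab` if absent.
#' @return An object of class `toy_policy`.
#' @export
make_toy_policy <- function(vocab, embedding_dim = 16L, seed = 1L,
                            end_token = "</s>", position_slots = 12L) {
  vocab <- as.character(vocab)
  if (!end_token %in% vocab) vocab <- c(vocab, end_token)
  if (anyDuplicated(vocab)) {
    stop("make_toy_policy(): vocabulary tokens must be unique", call. = FALSE)
  }
  if (length(vocab) < 2L) {
    stop("make_toy_policy(): need at least 2 tokens including the end token",
         call. = FALSE)
  }
  v <- length(vocab)
  d <- as.integer(embedding_dim)
  pp <- as.integer(position_slots)
  stopifnot(d >= 1L, pp >= 1L)
  params <- with_preserved_rng({
    set.seed(seed)
    list(
      U = matrix(stats::rnorm(v * (v + 1L), sd = 0.1), v, v + 1L),
      A = matrix(stats::rnorm(v * d, sd = 0.1), v, d),
      B = matrix(stats::rnorm(d * v, sd = 0.1), d, v),
      Q = matrix(stats::rnorm(v * pp, sd = 0.1), v, pp),
      b = stats::rnorm(v, sd = 0.1)
    )
  })
  out <- list(
    vocab = vocab, v = v, d = d, p = pp, seed = as.integer(seed),
    end_id = match(end_token, vocab), end_token = end_token,
    params = params
  )
  class(out) <- "toy_policy"
  out
}

#' @export
print.toy_policy <- function(x, ...) {
  cat(sprintf("toy_policy: %d tokens (end '%s'), rank-%d source map, %d position slots, %d parameters\n",
              x$v, x$end_token, x$d, x$p, length(policy_get_params(x))))
  invisible(x)
}

# Run an expression with the global RNG state preserved, so that seeded
# internals never perturb the caller's random stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' Map token surface forms to ids under a policy's vocabulary
#'
#' @param model A `toy_policy`.
#' @param tokens Character vector of surface forms.
#' @return Integer vector of ids.
#' @export
policy_token_ids <- function(model, tokens) {
  ids <- match(tokens, model$vocab)
  if (anyNA(ids)) {
    stop(sprintf("unknown token(s) outside vocabulary: %s",
                 paste(unique(tokens[is.na(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  ids
}

#' Detokenize ids to text
#'
#' Joins surface forms with spaces; the end token is dropped.
#'
#' @param model A `toy_policy`.
#' @param ids Integer token ids.
#' @return Character scalar (possibly empty).
#' @export
policy_detokenize <- function(model, ids) {
  ids <- ids[ids != model$end_id]
  paste(model$vocab[ids], collapse = " ")
}

# L1-normalized bag-of-token counts of the source.
.source_features <- function(model, source_ids) {
  phi <- tabulate(source_ids, nbins = model$v)
  s <- sum(phi)
  if (s > 0) phi / s else phi
}

# Source-conditioned logit base b + A (B phi); constant across decode steps.
.logit_base <- function(model, source_ids) {
  phi <- .source_features(model, source_ids)
  as.numeric(model$params$b + model$params$A %*% (model$params$B %*% phi))
}

.log_softmax <- function(logits) {
  m <- max(logits)
  logits - (m + log(sum(exp(logits - m))))
}

#' Per-step log-probabilities over the vocabulary
#'
#' Log-probabilities of the next token given the source and the prefix
#' generated so far. Only the last prefix token enters the transition
#' term; `logsumexp` of the result is 0 by construction.
#'
#' @param model A `toy_policy`.
#' @param source_ids Integer ids of the source tokens.
#' @param prefix_ids Integer ids generated so far (may be empty).
#' @return Numeric vector of length `model$v` of log-probabilities.
#' @export
token_logprobs <- function(model, source_ids, prefix_ids = integer(0)) {
  .validate_ids(model, source_ids)
  .validate_ids(model, prefix_ids)
  logits <- .logit_base(model, source_ids)
  n <- length(prefix_ids)
  prev <- if (n > 0L) prefix_ids[n] else model$v + 1L # start column
  pos <- min(n + 1L, model$p)
  .log_softmax(logits + model$params$U[, prev] + model$params$Q[, pos])
}

.validate_ids <- function(model, ids) {
  if (length(ids) && (anyNA(ids) || any(ids < 1L) || any(ids > model$v))) {
    stop("token id outside vocabulary", call. = FALSE)
  }
  invisible(TRUE)
}

# Log-probabilities of each target token under forced decoding, plus the
# per-step distributions needed by the analytic gradients.
.forced_pass <- function(model, source_ids, target_ids) {
  base <- .logit_base(model, source_ids)
  m <- length(target_ids)
  logp <- numeric(m)
  probs <- matrix(0, model$v, m)
  prev <- model$v + 1L # start column
  for (t in seq_len(m)) {
    pos <- min(t, model$p)
    lp <- .log_softmax(base + model$params$U[, prev] +
                         model$params$Q[, pos])
    logp[t] <- lp[target_ids[t]]
    probs[, t] <- exp(lp)
    prev <- target_ids[t]
  }
  list(logp = logp, probs = probs)
}

#' Flatten / restore policy parameters
#'
#' The flat vector layout is `c(U, A, B, Q, b)` in column-major order; used
#' by the gradient checks and the plain-SGD update.
#'
#' @param model A `toy_policy`.
#' @return `policy_get_params`: numeric vector of all parameters.
#' @export
policy_get_params <- function(model) {
  with(model$params, c(as.numeric(U), as.numeric(A), as.numeric(B),
                       as.numeric(Q), b))
}

#' @rdname policy_get_params
#' @param theta Numeric vector as produced by `policy_get_params`.
#' @return `policy_set_params`: the model with parameters replaced.
#' @export
policy_set_params <- function(model, theta) {
  v <- model$v; d <- model$d; pp <- model$p
  sizes <- c(v * (v + 1L), v * d, d * v, v * pp, v)
  stopifnot(length(theta) == sum(sizes))
  idx <- cumsum(sizes)
  model$params$U <- matrix(theta[1:idx[1]], v, v + 1L)
  model$params$A <- matrix(theta[(idx[1] + 1):idx[2]], v, d)
  model$params$B <- matrix(theta[(idx[2] + 1):idx[3]], d, v)
  model$params$Q <- matrix(theta[(idx[3] + 1):idx[4]], v, pp)
  model$params$b <- theta[(idx[4] + 1):idx[5]]
  model
}

# Gradient accumulator in parameter shapes, all zeros.
.zero_grad <- function(model) {
  list(U = matrix(0, model$v, model$v + 1L),
       A = matrix(0, model$v, model$d),
       B = matrix(0, model$d, model$v),
       Q = matrix(0, model$v, model$p),
       b = numeric(model$v))
}

# Accumulate d(-sum_t w_t log p(y_t)) / d params for a forced pass over
# target_ids with per-step weights w (scalar or vector). The softmax
# gradient at step t is (p_t - onehot(y_t)); the source-feature terms
# factor out of the step sum because phi is constant within a sequence.
.accumulate_nll_grad <- function(model, grad, source_ids, target_ids,
                                 weights = 1) {
  pass <- .forced_pass(model, source_ids, target_ids)
  m <- length(target_ids)
  w <- rep_len(weights, m)
  gsum <- numeric(model$v)
  prev <- model$v + 1L # start column
  for (t in seq_len(m)) {
    g <- pass$probs[, t] * w[t]
    g[target_ids[t]] <- g[target_ids[t]] - w[t]
    grad$U[, prev] <- grad$U[, prev] + g
    pos <- min(t, model$p)
    grad$Q[, pos] <- grad$Q[, pos] + g
    gsum <- gsum + g
    prev <- target_ids[t]
  }
  phi <- .source_features(model, source_ids)
  u <- as.numeric(model$params$B %*% phi)
  grad$A <- grad$A + outer(gsum, u)
  grad$B <- grad$B + outer(as.numeric(crossprod(model$params$A, gsum)), phi)
  grad$b <- grad$b + gsum
  list(grad = grad, logp = pass$logp)
}

# Apply one plain-SGD step: theta <- theta - lr * grad.
.apply_grad <- function(model, grad, lr) {
  model$params$U <- model$params$U - lr * grad$U
  model$params$A <- model$params$A - lr * grad$A
  model$params$B <- model$params$B - lr * grad$B
  model$params$Q <- model$params$Q - lr * grad$Q
  model$params$b <- model$params$b - lr * grad$b
  model
}

# Checkpoint I/O -----------------------------------------------------------

#' Save / load toy-policy checkpoints
#'
#' Plain-text format: a small header (vocab size, rank, seed, end token,
#' vocabulary) followed by the flat parameter vector, one number per line
#' at full precision.
#'
#' @param model A `toy_policy`.
#' @param path File path.
#' @export
write_checkpoint <- function(model, path) {
  header <- c(
    sprintf("# toy_policy checkpoint"),
    sprintf("v %d", model$v),
    sprintf("d %d", model$d),
    sprintf("p %d", model$p),
    sprintf("seed %d", model$seed),
    sprintf("end_token %s", model$end_token),
    paste("vocab", paste(model$vocab, collapse = " "))
  )
  theta <- format(policy_get_params(model), digits = 17)
  writeLines(c(header, theta), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @return `read_checkpoint`: the restored `toy_policy`.
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  stopifnot(startsWith(lines[1], "# toy_policy"))
  field <- function(i) strsplit(lines[i], " ", fixed = TRUE)[[1]]
  v <- as.integer(field(2)[2])
  d <- as.integer(field(3)[2])
  pp <- as.integer(field(4)[2])
  seed <- as.integer(field(5)[2])
  end_token <- field(6)[2]
  vocab <- field(7)[-1]
  stopifnot(length(vocab) == v)
  theta <- as.numeric(lines[-(1:7)])
  model <- make_toy_policy(vocab, embedding_dim = d, seed = seed,
                           end_token = end_token, position_slots = pp)
  policy_set_params(model, theta)
}
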