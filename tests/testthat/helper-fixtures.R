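# Shared fixtures and independent oracles, built in code.

# Tiny deterministic lexicon used across reward tests.
tiny_lexicon <- function() {
  freq_lexicon(
    c("use", "utilize", "we", "cat", "sat", "the", "a", "b", "c", "d"),
    c(5.0, 2.0, 6.0, 4.5, 4.0, 7.0, 6.5, 4.0, 4.0, 4.0)
  )
}

# A fixed two-dimensional embedder mapping known texts to known vectors,
# for closed-form cosine checks.
fixed_embedder <- function(map) {
  embedding_model(function(text) map[[text]], dimension = 2L,
                  name = "fixed2d")
}

# Independent SARI oracle: direct enumeration of the operation sets per
# n, following the package's stated conventions but sharing no code with
# the implementation (base-R sets on ngram strings built here).
oracle_sari <- function(source, candidate, reference) {
  grams <- function(txt, n) {
    toks <- strsplit(tolower(txt), "[^a-z0-9']+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < n) return(character(0))
    unique(vapply(seq_len(length(toks) - n + 1),
                  function(i) paste(toks[i:(i + n - 1)], collapse = "\x1f"),
                  character(1)))
  }
  op <- function(cand, ref, prec_only = FALSE) {
    if (!length(cand) && !length(ref)) return(1)
    if (!length(cand) || !length(ref)) return(0)
    inter <- length(intersect(cand, ref))
    p <- inter / length(cand)
    if (prec_only) return(p)
    r <- inter / length(ref)
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  scores <- sapply(1:4, function(n) {
    s <- grams(source, n); cc <- grams(candidate, n); r <- grams(reference, n)
    c(add = op(setdiff(cc, s), setdiff(r, s)),
      keep = op(intersect(cc, s), intersect(r, s)),
      del = op(setdiff(s, cc), setdiff(s, r), prec_only = TRUE))
  })
  mean(rowMeans(scores))
}

# Central finite-difference gradient of f at theta (selected indices).
fd_gradient <- function(f, theta, idx, eps = 1e-5) {
  vapply(idx, function(j) {
    tp <- theta; tp[j] <- theta[j] + eps
    tm <- theta; tm[j] <- theta[j] - eps
    (f(tp) - f(tm)) / (2 * eps)
  }, numeric(1))
}

# Flatten an analytic gradient accumulator to the theta layout.
flat_grad <- function(g) c(as.numeric(g$U), as.numeric(g$A),
                           as.numeric(g$B), as.numeric(g$Q), g$b)

# Small policy + pair used in several scst tests.
tiny_policy <- function(seed = 2) {
  make_toy_policy(c("a", "b", "c", "d"), embedding_dim = 3, seed = seed)
}
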