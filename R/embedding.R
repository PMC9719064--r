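# Text-embedding contract and the packaged fallback embedder.
#
# The relevance reward only needs "map text -> fixed-dimension vector,
# deterministically". Any sentence-embedding model (e.g. a biomedical
# sentence encoder) can be attached by wrapping it in embedding_model();
# the packaged default is a deterministic hashed bag-of-words embedder so
# that everything runs with no model download.

#' Wrap an embedding function in the embedding-model contract
#'
#' @param fn Function mapping a character scalar to a numeric vector of
#'   length `dimension`.
#' @param dimension Embedding dimension, >= 1.
#' @param name Label used in printing and config echoes.
#' @return An object of class `embedding_model`.
#' @export
embedding_model <- function(fn, dimension, name = "custom") {
  stopifnot(is.function(fn), dimension >= 1)
  out <- list(fn = fn, dimension = as.integer(dimension), name = name)
  class(out) <- "embedding_model"
  out
}

#' Embed a text
#'
#' @param model An `embedding_model`.
#' @param text Character scalar.
#' @return Numeric vector of length `model$dimension`.
#' @export
embed_text <- function(model, text) {
  stopifnot(inherits(model, "embedding_model"))
  v <- model$fn(text)
  if (!is.numeric(v) || length(v) != model$dimension) {
    stop("embed_text(): embedder returned a vector of the wrong shape",
         call. = FALSE)
  }
  as.numeric(v)
}

# Deterministic polynomial hash of a string into 0..(m-1). Works on UTF-8
# bytes so results are platform independent.
.string_hash <- function(s, m, seed = 1L) {
  bytes <- as.integer(utf8ToInt(enc2utf8(s)))
  h <- as.numeric(seed)
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h %% m)
}

#' Hashed bag-of-words embedder
#'
#' The packaged fallback embedding model: each word type of the text is
#' hashed to one of `dimension` buckets with a signed contribution
#' (feature hashing), and the bucket totals form the embedding. Identical
#' texts always map to identical vectors; texts sharing more vocabulary
#' have higher cosine similarity.
#'
#' @param dimension Number of hash buckets (default 64).
#' @param hash_seed Fixed integer seed of the hash (default 17); this is
#'   a structural constant, not a random seed.
#' @return An `embedding_model`.
#' @export
hashed_bow_embedder <- function(dimension = 64L, hash_seed = 17L) {
  dimension <- as.integer(dimension)
  stopifnot(dimension >= 1L)
  memo <- new.env(parent = emptyenv()) # word -> c(bucket, sign); pure
  fn <- function(text) {
    v <- numeric(dimension)
    toks <- tokenize_words(text)
    for (w in toks) {
      h <- memo[[w]]
      if (is.null(h)) {
        h <- c(.string_hash(w, dimension, seed = hash_seed) + 1L,
               if (.string_hash(w, 2L, seed = hash_seed + 1L) == 0L) 1L else -1L)
        memo[[w]] <- h
      }
      v[h[1]] <- v[h[1]] + h[2]
    }
    v
  }
  embedding_model(fn, dimension, name = sprintf("hashed_bow_%d", dimension))
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("embedding_model '%s', dimension %d\n", x$name, x$dimension))
  invisible(x)
}
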