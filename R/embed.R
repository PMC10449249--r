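# Text vectorization.  Diagnosis text maps to a 20 x 768 matrix, a
# symptom list to a 50 x 768 matrix, mirroring the fixed embedding
# geometry of the classifier.  The default embedder is a deterministic
# hashed token projection \u2014 each token hashes to the seed of a
# Lehmer/Park-Miller stream that emits its 768-dimensional vector \u2014 so
# the package builds and tests fully offline.  A pretrained contextual
# embedder can be plugged in behind the same contract.

EMBED_DIM <- 768L
ROLE_LENGTHS <- c(diagnosis = 20L, symptom = 50L)
LCG_M <- 2147483647  # 2^31 - 1 (Park-Miller modulus; exact in doubles)
LCG_A <- 16807

# Deterministic polynomial string hash into [1, LCG_M - 1].
token_hash <- function(token) {
  bytes <- as.integer(utf8ToInt(enc2utf8(token)))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b + 1) %% LCG_M
  if (h == 0) h <- 1
  h
}

lcg_stream <- function(seed, n) {
  out <- numeric(n)
  s <- seed
  for (i in seq_len(n)) {
    s <- (LCG_A * s) %% LCG_M
    out[i] <- s / LCG_M
  }
  out
}

#' Create the default hashing embedder
#'
#' @param dim Embedding width (768 by default; fixed by the model
#'   geometry).
#' @param scale Standard-deviation scale of the token vectors.
#' @return A `hash_embedder` object: carries a per-session token cache and
#'   a `vectorize_tokens(tokens)` closure mapping each token to a
#'   deterministic `dim`-vector (uniform, zero-mean, sd `scale`).
#' @export
hash_embedder <- function(dim = EMBED_DIM, scale = 1) {
  cache <- new.env(parent = emptyenv())
  embed_one <- function(token) {
    key <- paste0("t_", token)
    v <- cache[[key]]
    if (is.null(v)) {
      u <- lcg_stream(token_hash(token), dim)
      v <- (u - 0.5) * sqrt(12) * scale
      cache[[key]] <- v
    }
    v
  }
  structure(list(dim = as.integer(dim), scale = scale,
                 embed_one = embed_one,
                 spec = list(type = "hash", dim = as.integer(dim),
                             scale = scale)),
            class = "hash_embedder")
}

.default_embedder_env <- new.env(parent = emptyenv())

#' The shared default embedder instance
#'
#' Returns a package-level [hash_embedder()] singleton so the token
#' vector cache persists across calls (per-record prediction would
#' otherwise re-derive every token vector).
#' @return A `hash_embedder`.
#' @export
default_embedder <- function() {
  e <- .default_embedder_env$inst
  if (is.null(e)) {
    e <- hash_embedder()
    .default_embedder_env$inst <- e
  }
  e
}

# Whitespace/punctuation tokenization with CJK characters split
# one-per-token; symptom lists keep each term as one atomic token.
tokenize_text <- function(x) {
  if (length(x) == 0L) return(character())
  if (length(x) > 1L) return(as.character(x[nzchar(x)]))
  if (is.null(x) || is.na(x) || !nzchar(x)) return(character())
  cjk <- paste0("([", intToUtf8(0x4E00L), "-", intToUtf8(0x9FFFL), "])")
  x <- gsub(cjk, " \\1 ", enc2utf8(x), perl = TRUE)
  toks <- strsplit(x, "[\\s,;:()\\[\\]]+", perl = TRUE)[[1]]
  toks[nzchar(toks)]
}

#' Vectorize diagnosis text or a symptom list
#'
#' Maps a token sequence to an `L x 768` matrix: `L = 20` for the
#' diagnosis role, `L = 50` for the symptom role.  Sequences longer than
#' `L` are truncated at the tail; shorter ones are padded with all-zero
#' rows.  Empty input yields the all-zero matrix.
#'
#' @param x A single string (diagnosis) or a character vector of terms
#'   (symptoms; each term is one token).
#' @param role `"diagnosis"` or `"symptom"`.
#' @param embedder A [hash_embedder()] (or any object with `dim` and
#'   `embed_one`).
#' @return Numeric matrix of shape `(20, 768)` or `(50, 768)`.
#' @export
vectorize <- function(x, role = c("diagnosis", "symptom"),
                      embedder = hash_embedder()) {
  role <- match.arg(role)
  L <- ROLE_LENGTHS[[role]]
  toks <- tokenize_text(x)
  out <- matrix(0, nrow = L, ncol = embedder$dim)
  n <- min(length(toks), L)
  if (n > 0L)
    for (i in seq_len(n)) out[i, ] <- embedder$embed_one(toks[i])
  out
}

#' Vectorize a batch of inputs into an array
#'
#' @param xs List of inputs (strings or term vectors).
#' @inheritParams vectorize
#' @return Array of shape `(n, L, 768)`.
#' @export
vectorize_batch <- function(xs, role = c("diagnosis", "symptom"),
                            embedder = hash_embedder()) {
  role <- match.arg(role)
  L <- ROLE_LENGTHS[[role]]
  n <- length(xs)
  arr <- array(0, dim = c(n, L, embedder$dim))
  for (i in seq_len(n)) arr[i, , ] <- vectorize(xs[[i]], role, embedder)
  arr
}
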