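#' One-hot encode a single character
#'
#' Characters with Unicode code point below 127 are encoded at their code
#' point; every other character falls into the final (128th) slot, so all
#' ASCII letters, digits and punctuation get distinct codes and everything
#' else shares one.
#'
#' @param ch a single character (one code point).
#' @return numeric vector of length 128 with exactly one 1.
#' @export
encode_char <- function(ch) {
  stopifnot(is.character(ch), length(ch) == 1L)
  if (nchar(ch) != 1L)
    stop_phideid("encode_char expects exactly one character, got %s",
                 deparse(ch))
  v <- numeric(128)
  v[char_code(ch) + 1L] <- 1
  v
}

# 0-based one-hot indices for all characters of a token.
char_code <- function(token) {
  cp <- utf8ToInt(token)
  ifelse(cp < 127L, cp, 127L)
}

#' One-hot encode every character of a token
#'
#' @param token non-empty character scalar.
#' @return matrix with 128 rows and one column per character, each column a
#'   one-hot vector in character order.
#' @export
encode_token_chars <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  if (!nzchar(token)) stop_phideid("cannot encode an empty token")
  codes <- char_code(token)
  m <- matrix(0, nrow = 128, ncol = length(codes))
  m[cbind(codes + 1L, seq_along(codes))] <- 1
  m
}

#' Construct an embedding table
#'
#' @param vectors numeric matrix, one row per word, with rownames the (lower
#'   case) vocabulary.
#' @param default vector returned for out-of-vocabulary words; defaults to
#'   all zeros (neutral under concatenation with the learned character
#'   embedding).
#' @return object of class `embedding_table` with elements `dim`, `vectors`,
#'   `default`.
#' @export
embedding_table <- function(vectors, default = NULL) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  d <- ncol(vectors)
  if (is.null(default)) default <- numeric(d)
  stopifnot(length(default) == d)
  structure(list(dim = d, vectors = vectors, default = as.numeric(default)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table: %d words, dim %d>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' Look up the word vector of a token
#'
#' Lookup is case-insensitive (tokens are lower-cased first, matching common
#' Word2Vec practice); unknown words return the table default.
#'
#' @param table an [embedding_table()].
#' @param token character scalar.
#' @return numeric vector of length `table$dim`.
#' @export
lookup_word <- function(table, token) {
  i <- match(tolower(token), rownames(table$vectors))
  if (is.na(i)) table$default else table$vectors[i, ]
}

# Word-vector matrix (n x dim) for a token vector; vectorized lookup.
lookup_words <- function(table, tokens) {
  idx <- match(tolower(tokens), rownames(table$vectors))
  out <- matrix(table$default, nrow = length(tokens), ncol = table$dim,
                byrow = TRUE)
  hit <- !is.na(idx)
  if (any(hit)) out[hit, ] <- table$vectors[idx[hit], , drop = FALSE]
  out
}

#' Load a plain-text word-embedding table
#'
#' Reads the common `word v1 v2 ... vD` text format (one word per line,
#' whitespace separated); gzip-compressed files are handled transparently.
#' The dimension is inferred from the first row and all rows must agree.
#'
#' @param path path to the embedding file.
#' @return an [embedding_table()].
#' @export
load_embedding_table <- function(path) {
  con <- gzfile(path, "rt", encoding = "UTF-8")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_phideid("empty embedding file: %s", path)
  parts <- strsplit(lines, "[ \t]+")
  d <- length(parts[[1]]) - 1L
  if (d < 1L) stop_phideid("line 1: no vector components")
  bad <- which(lengths(parts) != d + 1L)
  if (length(bad) > 0L)
    stop_phideid("line %d: expected %d values, found %d",
                 bad[1], d, lengths(parts)[bad[1]] - 1L)
  words <- tolower(vapply(parts, `[[`, character(1), 1L))
  vecs <- matrix(as.numeric(vapply(parts, function(p) p[-1],
                                   character(d))),
                 ncol = d, byrow = TRUE)
  if (anyNA(vecs)) stop_phideid("non-numeric vector component in %s", path)
  rownames(vecs) <- words
  embedding_table(vecs)
}

#' Build a seeded random embedding table
#'
#' Stand-in for a pretrained Word2Vec table when none is available: entries
#' are i.i.d. uniform on [-0.1, 0.1], reproducible from the seed. Random but
#' fixed vectors keep words distinguishable for the tagger's word channel.
#'
#' @param vocab character vector of words (lower-cased, deduplicated).
#' @param dim embedding dimension (default 300).
#' @param seed integer seed.
#' @return an [embedding_table()].
#' @export
make_random_table <- function(vocab, dim = 300L, seed = 1L) {
  stopifnot(length(vocab) >= 1L, is_count(dim), dim >= 1)
  vocab <- unique(tolower(vocab))
  vecs <- with_seed(derive_seed(seed, 977L), {
    matrix(runif(length(vocab) * dim, -0.1, 0.1), nrow = length(vocab))
  })
  rownames(vecs) <- vocab
  embedding_table(vecs)
}

# Vocabulary of a corpus (lower-cased unique tokens).
corpus_vocab <- function(corpus) {
  unique(tolower(unlist(lapply(corpus, `[[`, "tokens"))))
}
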