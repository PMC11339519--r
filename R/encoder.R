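# Text-encoder contract shared by all training phases.
#
# An encoder maps a character vector to a matrix of embeddings (one row per
# text, `dimension` columns, unit-norm when requested). Two implementations
# ship with the package: the trainable reference encoder (character n-gram
# hashing followed by a trainable linear map) and a thin wrapper for
# arbitrary embedding functions (pretrained models, oracles, baselines).

#' Create the trainable reference encoder
#'
#' The reference encoder hashes character n-grams of the input text into
#' `hash_buckets` count features and applies a trainable linear map down to
#' `dimension` dimensions, followed by L2 normalization. It is a
#' deliberately small, CPU-friendly stand-in for a pretrained sentence
#' encoder: every training phase of the pipeline (contrastive,
#' self-distillation, soup, cross-lingual) can run against it end-to-end.
#' For each n-gram order n, the text is padded with `n - 1` boundary
#' markers on both sides, so every non-empty text produces at least one
#' feature per order.
#'
#' @param dimension Embedding dimension D (>= 2).
#' @param hash_buckets Number of hash buckets H (>= `dimension`).
#' @param ngram_range Integer pair `(min, max)` of character n-gram orders.
#' @param seed Integer seed for the random initialization of the linear map.
#' @param init_sd Standard deviation of the Gaussian weight initialization.
#'   The default gives an untrained encoder whose cosine geometry mirrors
#'   raw n-gram overlap (a random projection); a small value (e.g. 0.01)
#'   suits students trained from scratch purely by distillation, where the
#'   initialization is noise to be overwritten rather than a prior.
#' @return An object of class `lord_encoder` (architecture `"hash_linear"`)
#'   with a single trainable parameter array `W` of shape D x H.
#' @examples
#' enc <- make_reference_encoder(8, hash_buckets = 64, seed = 1)
#' e <- encode_texts(enc, c("fever", "fievre"))
#' rowSums(e^2)  # unit norms
#' @export
make_reference_encoder <- function(dimension, hash_buckets = 1024L,
                                   ngram_range = c(2L, 4L), seed = 0L,
                                   init_sd = 0.1) {
  if (dimension < 2L) stop_input("`dimension` must be >= 2")
  if (hash_buckets < dimension) {
    stop_input("`hash_buckets` must be >= `dimension`")
  }
  if (length(ngram_range) != 2L || ngram_range[1L] > ngram_range[2L] ||
      ngram_range[1L] < 1L) {
    stop_input("`ngram_range` must be an increasing pair of orders >= 1")
  }
  stopifnot(init_sd > 0)
  W <- with_seed(seed, matrix(stats::rnorm(dimension * hash_buckets,
                                           sd = init_sd),
                              nrow = dimension, ncol = hash_buckets))
  structure(
    list(arch = "hash_linear",
         dimension = as.integer(dimension),
         hash_buckets = as.integer(hash_buckets),
         ngram = as.integer(ngram_range),
         seed = as.integer(seed),
         params = list(W = W)),
    class = c("lord_encoder", "ontolord_encoder")
  )
}

#' Wrap an arbitrary embedding function as an encoder
#'
#' Adapter for plugging external models (or test oracles and random
#' baselines) into any operation that expects an encoder. The function must
#' map a character vector to a numeric matrix with one row per input text
#' and `dimension` columns; normalization is applied by [encode_texts()].
#'
#' @param fn `function(texts) -> matrix`.
#' @param dimension Embedding dimension the function returns.
#' @param tag Architecture tag recorded on the object.
#' @return An object of class `callable_encoder`.
#' @export
make_callable_encoder <- function(fn, dimension, tag = "callable") {
  stopifnot(is.function(fn), dimension >= 1L)
  structure(list(arch = tag, dimension = as.integer(dimension), fn = fn,
                 params = list()),
            class = c("callable_encoder", "ontolord_encoder"))
}

#' Deterministic random-embedding baseline
#'
#' Maps each distinct text to a pseudo-random unit vector keyed by a hash of
#' the text and `seed`. Same text, same vector; unrelated texts, unrelated
#' vectors. Serves as the chance-level baseline in retrieval sanity checks.
#'
#' @param dimension Embedding dimension.
#' @param seed Integer mixed into the per-text key.
#' @export
make_random_encoder <- function(dimension, seed = 0L) {
  force(dimension); force(seed)
  fn <- function(texts) {
    out <- matrix(0, length(texts), dimension)
    for (i in seq_along(texts)) {
      key <- (fnv1a(texts[[i]]) + seed) %% 2147483647
      out[i, ] <- with_seed(key, stats::rnorm(dimension))
    }
    out
  }
  make_callable_encoder(fn, dimension, tag = "random_baseline")
}

#' Encode texts
#'
#' Maps texts to embeddings, one row per text in input order. With
#' `normalize = TRUE` (the default everywhere in the pipeline) rows are
#' L2-normalized so cosine similarity equals the dot product.
#'
#' @param enc An encoder (`lord_encoder` or `callable_encoder`).
#' @param texts Character vector of non-empty strings.
#' @param normalize Return unit-norm rows.
#' @return Numeric matrix `length(texts)` x `dimension`.
#' @export
encode_texts <- function(enc, texts, normalize = TRUE) {
  UseMethod("encode_texts")
}

check_texts <- function(texts) {
  if (length(texts) == 0L) stop_input("`texts` must be non-empty")
  bad <- which(!nzchar(texts) | is.na(texts))
  if (length(bad)) {
    stop_input("empty text at index %d", bad[[1L]])
  }
  as.character(texts)
}

#' @export
encode_texts.lord_encoder <- function(enc, texts, normalize = TRUE) {
  texts <- check_texts(texts)
  X <- featurize_texts(texts, enc$hash_buckets, enc$ngram)
  E <- t(enc$params$W %*% X)
  if (normalize) E <- l2_normalize_rows(E)
  E
}

#' @export
encode_texts.callable_encoder <- function(enc, texts, normalize = TRUE) {
  texts <- check_texts(texts)
  E <- enc$fn(texts)
  if (!is.matrix(E) || nrow(E) != length(texts) || ncol(E) != enc$dimension) {
    stop_input("callable encoder returned a %s, expected %d x %d matrix",
               paste(dim(E), collapse = "x"), length(texts), enc$dimension)
  }
  if (normalize) E <- l2_normalize_rows(E)
  E
}

#' @export
print.ontolord_encoder <- function(x, ...) {
  cat(sprintf("<encoder arch=%s dim=%d>\n", x$arch, x$dimension))
  invisible(x)
}

# --- character n-gram hashing ------------------------------------------------

#' Character n-grams of a text
#'
#' Enumerates the character n-grams the reference encoder hashes, in
#' left-to-right order for each order `n` in `nmin:nmax`. With `pad = TRUE`
#' (what the encoder uses) the text is padded with `n - 1` `"#"` boundary
#' markers on each side of the text for order n.
#'
#' @param text A single string.
#' @param nmin,nmax Smallest and largest n-gram order.
#' @param pad Include boundary-padded n-grams.
#' @return Character vector of n-grams.
#' @export
char_ngrams <- function(text, nmin, nmax, pad = TRUE) {
  stopifnot(length(text) == 1L, nmin >= 1L, nmin <= nmax)
  out <- character(0)
  for (n in nmin:nmax) {
    s <- if (pad) paste0(strrep("#", n - 1L), text, strrep("#", n - 1L)) else text
    m <- nchar(s) - n + 1L
    if (m < 1L) next
    out <- c(out, substring(s, seq_len(m), seq_len(m) + n - 1L))
  }
  out
}

# Enumerate the hashed n-gram buckets of one text. For each order n the text
# is padded with n-1 '#' markers on each side; the polynomial rolling hash
# stays below 2^31 so all arithmetic is exact in doubles.
hash_ngram_buckets <- function(text, hash_buckets, ngram) {
  buckets <- integer(0)
  for (n in ngram[1L]:ngram[2L]) {
    pad <- strrep("#", n - 1L)
    codes <- utf8ToInt(paste0(pad, text, pad))
    m <- length(codes) - n + 1L
    if (m < 1L) next
    h <- numeric(m)
    for (k in 0L:(n - 1L)) {
      h <- (h * 31 + codes[seq_len(m) + k]) %% 2147483648
    }
    buckets <- c(buckets, as.integer(h %% hash_buckets) + 1L)
  }
  buckets
}

# Count-feature matrix, hash_buckets x length(texts). Repeated texts are
# featurized once.
featurize_texts <- function(texts, hash_buckets, ngram) {
  uniq <- unique(texts)
  cols <- matrix(0, nrow = hash_buckets, ncol = length(uniq))
  for (j in seq_along(uniq)) {
    b <- hash_ngram_buckets(uniq[[j]], hash_buckets, ngram)
    if (length(b)) cols[, j] <- tabulate(b, nbins = hash_buckets)
  }
  cols[, match(texts, uniq), drop = FALSE]
}

# --- checkpoint serialization ------------------------------------------------

#' Write / read encoder checkpoints
#'
#' Reference-encoder checkpoints are stored as a single JSON file holding a
#' manifest (architecture tag, dimension, hash buckets, n-gram range, seed)
#' and the named parameter arrays at full floating-point precision.
#' Callable encoders wrap arbitrary R functions and cannot be serialized.
#'
#' @param enc A `lord_encoder`.
#' @param path File path for the checkpoint (conventionally `.json`).
#' @return `write_encoder()` returns `path` invisibly; `read_encoder()`
#'   returns the restored encoder.
#' @export
write_encoder <- function(enc, path) {
  if (!inherits(enc, "lord_encoder")) {
    stop_input("only reference encoders can be serialized")
  }
  obj <- list(
    manifest = list(arch = enc$arch, dimension = enc$dimension,
                    hash_buckets = enc$hash_buckets, ngram = enc$ngram,
                    seed = enc$seed),
    params = lapply(enc$params, function(a) {
      list(dim = dim(a), data = as.numeric(a))
    })
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  man <- obj$manifest
  params <- lapply(obj$params, function(a) {
    array(as.numeric(a$data), dim = as.integer(a$dim))
  })
  structure(
    list(arch = man$arch[[1L]],
         dimension = as.integer(man$dimension[[1L]]),
         hash_buckets = as.integer(man$hash_buckets[[1L]]),
         ngram = as.integer(man$ngram),
         seed = as.integer(man$seed[[1L]]),
         params = params),
    class = c("lord_encoder", "ontolord_encoder")
  )
}

#' Cosine similarity between two embedding sets
#'
#' @param A,B Numeric matrices with one embedding per row (same number of
#'   columns). Rows are normalized internally.
#' @return `nrow(A)` x `nrow(B)` matrix of cosine similarities.
#' @export
cosine_matrix <- function(A, B) {
  tcrossprod(l2_normalize_rows(A), l2_normalize_rows(B))
}
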