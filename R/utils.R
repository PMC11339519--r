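# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so that independent calls cannot perturb each
# other's streams.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  code
}

# FNV-1a 32-bit hash of a character scalar, returned as a double in
# [0, 2^32). Used for config fingerprints and text-keyed seeds; arithmetic is
# done in doubles with explicit mod to stay inside the exact-integer range.
fnv1a <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(x))) {
    h <- bitwXor64(h, b %% 256)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor of two non-negative doubles < 2^32, bytewise.
bitwXor64 <- function(a, b) {
  r <- 0
  p <- 1
  for (i in 1:4) {
    r <- r + bitwXor(as.integer(a %% 256), as.integer(b %% 256)) * p
    a <- a %/% 256
    b <- b %/% 256
    p <- p * 256
  }
  r
}

# Stable row-normalization; zero rows are left at zero and flagged.
l2_normalize_rows <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
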