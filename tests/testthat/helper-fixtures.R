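# Shared fixture builders. Everything is generated in code at test time.

# write a small pipe-delimited table; `rows` is a list of character vectors
write_psv <- function(rows, path = tempfile(fileext = ".psv")) {
  writeLines(vapply(rows, paste, "", collapse = "|"), path)
  path
}

# three-concept toy graph files (drug/disease flavoured)
toy_graph_files <- function() {
  list(
    concepts = write_psv(list(
      c("C001", "en", "ranitidine", "drug"),
      c("C001", "en", "zantac", "drug"),
      c("C002", "en", "peptic ulcer", "disease"),
      c("C003", "en", "aspirin", "drug")
    )),
    definitions = write_psv(list(
      c("C001", "human",
        "an h2-antagonist substance frequently used to treat peptic ulcer"),
      c("C003", "human",
        "a synthetic compound used medicinally to relieve mild pain")
    )),
    relations = write_psv(list(
      c("C001", "may_treat", "C002"),
      c("C003", "may_treat", "C002")
    ))
  )
}

toy_graph <- function() {
  f <- toy_graph_files()
  load_knowledge_graph(f$concepts, f$definitions, f$relations)
}

# random unit-row matrix
unit_rows <- function(n, d) {
  m <- matrix(stats::rnorm(n * d), n, d)
  m / sqrt(rowSums(m^2))
}

# Spearman correlation of the upper triangles of two similarity matrices
sim_spearman <- function(enc_a, enc_b, texts) {
  Sa <- tcrossprod(encode_texts(enc_a, texts))
  Sb <- tcrossprod(encode_texts(enc_b, texts))
  stats::cor(Sa[upper.tri(Sa)], Sb[upper.tri(Sb)], method = "spearman")
}

# independent InfoNCE oracle: explicit scalar loops, no matrix operations
brute_force_infonce <- function(A, P, tau, symmetric) {
  B <- nrow(A)
  direction_loss <- function(anchor_first) {
    total <- 0
    for (i in seq_len(B)) {
      logits <- numeric(B)
      for (j in seq_len(B)) {
        s <- 0
        for (k in seq_len(ncol(A))) {
          s <- s + if (anchor_first) A[i, k] * P[j, k] else P[i, k] * A[j, k]
        }
        logits[j] <- s / tau
      }
      total <- total - log(exp(logits[i]) / sum(exp(logits)))
    }
    total / B
  }
  if (symmetric) {
    (direction_loss(TRUE) + direction_loss(FALSE)) / 2
  } else {
    direction_loss(TRUE)
  }
}

# a tiny deterministic "lookup" encoder over a fixed text -> row map
fixed_encoder <- function(texts, vectors) {
  make_callable_encoder(function(x) {
    idx <- match(x, texts)
    stopifnot(!anyNA(idx))
    vectors[idx, , drop = FALSE]
  }, ncol(vectors), tag = "fixed")
}

# encoder realizing prescribed pair cosines: pair i gets sentences "ai"/"bi"
# with cos = scores[i], via 2-d rotations
toy_sts_encoder <- function(scores) {
  texts <- c(paste0("a", seq_along(scores)), paste0("b", seq_along(scores)))
  ang <- acos(pmin(1, pmax(-1, scores)))
  emb <- rbind(
    t(vapply(seq_along(scores), function(i) c(1, 0), numeric(2))),
    t(vapply(seq_along(scores), function(i) c(cos(ang[i]), sin(ang[i])),
             numeric(2))))
  fixed_encoder(texts, emb)
}

# 4-entry dictionary over 3 concepts (one concept has two names) with fixed
# toy embeddings, plus 3 mentions
nel_fixture <- function() {
  emb <- rbind(
    m1 = c(1, 0, 0), m2 = c(0, 1, 0.2), m3 = c(0.4, 0.4, 0.8),
    d1 = c(0.9, 0.1, 0), d2 = c(0.1, 0.9, 0), d2b = c(0, 0.8, 0.4),
    d3 = c(0, 0, 1))
  dict <- data.frame(concept_id = c("K1", "K2", "K2", "K3"),
                     name = c("d1", "d2", "d2b", "d3"),
                     semantic_type = c("T1", "T2", "T2", "T3"),
                     stringsAsFactors = FALSE)
  examples <- data.frame(mention = c("m1", "m2", "m3"),
                         gold_concept_id = c("K1", "K2", "K1"),
                         stringsAsFactors = FALSE)
  list(enc = fixed_encoder(rownames(emb), emb), emb = emb, dict = dict,
       examples = examples)
}
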