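# Cross-lingual distillation: freeze the monolingual teacher and train a
# multilingual student so that a source-language text and its translation
# both map to the teacher's embedding of the source text (the two-term
# parallel-corpus distillation objective). Also provides mutual-best bitext
# mining to construct the parallel corpus from per-language name lists.

#' Mine parallel name pairs by mutual-best alignment
#'
#' Scores every source/target name combination with a pluggable
#' encoder-like scorer (cosine similarity of its embeddings) and keeps the
#' pairs `(i, j)` that are mutual best matches with score at or above
#' `threshold`. Each side is used at most once; ties resolve to the first
#' index. An empty result is legal.
#'
#' @param source_names,target_names Non-empty character vectors.
#' @param scorer An encoder used only to score candidate pairs (e.g. a
#'   pretrained multilingual model behind [make_callable_encoder()]).
#' @param threshold Minimum cosine score in `[-1, 1]`; default 0.8.
#' @return Data frame `(source_text, target_text, score)`.
#' @export
mine_parallel_pairs <- function(source_names, target_names, scorer,
                                threshold = 0.8) {
  source_names <- check_texts(source_names)
  target_names <- check_texts(target_names)
  if (threshold < -1 || threshold > 1) {
    stop_input("`threshold` must lie in [-1, 1]")
  }
  S <- cosine_matrix(encode_texts(scorer, source_names),
                     encode_texts(scorer, target_names))
  best_j <- apply(S, 1L, which.max)
  best_i <- apply(S, 2L, which.max)
  keep <- which(best_i[best_j] == seq_along(source_names) &
                  S[cbind(seq_along(source_names), best_j)] >= threshold)
  data.frame(source_text = source_names[keep],
             target_text = target_names[best_j[keep]],
             score = S[cbind(keep, best_j[keep])],
             stringsAsFactors = FALSE)
}

#' Configuration for cross-lingual distillation
#'
#' @param epochs Full-batch gradient steps.
#' @param learning_rate Step size for the student parameters.
#' @param momentum Classical momentum coefficient in `[0, 1)`.
#' @param seed Seed recorded for the run.
#' @export
xlingual_config <- function(epochs = 400L, learning_rate = 2.0,
                            momentum = 0.95, seed = 0L) {
  stopifnot(epochs >= 0L, learning_rate > 0, momentum >= 0, momentum < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 momentum = momentum, seed = as.integer(seed)),
            class = "xlingual_config")
}

#' Distill a monolingual teacher into a multilingual student
#'
#' Minimizes `MSE(student(source) - teacher(source)) +
#' MSE(student(target) - teacher(source))` over the parallel pairs; the
#' teacher is frozen (its parameters are read once and never touched) and
#' must share the student's embedding dimension. With `epochs = 0` the
#' student is returned unchanged.
#'
#' @param student A trainable reference encoder (typically with a larger
#'   hash space, to host several languages).
#' @param teacher A (frozen) encoder of the same dimension.
#' @param pairs Data frame with `source_text` and `target_text`.
#' @param cfg An [xlingual_config()].
#' @return The trained student with a `history` attribute (epoch, loss).
#' @export
train_crosslingual_distillation <- function(student, teacher, pairs,
                                            cfg = xlingual_config()) {
  check_reference_encoder(student)
  stopifnot(inherits(cfg, "xlingual_config"))
  if (student$dimension != teacher$dimension) {
    stop_input("student dimension (%d) differs from teacher dimension (%d); configure a fixed adapter or matching encoders",
               student$dimension, teacher$dimension)
  }
  if (nrow(pairs) == 0L) return(student)
  Tt <- encode_texts(teacher, pairs$source_text)  # frozen targets
  n <- nrow(Tt)
  D <- ncol(Tt)
  cache <- feature_cache(student, c(pairs$source_text, pairs$target_text))
  Xs <- cache$X[, cache$index(pairs$source_text), drop = FALSE]
  Xt <- cache$X[, cache$index(pairs$target_text), drop = FALSE]
  W <- student$params$W
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  vW <- W * 0
  for (ep in seq_len(cfg$epochs)) {
    fs <- ref_forward(W, Xs)
    ft <- ref_forward(W, Xt)
    Rs <- fs$E - Tt
    Rt <- ft$E - Tt
    loss <- mean(Rs^2) + mean(Rt^2)
    GW <- ref_grad_W(fs, Xs, 2 * Rs / (n * D)) +
      ref_grad_W(ft, Xt, 2 * Rt / (n * D))
    vW <- cfg$momentum * vW + GW
    W <- W - cfg$learning_rate * vW
    if (ep %% 25L == 1L || ep == cfg$epochs) {
      history <- rbind(history, data.frame(epoch = ep, loss = loss))
    }
  }
  student$params$W <- W
  attr(student, "history") <- history
  student
}

#' Parallel corpus serialization
#'
#' Tab-separated `(source_text, target_text, language, score)` with the
#' package's standard escaping; `split` (train/heldout) is carried when the
#' column is present in the data frame.
#'
#' @param pairs Parallel pair data frame.
#' @param path File path.
#' @export
write_parallel_file <- function(pairs, path) {
  cols <- intersect(c("source_text", "target_text", "language", "score",
                      "split"), names(pairs))
  write_tsv_records(pairs[, cols], path)
}

#' @rdname write_parallel_file
#' @export
read_parallel_file <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  cols <- strsplit(first, "\t", fixed = TRUE)[[1L]]
  df <- read_tsv_records(path, cols)
  if (!all(c("source_text", "target_text") %in% names(df))) {
    stop_input("%s: parallel corpus needs source_text and target_text columns",
               path)
  }
  if ("score" %in% names(df)) df$score <- as.numeric(df$score)
  df
}
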