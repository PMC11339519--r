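# Phase 1: contrastive training with in-batch negatives.
#
# Batches pair each concept's name (anchor) with one of its definitions or
# relation verbalizations (positive); the InfoNCE objective attracts each
# anchor to its own positive and repels the positives of the other concepts
# in the batch. An STS regression adaptation can bracket the contrastive
# epochs (before and after) to keep the encoder aligned with graded
# sentence-similarity judgments.

#' Configuration for the contrastive phase
#'
#' @param batch_size In-batch negatives count B (>= 2). Each batch holds B
#'   pairs with pairwise-distinct concept ids, so no in-batch negative is a
#'   false negative.
#' @param temperature Softmax temperature tau (> 0) dividing the cosine
#'   logits. Fixed, not learned. The default (0.2) is deliberately larger
#'   than the values common for deep contrastive encoders: the loss only
#'   pushes the positive margin to the order of tau, and the downstream
#'   self-distillation phase needs the name and definition embeddings of a
#'   concept to end up tightly aligned, not merely separated from the
#'   in-batch negatives.
#' @param symmetric Use the mean of the name->definition and
#'   definition->name directions of the loss.
#' @param epochs Contrastive epochs; each epoch takes
#'   `floor(nrow(corpus) / batch_size)` SGD steps.
#' @param learning_rate SGD step size for the encoder parameters.
#' @param seed Master seed for batch sampling.
#' @param adapt_before,adapt_after Run the STS adaptation sub-phase before /
#'   after the contrastive epochs (skipped when no STS data is supplied).
#' @param sts_steps Gradient steps per STS adaptation sub-phase.
#' @param sts_learning_rate Step size for the STS adaptation.
#' @return A list of class `contrastive_config`.
#' @export
contrastive_config <- function(batch_size = 32L, temperature = 0.2,
                               symmetric = TRUE, epochs = 40L,
                               learning_rate = 0.2, seed = 0L,
                               adapt_before = TRUE, adapt_after = TRUE,
                               sts_steps = 150L, sts_learning_rate = 0.5) {
  if (batch_size < 2L) stop_input("`batch_size` must be >= 2")
  if (temperature <= 0) stop_input("`temperature` must be positive")
  if (epochs < 0L || learning_rate <= 0) {
    stop_input("`epochs` must be >= 0 and `learning_rate` positive")
  }
  structure(list(batch_size = as.integer(batch_size),
                 temperature = temperature, symmetric = isTRUE(symmetric),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 seed = as.integer(seed),
                 adapt_before = isTRUE(adapt_before),
                 adapt_after = isTRUE(adapt_after),
                 sts_steps = as.integer(sts_steps),
                 sts_learning_rate = sts_learning_rate),
            class = "contrastive_config")
}

#' Sample a contrastive batch
#'
#' Draws `B` pairs with pairwise-distinct concept ids: concepts are sampled
#' uniformly without replacement among the distinct ids of the corpus, then
#' one pair is drawn uniformly among each selected concept's pairs. Uses
#' the current RNG state; wrap in a seeded context for reproducibility.
#'
#' @param corpus Corpus data frame from [build_contrastive_corpus()].
#' @param B Batch size; must not exceed the number of distinct concepts.
#' @return List with `anchors`, `positives` (character) and `concept_ids`.
#' @export
sample_batch <- function(corpus, B) {
  idx <- split(seq_len(nrow(corpus)), corpus$concept_id)
  sample_batch_indexed(corpus, idx, B)
}

# fast path used by the training loop: concept index precomputed once
sample_batch_indexed <- function(corpus, idx, B) {
  if (length(idx) < B) {
    stop_input("corpus has %d distinct concepts, cannot sample a batch of %d",
               length(idx), B)
  }
  chosen <- sample.int(length(idx), B)
  rows <- vapply(idx[chosen], function(r) {
    if (length(r) == 1L) r else r[sample.int(length(r), 1L)]
  }, 0L)
  list(anchors = corpus$anchor_text[rows],
       positives = corpus$positive_text[rows],
       concept_ids = corpus$concept_id[rows])
}

#' InfoNCE loss over in-batch negatives
#'
#' Given B unit-norm anchor embeddings and their B positives, forms the
#' B x B cosine-similarity matrix divided by `temperature` and returns the
#' mean cross-entropy of its row-wise softmax with the diagonal as the true
#' class. With `symmetric = TRUE`, the mean of the row-wise
#' (name -> definition) and column-wise (definition -> name) directions.
#' A single-pair batch has one logit and therefore loss 0.
#'
#' @param anchor_embs,positive_embs Matrices of B unit-norm rows.
#' @param temperature Positive temperature.
#' @param symmetric Average both softmax directions.
#' @return Non-negative finite scalar.
#' @export
info_nce_loss <- function(anchor_embs, positive_embs, temperature = 0.05,
                          symmetric = TRUE) {
  check_nce_inputs(anchor_embs, positive_embs, temperature)
  info_nce_core(anchor_embs, positive_embs, temperature, symmetric,
                want_grad = FALSE)$loss
}

check_nce_inputs <- function(A, P, temperature) {
  if (!is.matrix(A) || !is.matrix(P) || nrow(A) == 0L) {
    stop_input("embedding inputs must be non-empty matrices")
  }
  if (!all(dim(A) == dim(P))) stop_input("anchor/positive shape mismatch")
  if (temperature <= 0) stop_input("`temperature` must be positive")
  dev <- max(abs(sqrt(rowSums(A^2)) - 1), abs(sqrt(rowSums(P^2)) - 1))
  if (dev > 1e-3) {
    stop_input("embeddings must be unit-normalized (max norm deviation %.2g)",
               dev)
  }
  invisible(TRUE)
}

# loss and, optionally, gradients w.r.t. the (normalized) embeddings
info_nce_core <- function(A, P, tau, symmetric, want_grad) {
  B <- nrow(A)
  S <- tcrossprod(A, P) / tau
  # row direction: softmax over each row, diagonal is the true class
  row_max <- apply(S, 1L, max)
  lse_r <- row_max + log(rowSums(exp(S - row_max)))
  loss_r <- mean(lse_r - diag(S))
  Pr <- exp(S - lse_r)  # row-softmax (recycled by column; S - lse_r per row)
  if (symmetric) {
    col_max <- apply(S, 2L, max)
    lse_c <- col_max + log(colSums(exp(sweep(S, 2L, col_max))))
    loss_c <- mean(lse_c - diag(S))
    Pc <- exp(sweep(S, 2L, lse_c))
    loss <- (loss_r + loss_c) / 2
  } else {
    loss <- loss_r
  }
  if (!want_grad) return(list(loss = loss))
  I <- diag(B)
  G_S <- (Pr - I) / B
  if (symmetric) G_S <- (G_S + (Pc - I) / B) / 2
  list(loss = loss,
       dA = G_S %*% P / tau,
       dP = crossprod(G_S, A) / tau)
}

# --- reference-encoder autodiff helpers -------------------------------------

# forward pass keeping the pre-normalization activations
ref_forward <- function(W, X) {
  Z <- t(W %*% X)
  nrm <- sqrt(rowSums(Z^2))
  nrm[nrm == 0] <- 1
  list(E = Z / nrm, nrm = nrm)
}

# gradient w.r.t. W given the gradient w.r.t. the normalized embeddings
ref_grad_W <- function(fwd, X, G_E) {
  G_Z <- (G_E - rowSums(G_E * fwd$E) * fwd$E) / fwd$nrm
  crossprod(G_Z, t(X))
}

check_reference_encoder <- function(enc) {
  if (!inherits(enc, "lord_encoder")) {
    stop_input("training requires the trainable reference encoder")
  }
  invisible(enc)
}

# featurize every unique text once; returns the feature matrix and a lookup
feature_cache <- function(enc, texts) {
  uniq <- unique(texts)
  X <- featurize_texts(uniq, enc$hash_buckets, enc$ngram)
  list(X = X, index = function(t) match(t, uniq))
}

#' One STS adaptation step
#'
#' Performs a single full-batch gradient step minimizing the mean squared
#' error between the cosine similarity of each sentence pair and its gold
#' score rescaled to `[0, 1]` (gold / 5).
#'
#' @param enc A trainable reference encoder.
#' @param pairs Data frame with `sentence1`, `sentence2`, `gold` in `[0, 5]`.
#' @param learning_rate Step size.
#' @return List with the updated `encoder` and the pre-step `loss`.
#' @export
sts_adaptation_step <- function(enc, pairs, learning_rate = 0.5) {
  check_reference_encoder(enc)
  if (any(pairs$gold < 0 | pairs$gold > 5)) {
    stop_input("gold STS scores must lie in [0, 5]")
  }
  cache <- feature_cache(enc, c(pairs$sentence1, pairs$sentence2))
  res <- sts_step_cached(enc$params$W, cache$X,
                         cache$index(pairs$sentence1),
                         cache$index(pairs$sentence2),
                         pairs$gold / 5, learning_rate)
  enc$params$W <- res$W
  list(encoder = enc, loss = res$loss)
}

sts_step_cached <- function(W, X, i1, i2, target, lr) {
  n <- length(i1)
  X1 <- X[, i1, drop = FALSE]
  X2 <- X[, i2, drop = FALSE]
  f1 <- ref_forward(W, X1)
  f2 <- ref_forward(W, X2)
  cs <- rowSums(f1$E * f2$E)
  resid <- cs - target
  loss <- mean(resid^2)
  g <- 2 * resid / n
  G1 <- g * f2$E
  G2 <- g * f1$E
  GW <- ref_grad_W(f1, X1, G1) + ref_grad_W(f2, X2, G2)
  list(W = W - lr * GW, loss = loss)
}

#' Run the contrastive phase
#'
#' Executes, in order: STS adaptation (if configured and `sts_data` given),
#' the contrastive epochs, and a second STS adaptation. Each sub-phase is
#' skippable; with everything disabled the encoder is returned unchanged.
#' The run is bit-reproducible from `cfg$seed`. The loss history of all
#' sub-phases is attached as `attr(, "history")`, a data frame with
#' `phase`, `epoch`, `step`, `loss`.
#'
#' @param enc A trainable reference encoder (the base model).
#' @param corpus Contrastive corpus data frame.
#' @param sts_data Optional STS data frame (`sentence1`, `sentence2`,
#'   `gold`).
#' @param cfg A [contrastive_config()].
#' @return The trained encoder with a `history` attribute.
#' @export
train_contrastive_phase <- function(enc, corpus, sts_data = NULL,
                                    cfg = contrastive_config()) {
  check_reference_encoder(enc)
  stopifnot(inherits(cfg, "contrastive_config"))
  history <- list()
  log_row <- function(phase, epoch, step, loss) {
    history[[length(history) + 1L]] <<-
      data.frame(phase = phase, epoch = epoch, step = step, loss = loss)
  }

  run_adaptation <- function(enc, tag) {
    if (is.null(sts_data) || cfg$sts_steps < 1L) return(enc)
    cache <- feature_cache(enc, c(sts_data$sentence1, sts_data$sentence2))
    i1 <- cache$index(sts_data$sentence1)
    i2 <- cache$index(sts_data$sentence2)
    if (any(sts_data$gold < 0 | sts_data$gold > 5)) {
      stop_input("gold STS scores must lie in [0, 5]")
    }
    W <- enc$params$W
    for (s in seq_len(cfg$sts_steps)) {
      res <- sts_step_cached(W, cache$X, i1, i2, sts_data$gold / 5,
                             cfg$sts_learning_rate)
      W <- res$W
      if (s %% 10L == 1L || s == cfg$sts_steps) log_row(tag, 1L, s, res$loss)
    }
    enc$params$W <- W
    enc
  }

  with_seed(cfg$seed, {
    if (cfg$adapt_before) enc <- run_adaptation(enc, "sts_before")

    if (cfg$epochs > 0L && nrow(corpus) > 0L) {
      cache <- feature_cache(enc, c(corpus$anchor_text, corpus$positive_text))
      ia <- cache$index(corpus$anchor_text)
      ip <- cache$index(corpus$positive_text)
      idx <- split(seq_len(nrow(corpus)), corpus$concept_id)
      steps <- max(1L, nrow(corpus) %/% cfg$batch_size)
      W <- enc$params$W
      for (ep in seq_len(cfg$epochs)) {
        ep_loss <- 0
        for (s in seq_len(steps)) {
          b <- sample_batch_rows(idx, cfg$batch_size)
          Xa <- cache$X[, ia[b], drop = FALSE]
          Xp <- cache$X[, ip[b], drop = FALSE]
          fa <- ref_forward(W, Xa)
          fp <- ref_forward(W, Xp)
          g <- info_nce_core(fa$E, fp$E, cfg$temperature, cfg$symmetric,
                             want_grad = TRUE)
          GW <- ref_grad_W(fa, Xa, g$dA) + ref_grad_W(fp, Xp, g$dP)
          W <- W - cfg$learning_rate * GW
          ep_loss <- ep_loss + g$loss
        }
        log_row("contrastive", ep, steps, ep_loss / steps)
      }
      enc$params$W <- W
    }

    if (cfg$adapt_after) enc <- run_adaptation(enc, "sts_after")
  })

  attr(enc, "history") <- if (length(history)) {
    do.call(rbind, history)
  } else {
    data.frame(phase = character(0), epoch = integer(0), step = integer(0),
               loss = numeric(0))
  }
  enc
}

# row indices of a batch with distinct concepts (see sample_batch)
sample_batch_rows <- function(idx, B) {
  if (length(idx) < B) {
    stop_input("corpus has %d distinct concepts, cannot sample a batch of %d",
               length(idx), B)
  }
  chosen <- sample.int(length(idx), B)
  vapply(idx[chosen], function(r) {
    if (length(r) == 1L) r else r[sample.int(length(r), 1L)]
  }, 0L)
}
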