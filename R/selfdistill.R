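# Phase 2: supervised self-distillation.
#
# The contrastive model (teacher) embeds each concept's name and one
# definition; the two vectors are averaged into a per-concept embedding,
# compressed with PCA, and a fresh base encoder (student) plus a randomly
# initialized linear projection head are trained with MSE so that every
# textual variant of a concept regresses to that concept's reduced target.
# The head is discarded at export: the deliverable is the student's own
# full-dimension embedding.

#' Build the per-concept teacher embedding bank
#'
#' Embeds, for every concept of the graph, its preferred name and one
#' definition chosen by `definition_policy` (default: first generated
#' definition, else first human one), and stores their elementwise average.
#' Concepts with no definition use the name embedding for both slots, so
#' their average equals the name embedding.
#'
#' @param teacher An encoder (typically the contrastive model).
#' @param graph A validated `knowledge_graph`.
#' @param definition_policy `"generated_first"` or `"human_first"`.
#' @return Object of class `concept_bank`: list of matrices `name_emb`,
#'   `def_emb`, `averaged` (one row per concept, rownames = concept ids).
#' @export
build_concept_embedding_bank <- function(teacher, graph,
                                         definition_policy = c("generated_first",
                                                               "human_first")) {
  definition_policy <- match.arg(definition_policy)
  validate_knowledge_graph(graph)
  ids <- kg_concept_ids(graph)
  names_txt <- vapply(ids, function(id) preferred_name(graph, id), "")
  defs_txt <- vapply(ids, function(id) {
    pick_definition(kg_get_concept(graph, id), definition_policy)
  }, "")
  has_def <- nzchar(defs_txt)
  name_emb <- encode_texts(teacher, names_txt)
  def_emb <- name_emb
  if (any(has_def)) {
    def_emb[has_def, ] <- encode_texts(teacher, defs_txt[has_def])
  }
  averaged <- (name_emb + def_emb) / 2
  rownames(name_emb) <- rownames(def_emb) <- rownames(averaged) <- ids
  structure(list(name_emb = name_emb, def_emb = def_emb, averaged = averaged),
            class = "concept_bank")
}

pick_definition <- function(concept, policy) {
  defs <- concept$definitions
  if (!nrow(defs)) return("")
  order_src <- if (policy == "generated_first") {
    c("generated", "human")
  } else {
    c("human", "generated")
  }
  for (src in order_src) {
    hit <- which(defs$source == src)
    if (length(hit)) return(defs$text[hit[[1L]]])
  }
  defs$text[[1L]]
}

#' Fit the PCA compression of the embedding bank
#'
#' Principal component analysis of the averaged per-concept embeddings
#' (centered, unscaled). Components follow a fixed sign convention (the
#' largest-magnitude coordinate of each component is positive) so repeated
#' fits are reproducible.
#'
#' @param bank A `concept_bank`.
#' @param d Target dimension (default 64); must not exceed the number of
#'   bank entries or the embedding dimension.
#' @return Object of class `pca_transform`: `mean` (length D),
#'   `components` (d x D, orthonormal rows), `eigenvalues` (top d sample
#'   covariance eigenvalues) and `explained_variance` (fractions of total
#'   variance, non-increasing).
#' @export
fit_pca <- function(bank, d = 64L) {
  stopifnot(inherits(bank, "concept_bank"))
  X <- bank$averaged
  if (d < 1L) stop_input("`d` must be >= 1")
  if (nrow(X) < d) {
    stop_input("PCA rank error: %d entries cannot support d = %d", nrow(X), d)
  }
  if (ncol(X) < d) {
    stop_input("`d` (%d) exceeds the embedding dimension (%d)", d, ncol(X))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  comp <- t(pc$rotation[, seq_len(d), drop = FALSE])
  # sign convention: largest-|coordinate| of each component made positive
  for (i in seq_len(d)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  ev <- pc$sdev^2
  structure(list(mean = unname(pc$center), components = unname(comp),
                 d = as.integer(d),
                 eigenvalues = ev[seq_len(d)],
                 explained_variance = ev[seq_len(d)] / sum(ev)),
            class = "pca_transform")
}

#' Project vectors with a fitted PCA transform
#'
#' @param pca A `pca_transform`.
#' @param X Matrix with one D-dimensional vector per row.
#' @return Matrix of d-dimensional projections `components (x - mean)`.
#' @export
pca_project <- function(pca, X) {
  stopifnot(inherits(pca, "pca_transform"))
  if (ncol(X) != length(pca$mean)) {
    stop_input("dimension mismatch: data has %d columns, PCA expects %d",
               ncol(X), length(pca$mean))
  }
  sweep(X, 2L, pca$mean) %*% t(pca$components)
}

#' Build the per-concept distillation targets
#'
#' Projects each concept's averaged teacher embedding through the fitted
#' PCA transform. Both the name variant and the definition variant of a
#' concept regress to this one target during distillation. With
#' `normalize = TRUE` (the default) each target is rescaled to unit norm
#' after projection: since the student emits unit-norm embeddings and the
#' projection head is (near-)isometric, unit targets make an exact fit
#' attainable and force the fitted geometry into the student's embedding
#' space.
#'
#' @param bank A `concept_bank`.
#' @param pca A `pca_transform` fitted on the same embedding dimension.
#' @param normalize Rescale each projected target to unit norm.
#' @return Numeric matrix (concepts x d) with concept ids as rownames.
#' @export
make_distillation_targets <- function(bank, pca, normalize = TRUE) {
  stopifnot(inherits(bank, "concept_bank"))
  tg <- pca_project(pca, bank$averaged)
  if (normalize) {
    nrm <- sqrt(rowSums(tg^2))
    nrm[nrm == 0] <- 1
    tg <- tg / nrm
  }
  tg
}

#' Random linear projection head
#'
#' A randomly initialized linear map from the student's embedding space to
#' the target space. The weights are drawn as a random partial isometry
#' (orthonormal rows, obtained by QR decomposition of a seeded Gaussian
#' matrix): a head that starts — and, under the small head learning rate
#' of [distill_config()], stays — angle-preserving, so the geometry of the
#' targets must be realized in the student's own embedding space rather
#' than absorbed by the head.
#'
#' @param d Output (target) dimension.
#' @param dimension Input (student embedding) dimension D (>= `d`).
#' @param seed Seed for the random initialization.
#' @return Object of class `projection_head` with `weights` (d x D,
#'   orthonormal rows), `bias` (length d, zeros) and the seed.
#' @export
new_projection_head <- function(d, dimension, seed = 0L) {
  stopifnot(d >= 1L, dimension >= d)
  W <- with_seed(seed, {
    M <- matrix(stats::rnorm(dimension * d), nrow = dimension, ncol = d)
    t(qr.Q(qr(M)))
  })
  structure(list(weights = W, bias = numeric(d), seed = as.integer(seed)),
            class = "projection_head")
}

#' Textual variants used for distillation
#'
#' Enumerates the training variants of a graph: all names of every concept
#' plus its definitions (both sources), optionally extended with relation
#' verbalizations. All variants of a concept regress to the same target.
#'
#' @param graph A `knowledge_graph`.
#' @param include_templates Also emit relation verbalizations.
#' @param templates,fallback Passed to [verbalize_relation()] when
#'   `include_templates` is set.
#' @return Data frame `(concept_id, text, source_kind)`.
#' @export
build_distillation_variants <- function(graph, include_templates = FALSE,
                                        templates = default_relation_templates(),
                                        fallback = default_fallback_template()) {
  out <- list()
  for (co in graph$concepts) {
    out[[length(out) + 1L]] <- textual_variant(co$concept_id, co$names, "name")
    if (nrow(co$definitions)) {
      out[[length(out) + 1L]] <-
        textual_variant(co$concept_id, co$definitions$text,
                        paste0(co$definitions$source, "_definition"))
    }
  }
  if (include_templates && nrow(graph$relations)) {
    for (i in seq_len(nrow(graph$relations))) {
      out[[length(out) + 1L]] <-
        verbalize_relation(graph$relations[i, ], graph, templates, fallback)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Configuration for the self-distillation phase
#'
#' @param epochs Full-batch gradient steps.
#' @param learning_rate Step size for the student's encoder parameters.
#' @param head_learning_rate Step size for the projection head; much
#'   smaller than `learning_rate` by default so the head stays close to
#'   its (near-isometric) initialization and the student's own embedding
#'   space, rather than the head, absorbs the target geometry.
#' @param momentum Classical momentum coefficient in `[0, 1)`.
#' @param seed Seed recorded for the run (the only randomness is the head
#'   initialization, already fixed by the head's own seed).
#' @export
distill_config <- function(epochs = 1600L, learning_rate = 2.0,
                           head_learning_rate = learning_rate / 100,
                           momentum = 0.95, seed = 0L) {
  stopifnot(epochs >= 0L, learning_rate > 0, head_learning_rate >= 0,
            momentum >= 0, momentum < 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 head_learning_rate = head_learning_rate,
                 momentum = momentum, seed = as.integer(seed)),
            class = "distill_config")
}

#' Train the self-distillation student
#'
#' Minimizes the mean squared error between `head(student(text))` and the
#' concept's d-dimensional target, over all textual variants, by full-batch
#' gradient descent on the student's parameters and the head jointly. The
#' student should be a fresh base encoder that has not undergone the
#' contrastive phase. With `epochs = 0` both are returned unchanged.
#'
#' @param student A trainable reference encoder.
#' @param head A [new_projection_head()] matching the student dimension and
#'   target dimension.
#' @param variants Data frame `(concept_id, text, source_kind)`; every
#'   concept id must have a row in `targets`.
#' @param targets Target matrix from [make_distillation_targets()].
#' @param cfg A [distill_config()].
#' @return List `(student, head)` with the training `history` (epoch, loss)
#'   attached to the student.
#' @export
train_self_distillation <- function(student, head, variants, targets,
                                    cfg = distill_config()) {
  check_reference_encoder(student)
  stopifnot(inherits(head, "projection_head"), inherits(cfg, "distill_config"))
  missing <- setdiff(unique(variants$concept_id), rownames(targets))
  if (length(missing)) {
    stop_input("variant has no distillation target for concept %s",
               missing[[1L]])
  }
  if (nrow(head$weights) != ncol(targets) ||
      ncol(head$weights) != student$dimension) {
    stop_input("projection head shape (%d x %d) does not match student D=%d, d=%d",
               nrow(head$weights), ncol(head$weights), student$dimension,
               ncol(targets))
  }
  T_ <- targets[variants$concept_id, , drop = FALSE]
  n <- nrow(T_)
  d <- ncol(T_)
  cache <- feature_cache(student, variants$text)
  X <- cache$X[, cache$index(variants$text), drop = FALSE]
  W <- student$params$W
  A <- head$weights
  b <- head$bias
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  vA <- A * 0; vb <- b * 0; vW <- W * 0
  for (ep in seq_len(cfg$epochs)) {
    fwd <- ref_forward(W, X)
    P <- fwd$E %*% t(A) + matrix(b, n, d, byrow = TRUE)
    R <- P - T_
    loss <- mean(R^2)
    G_P <- 2 * R / (n * d)
    G_A <- crossprod(G_P, fwd$E)
    G_b <- colSums(G_P)
    G_E <- G_P %*% A
    G_W <- ref_grad_W(fwd, X, G_E)
    vA <- cfg$momentum * vA + G_A
    vb <- cfg$momentum * vb + G_b
    vW <- cfg$momentum * vW + G_W
    A <- A - cfg$head_learning_rate * vA
    b <- b - cfg$head_learning_rate * vb
    W <- W - cfg$learning_rate * vW
    if (ep %% 25L == 1L || ep == cfg$epochs) {
      history <- rbind(history, data.frame(epoch = ep, loss = loss))
    }
  }
  student$params$W <- W
  head$weights <- A
  head$bias <- b
  attr(student, "history") <- history
  list(student = student, head = head)
}
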