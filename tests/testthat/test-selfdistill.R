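test_that("bank averages equal an explicit elementwise loop over name and definition", {
  g <- toy_graph()
  enc <- make_reference_encoder(8, 256, seed = 2)
  bank <- build_concept_embedding_bank(enc, g, "human_first")
  for (id in kg_concept_ids(g)) {
    co <- kg_get_concept(g, id)
    e_name <- encode_texts(enc, co$names[1])[1, ]
    has_def <- nrow(co$definitions) > 0
    e_def <- if (has_def) {
      encode_texts(enc, co$definitions$text[co$definitions$source == "human"][1])[1, ]
    } else {
      e_name
    }
    avg <- numeric(8)
    for (k in 1:8) avg[k] <- (e_name[k] + e_def[k]) / 2
    expect_equal(unname(bank$averaged[id, ]), avg, tolerance = 1e-9)
  }
  # a concept with no definition averages to its own name embedding
  expect_equal(bank$averaged["C002", ], bank$name_emb["C002", ],
               tolerance = 1e-12)
})

test_that("the definition policy prefers generated then human (and vice versa)", {
  g <- toy_graph()
  agct <- write_psv(list(c("C001", "a generated gloss")))
  g <- attach_generated_definitions(g, agct)
  enc <- make_reference_encoder(8, 256, seed = 2)
  b_gen <- build_concept_embedding_bank(enc, g, "generated_first")
  b_hum <- build_concept_embedding_bank(enc, g, "human_first")
  e_gen <- encode_texts(enc, "a generated gloss")[1, ]
  expect_equal(unname(b_gen$def_emb["C001", ]), unname(e_gen),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(b_hum$def_emb["C001", ],
                                b_gen$def_emb["C001", ])))
})

test_that("PCA matches an independent covariance eigendecomposition", {
  withr::with_seed(5, {
    X <- matrix(stats::rnorm(50 * 8), 50, 8) %*% diag(c(4, 3, 2, 1.5, 1, 0.5, 0.2, 0.1))
    bank <- structure(list(averaged = X), class = "concept_bank")
    pca <- fit_pca(bank, 3)
    eig <- eigen(stats::cov(X), symmetric = TRUE)
    expect_equal(pca$eigenvalues, eig$values[1:3], tolerance = 1e-8)
    for (i in 1:3) {
      v <- eig$vectors[, i]
      # components agree up to sign
      expect_equal(abs(sum(pca$components[i, ] * v)), 1, tolerance = 1e-8)
    }
    expect_true(all(diff(pca$explained_variance) <= 1e-12))
    # orthonormal rows
    expect_equal(tcrossprod(pca$components), diag(3), tolerance = 1e-8)
  })
})

test_that("data in a d-dimensional subspace reconstructs exactly; d = D is invertible", {
  withr::with_seed(6, {
    basis <- qr.Q(qr(matrix(stats::rnorm(8 * 3), 8, 3)))
    X <- matrix(stats::rnorm(40 * 3), 40, 3) %*% t(basis) +
      matrix(stats::rnorm(8), 40, 8, byrow = TRUE)
    bank <- structure(list(averaged = X), class = "concept_bank")
    pca <- fit_pca(bank, 3)
    Z <- pca_project(pca, X)
    recon <- Z %*% pca$components +
      matrix(pca$mean, nrow(X), 8, byrow = TRUE)
    expect_equal(recon, X, tolerance = 1e-8)

    Xf <- matrix(stats::rnorm(30 * 5), 30, 5)
    bf <- structure(list(averaged = Xf), class = "concept_bank")
    pf <- fit_pca(bf, 5)
    Zf <- pca_project(pf, Xf)
    expect_equal(Zf %*% pf$components + matrix(pf$mean, 30, 5, byrow = TRUE),
                 Xf, tolerance = 1e-8)
  })
})

test_that("PCA rank and dimension errors are raised", {
  bank <- structure(list(averaged = matrix(0, 5, 8)), class = "concept_bank")
  expect_error(fit_pca(bank, 6), "rank error")
  expect_error(fit_pca(structure(list(averaged = matrix(stats::rnorm(80), 10, 8)),
                                 class = "concept_bank"), 9),
               "dimension")
})

test_that("the PCA sign convention makes repeated fits identical", {
  withr::with_seed(8, {
    X <- matrix(stats::rnorm(30 * 6), 30, 6)
    bank <- structure(list(averaged = X), class = "concept_bank")
    p1 <- fit_pca(bank, 4)
    p2 <- fit_pca(structure(list(averaged = X[sample(30), ]),
                            class = "concept_bank"), 4)
    expect_equal(p1$components, p2$components, tolerance = 1e-8)
    expect_true(all(apply(p1$components, 1,
                          function(r) r[which.max(abs(r))] > 0)))
  })
})

test_that("targets follow the matrix formula and center to zero at the mean", {
  g <- toy_graph()
  enc <- make_reference_encoder(8, 256, seed = 3)
  bank <- build_concept_embedding_bank(enc, g)
  pca <- fit_pca(bank, 2)
  raw <- make_distillation_targets(bank, pca, normalize = FALSE)
  for (i in seq_len(nrow(raw))) {
    expect_equal(unname(raw[i, ]),
                 unname(as.numeric(pca$components %*%
                                     (bank$averaged[i, ] - pca$mean))),
                 tolerance = 1e-9)
  }
  # an averaged vector equal to the PCA mean projects to the zero vector
  at_mean <- pca_project(pca, matrix(pca$mean, 1))
  expect_equal(as.numeric(at_mean), c(0, 0), tolerance = 1e-12)
  # normalized targets are unit rows
  tg <- make_distillation_targets(bank, pca)
  expect_equal(unname(sqrt(rowSums(tg^2))), rep(1, nrow(tg)),
               tolerance = 1e-9)
})

test_that("total variance of raw targets equals the sum of the top-d eigenvalues", {
  withr::with_seed(9, {
    X <- matrix(stats::rnorm(40 * 8), 40, 8)
    bank <- structure(list(averaged = X), class = "concept_bank")
    pca <- fit_pca(bank, 3)
    tg <- pca_project(pca, X)
    expect_equal(sum(apply(tg, 2, stats::var)), sum(pca$eigenvalues),
                 tolerance = 1e-6)
  })
})

test_that("the projection head is a seeded random partial isometry", {
  h1 <- new_projection_head(4, 12, seed = 3)
  h2 <- new_projection_head(4, 12, seed = 3)
  h3 <- new_projection_head(4, 12, seed = 4)
  expect_identical(h1$weights, h2$weights)
  expect_false(identical(h1$weights, h3$weights))
  expect_equal(tcrossprod(h1$weights), diag(4), tolerance = 1e-9)
  expect_equal(h1$bias, numeric(4))
})

test_that("zero-epoch distillation leaves the student untouched; missing targets error", {
  g <- toy_graph()
  enc <- make_reference_encoder(8, 256, seed = 1)
  bank <- build_concept_embedding_bank(enc, g)
  pca <- fit_pca(bank, 2)
  targets <- make_distillation_targets(bank, pca)
  variants <- build_distillation_variants(g)
  fit <- train_self_distillation(enc, new_projection_head(2, 8, 1),
                                 variants, targets,
                                 distill_config(epochs = 0))
  expect_identical(fit$student$params, enc$params)

  orphan <- rbind(variants,
                  data.frame(concept_id = "C999", text = "stray",
                             source_kind = "name"))
  expect_error(train_self_distillation(enc, new_projection_head(2, 8, 1),
                                       orphan, targets, distill_config()),
               "C999")
})

test_that("name and definition variants of a concept regress to one identical target", {
  g <- toy_graph()
  enc <- make_reference_encoder(8, 256, seed = 1)
  bank <- build_concept_embedding_bank(enc, g)
  targets <- make_distillation_targets(bank, fit_pca(bank, 2))
  variants <- build_distillation_variants(g)
  for (id in unique(variants$concept_id)) {
    rows <- variants$concept_id == id
    tg <- targets[variants$concept_id[rows], , drop = FALSE]
    expect_true(all(apply(tg, 2, function(col) all(col == col[1]))))
  }
})

test_that("a single-concept fit drives the training loss to zero", {
  enc <- make_reference_encoder(8, 256, seed = 2)
  variants <- data.frame(concept_id = "C1", text = "only name",
                         source_kind = "name")
  target <- matrix(c(1, 0) / 1, 1, 2, dimnames = list("C1", NULL))
  fit <- train_self_distillation(enc, new_projection_head(2, 8, 1),
                                 variants, target,
                                 distill_config(epochs = 300,
                                                learning_rate = 0.5,
                                                momentum = 0.9))
  h <- attr(fit$student, "history")
  expect_lt(h$loss[nrow(h)], 1e-4)
})
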