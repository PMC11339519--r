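make_pair_corpus <- function(n_concepts, pairs_per_concept = 2L) {
  ids <- sprintf("C%02d", seq_len(n_concepts))
  data.frame(
    concept_id = rep(ids, each = pairs_per_concept),
    anchor_text = rep(paste0("name", seq_len(n_concepts)),
                      each = pairs_per_concept),
    positive_text = paste0("def", rep(seq_len(n_concepts),
                                      each = pairs_per_concept), "v",
                           rep(seq_len(pairs_per_concept), n_concepts)),
    source_kind = "human_definition",
    stringsAsFactors = FALSE
  )
}

test_that("batches contain pairwise-distinct concepts; exhaustive when B equals them", {
  corpus <- make_pair_corpus(6)
  withr::with_seed(1, {
    for (i in 1:20) {
      b <- sample_batch(corpus, 6L)
      expect_equal(length(unique(b$concept_ids)), 6L)
      expect_setequal(b$concept_ids, unique(corpus$concept_id))
    }
  })
  expect_error(sample_batch(corpus, 7L), "distinct concepts")
})

test_that("per-concept sampling frequencies are uniform (chi-square)", {
  corpus <- make_pair_corpus(5)
  counts <- integer(5)
  names(counts) <- unique(corpus$concept_id)
  withr::with_seed(42, {
    for (i in seq_len(10000L)) {
      b <- sample_batch(corpus, 2L)
      counts[b$concept_ids] <- counts[b$concept_ids] + 1L
    }
  })
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("single-pair batches have loss exactly zero", {
  a <- unit_rows(1, 4)
  expect_equal(info_nce_loss(a, a, temperature = 1), 0)
})

test_that("the two-pair orthogonal identity case matches -ln(e/(e+1)) per direction", {
  A <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  expected <- -log(exp(1) / (exp(1) + 1))
  expect_equal(info_nce_loss(A, A, temperature = 1, symmetric = FALSE),
               expected, tolerance = 1e-6)
  expect_equal(info_nce_loss(A, A, temperature = 1, symmetric = TRUE),
               expected, tolerance = 1e-6)
})

test_that("the loss matches a brute-force loop oracle on random batches", {
  withr::with_seed(7, {
    for (B in c(2L, 4L, 8L)) {
      for (rep in 1:5) {
        A <- unit_rows(B, 6)
        P <- unit_rows(B, 6)
        for (sym in c(TRUE, FALSE)) {
          expect_equal(info_nce_loss(A, P, temperature = 0.2, symmetric = sym),
                       brute_force_infonce(A, P, 0.2, sym),
                       tolerance = 1e-6)
        }
      }
    }
  })
})

test_that("the loss validates its inputs", {
  A <- unit_rows(3, 4)
  expect_error(info_nce_loss(A[0, , drop = FALSE], A[0, , drop = FALSE]),
               "non-empty")
  expect_error(info_nce_loss(A * 2, A, temperature = 1), "unit-normalized")
  expect_error(info_nce_loss(A, A, temperature = 0), "positive")
})

test_that("the loss is permutation-equivariant and direction-consistent", {
  withr::with_seed(11, {
    A <- unit_rows(5, 8)
    P <- unit_rows(5, 8)
    l <- info_nce_loss(A, P, 0.1, symmetric = TRUE)
    perm <- sample(5)
    expect_equal(info_nce_loss(A[perm, ], P[perm, ], 0.1, symmetric = TRUE),
                 l, tolerance = 1e-9)
    # asymmetric loss equals the row-direction term of the symmetric pair
    lr <- info_nce_loss(A, P, 0.1, symmetric = FALSE)
    lc <- info_nce_loss(P, A, 0.1, symmetric = FALSE)
    expect_equal((lr + lc) / 2, l, tolerance = 1e-9)
  })
})

test_that("STS gold maps to [0,1] targets and out-of-range gold is rejected", {
  enc <- make_reference_encoder(8, 128, seed = 1)
  bad <- data.frame(sentence1 = "a b", sentence2 = "c d", gold = 6)
  expect_error(sts_adaptation_step(enc, bad, 0.1), "\\[0, 5\\]")
  # a gold of 5 pulls the cosine toward 1, a gold of 0 toward 0
  pull <- function(gold) {
    e <- enc
    pr <- data.frame(sentence1 = "shared words here",
                     sentence2 = "shared words there", gold = gold)
    c0 <- sum(encode_texts(e, pr$sentence1) * encode_texts(e, pr$sentence2))
    for (i in 1:100) e <- sts_adaptation_step(e, pr, 0.5)$encoder
    c1 <- sum(encode_texts(e, pr$sentence1) * encode_texts(e, pr$sentence2))
    c(c0, c1)
  }
  up <- pull(5)
  expect_gt(up[2], up[1])
  expect_equal(up[2], 1, tolerance = 0.05)
  down <- pull(0)
  expect_lt(down[2], down[1])
  expect_equal(down[2], 0, tolerance = 0.05)
})

test_that("a single pair's cosine moves monotonically toward its target", {
  enc <- make_reference_encoder(8, 128, seed = 3)
  pr <- data.frame(sentence1 = "aaab bbb", sentence2 = "aaab bbb ccc",
                   gold = 4)
  target <- 4 / 5
  gap <- abs(sum(encode_texts(enc, pr$sentence1) *
                   encode_texts(enc, pr$sentence2)) - target)
  gaps <- gap
  for (i in 1:200) {
    enc <- sts_adaptation_step(enc, pr, 0.3)$encoder
    if (i %% 50 == 0) {
      gaps <- c(gaps, abs(sum(encode_texts(enc, pr$sentence1) *
                                encode_texts(enc, pr$sentence2)) - target))
    }
  }
  expect_true(all(diff(gaps) <= 1e-6))
  expect_lt(gaps[length(gaps)], 0.02)
})

test_that("a fully disabled phase is a no-op and runs are seed-reproducible", {
  cfg0 <- synth_config(n_topics = 2, concepts_per_topic = 4,
                       names_per_concept = 2, vocab_size = 80, seed = 2)
  g <- generate_synthetic_ontology(cfg0)
  corpus <- build_contrastive_corpus(g, seed = 0)
  enc <- make_reference_encoder(16, 512, seed = 4)
  off <- contrastive_config(batch_size = 4, epochs = 0,
                            adapt_before = FALSE, adapt_after = FALSE)
  out <- train_contrastive_phase(enc, corpus, NULL, off)
  expect_identical(out$params, enc$params)

  cfg <- contrastive_config(batch_size = 4, epochs = 3, seed = 9,
                            adapt_before = FALSE, adapt_after = FALSE)
  r1 <- train_contrastive_phase(enc, corpus, NULL, cfg)
  r2 <- train_contrastive_phase(enc, corpus, NULL, cfg)
  expect_identical(r1$params, r2$params)
  expect_identical(attr(r1, "history"), attr(r2, "history"))
})

test_that("the epoch-mean contrastive loss decreases over training", {
  fx <- acceptance_fixture()
  teacher <- acceptance_teacher()
  h <- attr(teacher, "history")
  h <- h[h$phase == "contrastive", ]
  first <- h$loss[1]
  last <- h$loss[nrow(h)]
  expect_lt(last, first * 0.5)
  # monotone on epoch means within a 5% noise tolerance
  expect_true(all(diff(h$loss) <= 0.05 * first))
})
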