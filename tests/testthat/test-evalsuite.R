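test_that("scores proportional (or anti-proportional) to gold give r = +/-1", {
  gold <- c(0, 1.25, 2.5, 3.75, 5)
  enc <- toy_sts_encoder(gold / 5)
  pairs <- data.frame(sentence1 = paste0("a", 1:5),
                      sentence2 = paste0("b", 1:5), gold = gold)
  expect_equal(eval_sts(enc, pairs), 1.0, tolerance = 1e-12)
  anti <- toy_sts_encoder(1 - gold / 5)
  expect_equal(eval_sts(anti, pairs), -1.0, tolerance = 1e-12)
})

test_that("Pearson matches the textbook formula with hand-expanded sums", {
  scores <- c(0.9, 0.1, 0.5, 0.3, 0.7)
  gold <- c(4.5, 1.0, 2.0, 2.5, 3.0)
  enc <- toy_sts_encoder(scores)
  pairs <- data.frame(sentence1 = paste0("a", 1:5),
                      sentence2 = paste0("b", 1:5), gold = gold)
  n <- 5
  sx <- sum(scores); sy <- sum(gold)
  sxx <- sum(scores^2); syy <- sum(gold^2); sxy <- sum(scores * gold)
  manual <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  expect_equal(eval_sts(enc, pairs), manual, tolerance = 1e-9)
})

test_that("degenerate inputs raise undefined-correlation or range errors", {
  enc <- toy_sts_encoder(c(0.5, 0.5))
  flat <- data.frame(sentence1 = paste0("a", 1:2),
                     sentence2 = paste0("b", 1:2), gold = c(3, 3))
  expect_error(eval_sts(enc, flat), "zero variance")
  expect_error(eval_sts(enc, data.frame(sentence1 = "a1", sentence2 = "b1",
                                        gold = 2)), "at least 2")
  expect_error(eval_sts(enc, data.frame(sentence1 = paste0("a", 1:2),
                                        sentence2 = paste0("b", 1:2),
                                        gold = c(6, 2))), "\\[0, 5\\]")
})

test_that("Spearman handles ties by average ranks and matches a rank-then-Pearson oracle", {
  scores <- c(0.9, 0.8, 0.8, 0.4, 0.2, 0.1)
  gold <- c(5, 4, 3.5, 3.5, 1, 0.5)
  enc <- toy_sts_encoder(scores)
  pairs <- data.frame(term1 = paste0("a", 1:6), term2 = paste0("b", 1:6),
                      gold = gold)
  rho <- eval_bcr(enc, pairs)
  # oracle: average ranks, then the Pearson formula
  rx <- rank(scores); ry <- rank(gold)
  manual <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(rho, manual, tolerance = 1e-9)
  # identical and reversed rankings
  ident <- data.frame(term1 = paste0("a", 1:6), term2 = paste0("b", 1:6),
                      gold = scores)
  expect_equal(eval_bcr(enc, ident), 1.0)
  expect_equal(eval_bcr(enc, transform(ident, gold = -gold)), -1.0)
})

test_that("correlations are invariant to monotone rescalings of the gold", {
  withr::with_seed(2, {
    scores <- stats::runif(8)
    gold <- stats::runif(8, 0, 5)
    enc <- toy_sts_encoder(scores)
    sts <- data.frame(sentence1 = paste0("a", 1:8),
                      sentence2 = paste0("b", 1:8), gold = gold)
    bcr <- data.frame(term1 = paste0("a", 1:8), term2 = paste0("b", 1:8),
                      gold = gold)
    expect_equal(eval_sts(enc, transform(sts, gold = gold * 0.9 + 0.3)),
                 eval_sts(enc, sts), tolerance = 1e-12)
    expect_equal(eval_bcr(enc, transform(bcr, gold = gold^3)),
                 eval_bcr(enc, bcr), tolerance = 1e-12)
  })
})

test_that("NEL top-k matches exhaustive cosine-ranking enumeration", {
  fx <- nel_fixture()
  # oracle: exhaustive ranking, concept scored at its best name
  En <- fx$emb / sqrt(rowSums(fx$emb^2))
  oracle_topk <- function(mention, k) {
    sims <- En[mention, , drop = FALSE] %*% t(En[fx$dict$name, ])
    best <- tapply(as.numeric(sims), fx$dict$concept_id, max)
    names(sort(best, decreasing = TRUE))[seq_len(k)]
  }
  for (k in 1:3) {
    hits <- vapply(seq_len(3), function(i) {
      fx$examples$gold_concept_id[i] %in% oracle_topk(fx$examples$mention[i], k)
    }, TRUE)
    expect_equal(as.numeric(eval_nel_topk(fx$enc, fx$examples, fx$dict, k)),
                 mean(hits))
  }
})

test_that("top-k accuracy is non-decreasing in k and exhaustive k is perfect", {
  fx <- nel_fixture()
  accs <- vapply(1:3, function(k) {
    as.numeric(eval_nel_topk(fx$enc, fx$examples, fx$dict, k))
  }, 0)
  expect_true(all(diff(accs) >= 0))
  expect_equal(accs[3], 1.0)
})

test_that("a mention string-equal to a dictionary name is a top-1 hit under an injective encoder", {
  enc <- make_reference_encoder(32, 2048, seed = 5)
  dict <- data.frame(concept_id = c("K1", "K2"),
                     name = c("myocardial infarction", "common cold"),
                     semantic_type = "T")
  ex <- data.frame(mention = "common cold", gold_concept_id = "K2")
  expect_equal(as.numeric(eval_nel_topk(enc, ex, dict, 1)), 1.0)
})

test_that("dictionary order only matters through deterministic tie-breaking", {
  fx <- nel_fixture()
  acc1 <- as.numeric(eval_nel_topk(fx$enc, fx$examples, fx$dict, 1))
  perm <- c(4, 2, 3, 1)
  acc2 <- as.numeric(eval_nel_topk(fx$enc, fx$examples,
                                   fx$dict[perm, ], 1))
  expect_equal(acc1, acc2)
  expect_error(eval_nel_topk(fx$enc, fx$examples, fx$dict[0, ], 1),
               "empty dictionary")
})

test_that("semantic-type filtering removes exactly the excluded gold types", {
  fx <- nel_fixture()
  ex5 <- data.frame(mention = paste0("m", c(1, 2, 3, 1, 2)),
                    gold_concept_id = c("K1", "K2", "K3", "K1", "K2"))
  none <- filter_by_semantic_type(ex5, fx$dict, character(0))
  expect_equal(nrow(none), 5L)
  all_types <- filter_by_semantic_type(ex5, fx$dict, c("T1", "T2", "T3"))
  expect_equal(nrow(all_types), 0L)
  some <- filter_by_semantic_type(ex5, fx$dict, "T2")
  expect_equal(nrow(some), 3L)
  expect_equal(attr(some, "n_removed"), 2L)
  expect_false(any(some$gold_concept_id == "K2"))
})

test_that("benchmark files round-trip and malformed rows carry line numbers", {
  sts <- data.frame(sentence1 = c("a b", "c d"), sentence2 = c("e", "f"),
                    gold = c(1.5, 4), stringsAsFactors = FALSE)
  p <- tempfile(); write_sts_file(sts, p)
  expect_equal(read_sts_file(p), sts)
  writeLines(c("sentence1\tsentence2\tgold", "only\ttwo"), p)
  expect_error(read_sts_file(p), ":2")
  writeLines(c("sentence1\tsentence2\tgold", "a\tb\tnot_a_number"), p)
  expect_error(read_sts_file(p), "non-numeric")

  dict <- data.frame(concept_id = "K1", name = "fever",
                     semantic_type = "T1", stringsAsFactors = FALSE)
  pd <- tempfile(); write_dictionary_file(dict, pd)
  expect_equal(read_dictionary_file(pd), dict)
})
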