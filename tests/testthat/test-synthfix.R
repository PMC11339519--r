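test_that("a zero-topic configuration yields an empty, valid graph", {
  g <- generate_synthetic_ontology(synth_config(n_topics = 0))
  expect_equal(kg_size(g), 0L)
  expect_silent(validate_knowledge_graph(g))
})

test_that("the generator is byte-reproducible from its seed", {
  cfg <- synth_config(n_topics = 2, concepts_per_topic = 3,
                      names_per_concept = 2, vocab_size = 60, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  write_knowledge_graph(generate_synthetic_ontology(cfg), d1)
  write_knowledge_graph(generate_synthetic_ontology(cfg), d2)
  for (fn in c("concepts.psv", "definitions.psv", "relations.psv")) {
    expect_identical(readLines(file.path(d1, fn)),
                     readLines(file.path(d2, fn)))
  }
})

test_that("concept and name counts follow the configuration arithmetic", {
  cfg <- synth_config(n_topics = 3, concepts_per_topic = 4,
                      names_per_concept = 2, vocab_size = 120, seed = 1)
  g <- generate_synthetic_ontology(cfg)
  expect_equal(kg_size(g), 12L)
  expect_equal(sum(vapply(g$concepts, function(co) length(co$names), 0L)),
               24L)
  expect_equal(nrow(attr(g, "synth")$names_df), 24L)
})

test_that("cipher translation is the identity for the identity map and invertible", {
  identity_map <- stats::setNames(c(letters, " "), c(letters, " "))
  expect_equal(cipher_translate("peptic ulcer", identity_map), "peptic ulcer")
  rot <- make_rot_cipher(5)
  inv <- stats::setNames(names(rot), rot)
  txt <- "fracture of the femur"
  expect_equal(cipher_translate(cipher_translate(txt, rot), inv), txt)
})

test_that("a rot-1 cipher maps fever to gfwfs; unknown characters error", {
  expect_equal(cipher_translate("fever", make_rot_cipher(1)), "gfwfs")
  expect_error(cipher_translate("Fever", make_rot_cipher(1)), "'F'")
  expect_error(cipher_translate("x", c(a = "b", b = "a", x = "b")),
               "bijective")
})

test_that("random ciphers are seeded bijections over the alphabet", {
  c1 <- make_random_cipher(3)
  c2 <- make_random_cipher(3)
  expect_identical(c1, c2)
  expect_setequal(unname(c1), c(letters, " "))
  expect_equal(c1[[" "]], " ")
})

test_that("gold scores reflect the latent structure before jitter", {
  cfg <- synth_config(seed = 0)
  g <- generate_synthetic_ontology(cfg)
  bm <- generate_benchmarks(g, cfg)
  latent <- bm$latent
  look <- function(t) latent[match(t, latent$text), ]
  a <- look(bm$sts$sentence1); b <- look(bm$sts$sentence2)
  base_gold <- 5 * ((a$topic == b$topic) + (a$concept == b$concept)) / 2
  expect_true(all(abs(bm$sts$gold - base_gold) <= cfg$jitter + 1e-9))
  # same-concept pairs sit at the top of the scale, cross-topic at the bottom
  expect_true(all(bm$sts$gold[a$concept == b$concept] >= 4.5 - 1e-9))
  expect_true(all(bm$sts$gold[a$topic != b$topic] <= 0.5 + 1e-9))
  expect_true(all(bm$sts$gold >= 0 & bm$sts$gold <= 5))
})

test_that("benchmark sizes follow the configuration", {
  cfg <- synth_config(seed = 0)
  g <- generate_synthetic_ontology(cfg)
  bm <- generate_benchmarks(g, cfg)
  expect_equal(nrow(bm$sts), 3 * ceiling(cfg$n_sts_pairs / 3))
  expect_equal(nrow(bm$bcr), 3 * ceiling(cfg$n_bcr_pairs / 3))
  # one mention per alias synonym
  n_alias <- kg_size(g) * (cfg$names_per_concept - 1)
  expect_equal(nrow(bm$nel_examples), n_alias)
  expect_equal(nrow(bm$dictionary), kg_size(g))
})

test_that("held-out mentions never string-match any dictionary entry", {
  cfg <- synth_config(seed = 0)
  g <- generate_synthetic_ontology(cfg)
  bm <- generate_benchmarks(g, cfg)
  expect_false(any(bm$nel_examples$mention %in% bm$dictionary$name))
})

test_that("the latent oracle encoder attains the designed upper bounds", {
  cfg <- synth_config(seed = 0)
  g <- generate_synthetic_ontology(cfg)
  bm <- generate_benchmarks(g, cfg)
  oracle <- make_oracle_encoder(bm$latent)
  expect_equal(as.numeric(eval_nel_topk(oracle, bm$nel_examples,
                                        bm$dictionary, 1)), 1.0)
  expect_gte(eval_sts(oracle, bm$sts), 0.95)
})

test_that("a random encoder links mentions at chance level", {
  cfg <- synth_config(seed = 0)
  g <- generate_synthetic_ontology(cfg)
  bm <- generate_benchmarks(g, cfg)
  rnd <- make_random_encoder(32, seed = 11)
  acc <- as.numeric(eval_nel_topk(rnd, bm$nel_examples, bm$dictionary, 1))
  expect_lte(acc, 2 / kg_size(g) + 0.05)
})

test_that("parallel pairs are exact cipher translations with names in the training split", {
  cfg <- synth_config(seed = 0)
  g <- generate_synthetic_ontology(cfg)
  bm <- generate_benchmarks(g, cfg)
  pp <- bm$parallel
  expect_true(all(pp$target_text ==
                    cipher_translate(pp$source_text, cfg$languages$xx)))
  names_all <- attr(g, "synth")$names_df$text
  expect_true(all(pp$split[pp$source_text %in% names_all] == "train"))
  expect_true(any(pp$split == "heldout"))
})

test_that("fixture files land in the dialects the loaders consume", {
  cfg <- synth_config(n_topics = 2, concepts_per_topic = 3,
                      names_per_concept = 2, vocab_size = 60, seed = 4)
  g <- generate_synthetic_ontology(cfg)
  bm <- generate_benchmarks(g, cfg)
  dir <- tempfile()
  paths <- write_fixture_files(g, bm, dir)
  g2 <- load_knowledge_graph(paths$concepts, paths$definitions,
                             paths$relations)
  expect_equal(kg_size(g2), kg_size(g))
  g3 <- attach_generated_definitions(g2, paths$agct)
  expect_equal(attr(g3, "agct_report")$attached, kg_size(g))
  expect_equal(nrow(read_sts_file(paths$sts)), nrow(bm$sts))
  expect_equal(nrow(read_nel_file(paths$nel)), nrow(bm$nel_examples))
  expect_equal(nrow(read_dictionary_file(paths$dictionary)),
               nrow(bm$dictionary))
  expect_equal(nrow(read_parallel_file(paths$parallel)), nrow(bm$parallel))
})
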