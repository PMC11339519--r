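# Trained models shared by the slower end-to-end tests. Built once per test
# run, on first use, at the standard study conditions: the default synthetic
# ontology (5 topics x 10 concepts x 3 names, seed 0), generated definitions
# attached, and the package's default training configurations with the STS
# adaptation bracket disabled so the contrastive and distillation objectives
# are compared on equal footing.

.model_cache <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (is.null(.model_cache$fixture)) {
    cfg <- synth_config()
    g <- generate_synthetic_ontology(cfg)
    agct <- synthetic_agct_table(g)
    agct_path <- tempfile(fileext = ".psv")
    writeLines(paste(agct$concept_id, agct$text, sep = "|"), agct_path)
    g <- attach_generated_definitions(g, agct_path)
    bm <- generate_benchmarks(g, cfg)
    corpus <- build_contrastive_corpus(g, seed = 0)
    base <- make_reference_encoder(96, 4096, c(2, 4), seed = 1)
    .model_cache$fixture <- list(cfg = cfg, graph = g, bench = bm,
                                 corpus = corpus, base = base)
  }
  .model_cache$fixture
}

acceptance_teacher <- function() {
  if (is.null(.model_cache$teacher)) {
    fx <- acceptance_fixture()
    cc <- contrastive_config(adapt_before = FALSE, adapt_after = FALSE,
                             seed = 0)
    .model_cache$teacher <- train_contrastive_phase(fx$base, fx$corpus,
                                                    NULL, cc)
  }
  .model_cache$teacher
}

acceptance_students <- function(seeds = 1:5) {
  key <- paste0("students_", paste(seeds, collapse = "_"))
  if (is.null(.model_cache[[key]])) {
    fx <- acceptance_fixture()
    teacher <- acceptance_teacher()
    bank <- build_concept_embedding_bank(teacher, fx$graph)
    pca <- fit_pca(bank, 48)
    targets <- make_distillation_targets(bank, pca)
    variants <- build_distillation_variants(fx$graph)
    students <- lapply(seeds, function(s) {
      head <- new_projection_head(48, fx$base$dimension, seed = s)
      train_self_distillation(fx$base, head, variants, targets,
                              distill_config())$student
    })
    names(students) <- as.character(seeds)
    .model_cache[[key]] <- students
  }
  .model_cache[[key]]
}
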