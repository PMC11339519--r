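# Deterministic synthetic-data generator.
#
# Emulates the inputs every phase consumes: a clustered toy ontology
# (topics -> concepts -> synonyms, definitions, typed relations), graded
# STS and term-relatedness benchmarks, noisy entity-linking mentions with a
# concept dictionary, and deterministic "cipher-language" translations
# standing in for regional-release bitext. The latent topic/concept
# assignment of every emitted text is retained so that oracle and
# chance-level baselines can bound achievable scores.
#
# Surface design: the preferred name of a concept is its two-token core,
# which also appears in its definitions; additional synonyms are
# concept-specific but surface-independent alias token pairs. Synonymy is
# therefore carried by the ontology (shared definitions), not by surface
# overlap — linking an alias-derived mention to the dictionary name is
# impossible by string matching and must be learned.

#' Synthetic-ontology configuration
#'
#' @param n_topics Number of latent topics.
#' @param concepts_per_topic Concepts per topic.
#' @param names_per_concept Names per concept (first is the token core, the
#'   rest are alias synonyms).
#' @param vocab_size Size of the generated token vocabulary; must cover the
#'   distinct topic, concept and alias token needs.
#' @param noise_rate Per-character perturbation probability (swap, delete
#'   or duplicate) applied to alias names and mentions, in `[0, 1]`.
#' @param languages Named list of ciphers (see [make_rot_cipher()]), one
#'   per synthetic language.
#' @param seed Master seed; everything the generator emits is reproducible
#'   from it.
#' @param token_length Characters per vocabulary token.
#' @param n_sts_pairs,n_bcr_pairs Benchmark sizes.
#' @param jitter Half-width of the uniform jitter added to gold scores.
#' @export
synth_config <- function(n_topics = 5L, concepts_per_topic = 10L,
                         names_per_concept = 3L, vocab_size = 400L,
                         noise_rate = 0.08,
                         languages = list(xx = make_rot_cipher(7L)),
                         seed = 0L, token_length = 5L,
                         n_sts_pairs = 150L, n_bcr_pairs = 90L,
                         jitter = 0.5) {
  stopifnot(n_topics >= 0L, concepts_per_topic >= 0L, names_per_concept >= 0L,
            vocab_size >= 0L, noise_rate >= 0, noise_rate <= 1, jitter >= 0)
  structure(list(n_topics = as.integer(n_topics),
                 concepts_per_topic = as.integer(concepts_per_topic),
                 names_per_concept = as.integer(names_per_concept),
                 vocab_size = as.integer(vocab_size),
                 noise_rate = noise_rate, languages = languages,
                 seed = as.integer(seed),
                 token_length = as.integer(token_length),
                 n_sts_pairs = as.integer(n_sts_pairs),
                 n_bcr_pairs = as.integer(n_bcr_pairs),
                 jitter = jitter),
            class = "synth_config")
}

# --- cipher languages --------------------------------------------------------

cipher_alphabet <- function() c(letters, " ")

#' Cipher languages
#'
#' A cipher is a bijective character map over the generator alphabet
#' (lowercase letters plus space; space always maps to itself).
#' `make_rot_cipher(k)` rotates the 26 letters by `k`;
#' `make_random_cipher(seed)` draws a random letter permutation.
#' `cipher_translate()` applies a cipher to each text; a character outside
#' the cipher's alphabet is a mapping error. Translation is invertible by
#' construction.
#'
#' @param k Rotation amount.
#' @param seed Seed of the random permutation.
#' @param text Character vector to translate.
#' @param cipher A named character vector `from -> to`.
#' @return `make_*_cipher()` return the named map; `cipher_translate()` the
#'   translated texts.
#' @examples
#' cipher_translate("fever", make_rot_cipher(1))  # "gfwfs"
#' @export
make_rot_cipher <- function(k) {
  map <- c(letters[(seq_len(26L) - 1L + (k %% 26L)) %% 26L + 1L], " ")
  names(map) <- cipher_alphabet()
  map
}

#' @rdname make_rot_cipher
#' @export
make_random_cipher <- function(seed = 0L) {
  map <- c(with_seed(seed, sample(letters)), " ")
  names(map) <- cipher_alphabet()
  map
}

#' @rdname make_rot_cipher
#' @export
cipher_translate <- function(text, cipher) {
  if (anyDuplicated(cipher) || anyDuplicated(names(cipher))) {
    stop_input("cipher must be a bijective character map")
  }
  for (t in text) {
    chars <- strsplit(t, "", fixed = TRUE)[[1L]]
    unknown <- setdiff(chars, names(cipher))
    if (length(unknown)) {
      stop_input("character '%s' outside the cipher alphabet", unknown[[1L]])
    }
  }
  chartr(paste(names(cipher), collapse = ""),
         paste(cipher, collapse = ""), text)
}

# --- character perturbation --------------------------------------------------

# Per character, with probability `rate`: swap with the next character,
# delete it, or duplicate it (uniform choice). Never returns an empty
# string. Mimics informal mention variation without an external lexicon.
perturb_chars <- function(text, rate) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (stats::runif(1L) < rate) {
      op <- sample(c("swap", "delete", "duplicate"), 1L)
      if (op == "swap" && i < length(chars)) {
        out <- c(out, chars[[i + 1L]], chars[[i]])
        i <- i + 2L
        next
      } else if (op == "delete") {
        i <- i + 1L
        next
      } else {
        out <- c(out, chars[[i]], chars[[i]])
        i <- i + 1L
        next
      }
    }
    out <- c(out, chars[[i]])
    i <- i + 1L
  }
  res <- paste(out, collapse = "")
  if (!nzchar(trimws(res))) text else res
}

# --- ontology ----------------------------------------------------------------

random_tokens <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out)), function(i) {
      paste(sample(letters, len, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate a synthetic clustered ontology
#'
#' Builds a `knowledge_graph` of `n_topics * concepts_per_topic` concepts.
#' Each concept carries its two-token core as the preferred name plus
#' `names_per_concept - 1` alias synonyms (independent token pairs,
#' perturbed at `noise_rate`), a human definition concatenating topic and
#' concept tokens, and one typed relation to the next concept of its topic.
#' A parallel table of generated definitions (a differently worded template
#' over the same tokens) is available via [synthetic_agct_table()] for
#' attachment with [attach_generated_definitions()]. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A validated `knowledge_graph` with the latent structure attached
#'   as `attr(, "synth")`.
#' @export
generate_synthetic_ontology <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  n_concepts <- cfg$n_topics * cfg$concepts_per_topic
  if (n_concepts == 0L || cfg$names_per_concept == 0L) {
    g <- new_knowledge_graph(structure(list(), names = character(0)))
    attr(g, "synth") <- list(cfg = cfg, concept_topic = integer(0),
                             names_df = empty_names_df(),
                             generated_defs = data.frame(concept_id = character(0),
                                                         text = character(0)))
    return(g)
  }
  need <- 2L * cfg$n_topics + 2L * n_concepts +
    2L * n_concepts * (cfg$names_per_concept - 1L)
  if (cfg$vocab_size < need) {
    stop_input("vocab_size %d too small: need %d distinct tokens",
               cfg$vocab_size, need)
  }
  with_seed(cfg$seed, {
    vocab <- random_tokens(cfg$vocab_size, cfg$token_length)
    take <- local({
      pos <- 0L
      function(n) {
        out <- vocab[pos + seq_len(n)]
        pos <<- pos + n
        out
      }
    })
    topic_tok <- matrix(take(2L * cfg$n_topics), ncol = 2L)
    concept_tok <- matrix(take(2L * n_concepts), ncol = 2L)

    ids <- sprintf("C%04d", seq_len(n_concepts))
    topic_of <- rep(seq_len(cfg$n_topics), each = cfg$concepts_per_topic)
    names(topic_of) <- ids

    concepts <- vector("list", n_concepts)
    names(concepts) <- ids
    names_rows <- list()
    gen_defs <- character(n_concepts)
    for (i in seq_len(n_concepts)) {
      tt <- topic_tok[topic_of[[i]], ]
      ct <- concept_tok[i, ]
      core <- paste(ct[1L], ct[2L])
      nms <- core
      if (cfg$names_per_concept > 1L) {
        for (j in seq_len(cfg$names_per_concept - 1L)) {
          al <- take(2L)
          alias <- perturb_chars(paste(al[1L], al[2L]), cfg$noise_rate)
          while (alias %in% nms) alias <- paste(alias, "x")
          nms <- c(nms, alias)
        }
      }
      co <- new_concept(ids[[i]], nms, rep("en", length(nms)),
                        semantic_type = sprintf("T%02d", topic_of[[i]]))
      hdef <- paste("a", tt[1L], tt[2L], "disorder characterized by",
                    ct[1L], ct[2L])
      co <- concept_add_definition(co, hdef, "human")
      concepts[[i]] <- co
      gen_defs[[i]] <- paste(ct[1L], ct[2L], "denotes a", tt[1L], tt[2L],
                             "condition in this synthetic nosology")
      names_rows[[i]] <- data.frame(concept_id = ids[[i]], text = nms,
                                    role = c("core",
                                             rep("alias", length(nms) - 1L)),
                                    topic = topic_of[[i]],
                                    concept = i,
                                    stringsAsFactors = FALSE)
    }

    relations <- empty_relations()
    if (cfg$concepts_per_topic >= 2L) {
      preds <- c("closely_related_to", "shares_category_with")
      subj <- character(0); pred <- character(0); obj <- character(0)
      for (t in seq_len(cfg$n_topics)) {
        members <- ids[topic_of == t]
        nxt <- c(members[-1L], members[[1L]])
        subj <- c(subj, members)
        obj <- c(obj, nxt)
        pred <- c(pred, preds[(seq_along(members) %% 2L) + 1L])
      }
      relations <- data.frame(subject_id = subj, predicate = pred,
                              object_id = obj, stringsAsFactors = FALSE)
    }

    g <- new_knowledge_graph(concepts, relations)
    attr(g, "synth") <- list(
      cfg = cfg,
      concept_topic = topic_of,
      names_df = do.call(rbind, names_rows),
      generated_defs = data.frame(concept_id = ids, text = gen_defs,
                                  stringsAsFactors = FALSE)
    )
    validate_knowledge_graph(g)
    g
  })
}

empty_names_df <- function() {
  data.frame(concept_id = character(0), text = character(0),
             role = character(0), topic = integer(0), concept = integer(0),
             stringsAsFactors = FALSE)
}

#' Generated-definitions table of a synthetic ontology
#'
#' @param graph Graph from [generate_synthetic_ontology()].
#' @return Data frame `(concept_id, text)` of LLM-style generated
#'   definitions (synthetic stand-ins), writable as an AGCT-like table.
#' @export
synthetic_agct_table <- function(graph) {
  attr(graph, "synth")$generated_defs %||%
    stop_input("graph was not produced by generate_synthetic_ontology()")
}

# latent similarity on the 0-5 gold scale: topic overlap and concept
# overlap each contribute half
latent_gold <- function(topic1, topic2, concept1, concept2) {
  5 * ((topic1 == topic2) + (concept1 == concept2)) / 2
}

#' Generate evaluation benchmarks from a synthetic ontology
#'
#' Produces the five benchmark artifacts consumed by the evaluation harness
#' and the cross-lingual phase, all reproducible from the generator seed:
#'
#' * `sts`: sentence pairs (word-shuffled definition variants) with gold =
#'   scaled latent similarity (5 for same concept, 2.5 for same topic, 0
#'   otherwise) plus uniform jitter of half-width `cfg$jitter`, clipped to
#'   `[0, 5]`; sampled in equal strata. Half of the sentence pool belongs
#'   to general-domain topics and concepts that never appear in the
#'   training graph, mirroring the general-purpose share of an STS
#'   benchmark suite, so the metric is sensitive to forgetting of
#'   out-of-ontology semantics.
#' * `bcr`: name pairs with the same latent gold construction.
#' * `nel_examples` / `dictionary`: mentions are perturbed alias synonyms;
#'   the dictionary holds only the core names, so no mention string-matches
#'   a dictionary entry.
#' * `parallel`: `(name, cipher_translate(name))` pairs per configured
#'   language with an 80/20 train/heldout split column.
#' * `latent`: the topic/concept assignment of every emitted text, for
#'   oracle baselines.
#'
#' @param graph Graph from [generate_synthetic_ontology()].
#' @param cfg The same [synth_config()].
#' @return Named list of data frames (see above).
#' @export
generate_benchmarks <- function(graph, cfg = attr(graph, "synth")$cfg) {
  synth <- attr(graph, "synth")
  if (is.null(synth)) {
    stop_input("graph was not produced by generate_synthetic_ontology()")
  }
  names_df <- synth$names_df
  n_concepts <- kg_size(graph)
  with_seed(cfg$seed + 1000L, {
    latent <- names_df[, c("text", "topic", "concept")]

    # two word-shuffled sentence variants of each concept's human definition
    sent <- list()
    for (i in seq_len(n_concepts)) {
      id <- kg_concept_ids(graph)[[i]]
      def <- kg_get_concept(graph, id)$definitions
      def <- def$text[def$source == "human"][1L]
      words <- strsplit(def, " ", fixed = TRUE)[[1L]]
      for (v in 1:2) {
        sent[[length(sent) + 1L]] <-
          data.frame(text = paste(sample(words), collapse = " "),
                     topic = synth$concept_topic[[i]], concept = i,
                     stringsAsFactors = FALSE)
      }
    }
    # general-domain pool: topics and concepts outside the training graph,
    # emulating the general-purpose share of an STS benchmark suite; their
    # latent indices extend the ontology's
    n_gen_concepts <- cfg$n_topics * cfg$concepts_per_topic
    if (n_gen_concepts > 0L) {
      gt <- matrix(random_tokens(2L * cfg$n_topics, cfg$token_length),
                   ncol = 2L)
      gc <- matrix(random_tokens(2L * n_gen_concepts, cfg$token_length),
                   ncol = 2L)
      gen_topic_of <- rep(seq_len(cfg$n_topics), each = cfg$concepts_per_topic)
      for (i in seq_len(n_gen_concepts)) {
        tt <- gt[gen_topic_of[[i]], ]
        words <- c("a", tt[1L], tt[2L], "matter concerning", gc[i, 1L],
                   gc[i, 2L], "in everyday language")
        for (v in 1:2) {
          sent[[length(sent) + 1L]] <-
            data.frame(text = paste(sample(words), collapse = " "),
                       topic = cfg$n_topics + gen_topic_of[[i]],
                       concept = n_concepts + i,
                       stringsAsFactors = FALSE)
        }
      }
    }
    sentences <- do.call(rbind, sent) %||%
      data.frame(text = character(0), topic = integer(0), concept = integer(0))

    jit <- function(base) {
      pmin(5, pmax(0, base + stats::runif(length(base), -cfg$jitter,
                                          cfg$jitter)))
    }
    sts <- sample_graded_pairs(sentences, cfg$n_sts_pairs, jit,
                               c("sentence1", "sentence2"))
    bcr <- sample_graded_pairs(names_df[, c("text", "topic", "concept")],
                               cfg$n_bcr_pairs, jit, c("term1", "term2"))

    # NEL: dictionary of core names; mentions perturb the alias synonyms
    cores <- names_df[names_df$role == "core", ]
    dictionary <- data.frame(
      concept_id = cores$concept_id,
      name = cores$text,
      semantic_type = sprintf("T%02d", cores$topic),
      stringsAsFactors = FALSE)
    aliases <- names_df[names_df$role == "alias", ]
    mention <- character(nrow(aliases))
    for (i in seq_len(nrow(aliases))) {
      m <- perturb_chars(aliases$text[[i]], max(cfg$noise_rate, 0.05))
      tries <- 0L
      while (m %in% dictionary$name && tries < 20L) {
        m <- perturb_chars(aliases$text[[i]], max(cfg$noise_rate, 0.05))
        tries <- tries + 1L
      }
      mention[[i]] <- m
    }
    nel_examples <- data.frame(mention = mention,
                               gold_concept_id = aliases$concept_id,
                               stringsAsFactors = FALSE)
    if (nrow(aliases)) {
      latent <- rbind(latent,
                      data.frame(text = mention, topic = aliases$topic,
                                 concept = aliases$concept))
    }
    latent <- rbind(latent, sentences)

    # parallel bitext per cipher language: all names plus the definition
    # texts. The held-out split is drawn from the definition pairs, whose
    # tokens recur across the training pairs, so held-out generalization
    # is a compositional test rather than a memorization test; every name
    # stays in the training split.
    all_defs <- unlist(lapply(graph$concepts,
                              function(co) co$definitions$text))
    parallel <- list()
    for (lang in names(cfg$languages)) {
      src <- c(names_df$text, all_defs)
      if (!length(src)) next
      tgt <- cipher_translate(src, cfg$languages[[lang]])
      split <- rep("train", length(src))
      if (length(all_defs) >= 2L) {
        n_held <- max(1L, floor(length(all_defs) / 4))
        held <- nrow(names_df) + sample.int(length(all_defs), n_held)
        split[held] <- "heldout"
      }
      parallel[[lang]] <- data.frame(source_text = src, target_text = tgt,
                                     language = lang, score = 1,
                                     split = split, stringsAsFactors = FALSE)
    }
    parallel <- do.call(rbind, parallel) %||%
      data.frame(source_text = character(0), target_text = character(0),
                 language = character(0), score = numeric(0),
                 split = character(0))
    rownames(parallel) <- NULL
    latent <- unique(latent)
    rownames(latent) <- NULL

    list(sts = sts, bcr = bcr, nel_examples = nel_examples,
         dictionary = dictionary, parallel = parallel, latent = latent,
         sentences = sentences)
  })
}

# equal strata of same-concept / same-topic / cross-topic pairs over a
# table of (text, topic, concept) items
sample_graded_pairs <- function(items, n_pairs, jit, colnames2) {
  empty <- stats::setNames(
    data.frame(a = character(0), b = character(0), gold = numeric(0),
               stringsAsFactors = FALSE),
    c(colnames2, "gold"))
  if (!nrow(items) || n_pairs < 1L) return(empty)
  by_concept <- split(seq_len(nrow(items)), items$concept)
  by_topic <- split(seq_len(nrow(items)), items$topic)
  multi_concept <- by_concept[vapply(by_concept, length, 0L) >= 2L]
  per <- ceiling(n_pairs / 3)
  a <- integer(0); b <- integer(0)
  # same concept
  if (length(multi_concept)) {
    for (k in seq_len(per)) {
      rows <- multi_concept[[sample.int(length(multi_concept), 1L)]]
      pick <- sample(rows, 2L)
      a <- c(a, pick[[1L]]); b <- c(b, pick[[2L]])
    }
  }
  # same topic, different concepts
  wide_topics <- by_topic[vapply(by_topic, function(r) {
    length(unique(items$concept[r])) >= 2L
  }, TRUE)]
  if (length(wide_topics)) {
    for (k in seq_len(per)) {
      rows <- wide_topics[[sample.int(length(wide_topics), 1L)]]
      repeat {
        pick <- sample(rows, 2L)
        if (items$concept[pick[[1L]]] != items$concept[pick[[2L]]]) break
      }
      a <- c(a, pick[[1L]]); b <- c(b, pick[[2L]])
    }
  }
  # cross topic
  if (length(by_topic) >= 2L) {
    for (k in seq_len(per)) {
      ts <- sample.int(length(by_topic), 2L)
      a <- c(a, sample(by_topic[[ts[[1L]]]], 1L))
      b <- c(b, sample(by_topic[[ts[[2L]]]], 1L))
    }
  }
  if (!length(a)) return(empty)
  gold <- jit(latent_gold(items$topic[a], items$topic[b],
                          items$concept[a], items$concept[b]))
  out <- data.frame(items$text[a], items$text[b], gold,
                    stringsAsFactors = FALSE)
  names(out) <- c(colnames2, "gold")
  out
}

#' Oracle encoder over the latent assignments
#'
#' Embeds every registered text as the concatenation of its one-hot topic
#' and one-hot concept indicator (equal weight), so cosine similarity
#' equals 1 for same-concept texts, 0.5 for same-topic texts and 0
#' otherwise — an upper-bound baseline on the generated benchmarks.
#' Unregistered texts are an error.
#'
#' @param latent The `latent` table from [generate_benchmarks()].
#' @return A `callable_encoder`.
#' @export
make_oracle_encoder <- function(latent) {
  n_topics <- max(latent$topic)
  n_concepts <- max(latent$concept)
  dim_ <- n_topics + n_concepts
  fn <- function(texts) {
    idx <- match(texts, latent$text)
    if (anyNA(idx)) {
      stop_input("text not registered with the oracle: '%s'",
                 texts[which(is.na(idx))[1L]])
    }
    out <- matrix(0, length(texts), dim_)
    for (i in seq_along(texts)) {
      out[i, latent$topic[idx[[i]]]] <- 1 / sqrt(2)
      out[i, n_topics + latent$concept[idx[[i]]]] <- 1 / sqrt(2)
    }
    out
  }
  make_callable_encoder(fn, dim_, tag = "latent_oracle")
}

#' Write the full fixture set to disk
#'
#' Serializes a synthetic ontology and its benchmarks into the exact file
#' dialects the loaders consume: the three pipe-delimited graph tables, the
#' AGCT-style generated-definitions table, and the tab-separated STS, BCR,
#' NEL, dictionary and parallel files.
#'
#' @param graph Graph from [generate_synthetic_ontology()].
#' @param benchmarks List from [generate_benchmarks()].
#' @param dir Output directory.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_files <- function(graph, benchmarks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kg_paths <- write_knowledge_graph(graph, dir)
  agct <- synthetic_agct_table(graph)
  agct_path <- file.path(dir, "agct.psv")
  writeLines(paste(agct$concept_id, agct$text, sep = "|"), agct_path,
             useBytes = TRUE)
  paths <- list(concepts = unname(kg_paths[["concepts"]]),
                definitions = unname(kg_paths[["definitions"]]),
                relations = unname(kg_paths[["relations"]]),
                agct = agct_path,
                sts = file.path(dir, "sts.tsv"),
                bcr = file.path(dir, "bcr.tsv"),
                nel = file.path(dir, "nel.tsv"),
                dictionary = file.path(dir, "dict.tsv"),
                parallel = file.path(dir, "parallel.tsv"))
  write_sts_file(benchmarks$sts, paths$sts)
  write_bcr_file(benchmarks$bcr, paths$bcr)
  write_nel_file(benchmarks$nel_examples, paths$nel)
  write_dictionary_file(benchmarks$dictionary, paths$dictionary)
  write_parallel_file(benchmarks$parallel, paths$parallel)
  invisible(paths)
}
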