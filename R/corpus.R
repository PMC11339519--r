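# Contrastive training corpus: (concept name, positive text) pairs built
# from a knowledge graph. Positives are the concept's definitions (human
# and/or generated) and natural-language verbalizations of its relations.

#' Default relation verbalization templates
#'
#' Named map from relation predicate to a template with placeholders `{s}`
#' (subject preferred name), `{o}` (object preferred name) and `{p}`
#' (predicate). The wording is artifact-defined and user-editable; pass
#' your own map to [verbalize_relation()] or [build_contrastive_corpus()].
#'
#' @return Named character vector of templates.
#' @export
default_relation_templates <- function() {
  c(may_treat = "{s} is a concept that may treat {o}",
    may_prevent = "{s} is a concept that may prevent {o}",
    isa = "{s} is a kind of {o}",
    part_of = "{s} is a part of {o}",
    closely_related_to = "{s} is a concept closely related to {o}",
    shares_category_with = "{s} belongs to the same category as {o}")
}

#' Generic fallback template used for unmapped predicates
#' @rdname default_relation_templates
#' @export
default_fallback_template <- function() "{s} is related to {o} (via {p})"

fill_template <- function(template, s, o, p) {
  out <- gsub("{s}", tolower(s), template, fixed = TRUE)
  out <- gsub("{o}", tolower(o), out, fixed = TRUE)
  gsub("{p}", gsub("_", " ", p, fixed = TRUE), out, fixed = TRUE)
}

textual_variant <- function(concept_id, text, source_kind) {
  stopifnot(all(nzchar(text)))
  data.frame(concept_id = concept_id, text = text, source_kind = source_kind,
             stringsAsFactors = FALSE)
}

#' Verbalize a knowledge-graph relation
#'
#' Renders a relation triple as a short natural-language description
#' attached to the subject concept, by substituting the (lower-cased)
#' preferred names of subject and object into the predicate's template.
#' Predicates missing from the template map fall back to a generic template
#' unless `fallback` is `NULL`, in which case a template error names the
#' predicate.
#'
#' @param rel A single-row data frame or list with `subject_id`,
#'   `predicate`, `object_id`.
#' @param graph The owning `knowledge_graph`.
#' @param templates Named predicate -> template map.
#' @param fallback Generic template, or `NULL` to disable the fallback.
#' @return One textual variant (data frame row) with
#'   `source_kind = "relation_template"`.
#' @examples
#' \dontrun{
#' verbalize_relation(list(subject_id = "C1", predicate = "may_treat",
#'                         object_id = "C2"), graph)
#' }
#' @export
verbalize_relation <- function(rel, graph,
                               templates = default_relation_templates(),
                               fallback = default_fallback_template()) {
  s_id <- rel$subject_id[[1L]]
  o_id <- rel$object_id[[1L]]
  p <- rel$predicate[[1L]]
  tpl <- if (p %in% names(templates)) templates[[p]] else fallback
  if (is.null(tpl)) {
    stop_input("no template for predicate '%s' and fallback disabled", p)
  }
  text <- fill_template(tpl, preferred_name(graph, s_id),
                        preferred_name(graph, o_id), p)
  textual_variant(s_id, text, "relation_template")
}

#' Build the contrastive training corpus
#'
#' For every concept, emits one pair per admissible combination of an
#' anchor (each of the concept's names) with a positive (each admitted
#' definition, plus up to `max_templates_per_concept` relation
#' verbalizations sampled with `seed`). Concepts with no admissible
#' positive emit nothing; disabling every positive source yields an empty
#' corpus. With template sampling inactive (all verbalizations kept) the
#' result is seed-independent.
#'
#' @param graph A validated `knowledge_graph`.
#' @param use_human_defs,use_generated_defs,use_relation_templates Positive
#'   source toggles. Generated definitions are treated identically to human
#'   ones in pair construction.
#' @param max_templates_per_concept Cap on sampled relation verbalizations
#'   per concept (`Inf` keeps all).
#' @param templates,fallback Passed to [verbalize_relation()].
#' @param mirror_to_object Also attach each relation, inverted, to the
#'   object concept using `inverse_fallback`.
#' @param inverse_fallback Template used for mirrored verbalizations.
#' @param seed Seed for template sampling.
#' @return Data frame `(concept_id, anchor_text, positive_text,
#'   source_kind)` with one row per contrastive pair.
#' @export
build_contrastive_corpus <- function(graph,
                                     use_human_defs = TRUE,
                                     use_generated_defs = TRUE,
                                     use_relation_templates = TRUE,
                                     max_templates_per_concept = 2L,
                                     templates = default_relation_templates(),
                                     fallback = default_fallback_template(),
                                     mirror_to_object = FALSE,
                                     inverse_fallback = "{o} is related to {s} (via {p})",
                                     seed = 0L) {
  validate_knowledge_graph(graph)
  # gather relation verbalizations per subject (and mirrored per object)
  verb <- list()
  if (use_relation_templates && nrow(graph$relations)) {
    for (i in seq_len(nrow(graph$relations))) {
      rel <- graph$relations[i, ]
      v <- verbalize_relation(rel, graph, templates, fallback)
      verb[[v$concept_id]] <- c(verb[[v$concept_id]], v$text)
      if (mirror_to_object) {
        mt <- fill_template(inverse_fallback,
                            preferred_name(graph, rel$subject_id),
                            preferred_name(graph, rel$object_id),
                            rel$predicate)
        verb[[rel$object_id]] <- c(verb[[rel$object_id]], mt)
      }
    }
  }

  out <- vector("list", length(graph$concepts))
  with_seed(seed, {
    for (idx in seq_along(graph$concepts)) {
      co <- graph$concepts[[idx]]
      defs <- co$definitions
      pos_text <- character(0)
      pos_kind <- character(0)
      if (nrow(defs)) {
        keep <- (defs$source == "human" & use_human_defs) |
          (defs$source == "generated" & use_generated_defs)
        pos_text <- defs$text[keep]
        pos_kind <- paste0(defs$source[keep], "_definition")
      }
      vtexts <- verb[[co$concept_id]]
      if (length(vtexts)) {
        if (is.finite(max_templates_per_concept) &&
            length(vtexts) > max_templates_per_concept) {
          vtexts <- vtexts[sort(sample.int(length(vtexts),
                                           max_templates_per_concept))]
        }
        pos_text <- c(pos_text, vtexts)
        pos_kind <- c(pos_kind, rep("relation_template", length(vtexts)))
      }
      if (!length(pos_text)) next
      grid <- expand.grid(a = seq_along(co$names), p = seq_along(pos_text),
                          KEEP.OUT.ATTRS = FALSE)
      out[[idx]] <- data.frame(concept_id = co$concept_id,
                               anchor_text = co$names[grid$a],
                               positive_text = pos_text[grid$p],
                               source_kind = pos_kind[grid$p],
                               stringsAsFactors = FALSE)
    }
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(concept_id = character(0), anchor_text = character(0),
                      positive_text = character(0), source_kind = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Corpus serialization
#'
#' Writes/reads the contrastive corpus as a tab-separated file with header
#' `concept_id  anchor_text  positive_text  source_kind`; tabs, newlines
#' and backslashes inside texts are backslash-escaped.
#'
#' @param corpus Corpus data frame from [build_contrastive_corpus()].
#' @param path File path.
#' @export
write_corpus <- function(corpus, path) {
  write_tsv_records(corpus[, c("concept_id", "anchor_text", "positive_text",
                               "source_kind")], path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  df <- read_tsv_records(path, c("concept_id", "anchor_text",
                                 "positive_text", "source_kind"))
  bad <- !df$source_kind %in% c("human_definition", "generated_definition",
                                "relation_template")
  if (any(bad)) {
    stop_input("%s: unknown source_kind '%s'", path, df$source_kind[bad][[1L]])
  }
  df
}
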