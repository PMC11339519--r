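# Evaluation harness: semantic textual similarity (Pearson), biomedical
# concept relatedness (Spearman), and dense named-entity linking (Top-k
# accuracy over a concept dictionary), plus semantic-type filtering of NEL
# test sets.

pair_scores <- function(enc, a, b) {
  E1 <- encode_texts(enc, a)
  E2 <- encode_texts(enc, b)
  rowSums(E1 * E2)
}

check_correlation_inputs <- function(x, y) {
  if (length(x) < 2L) stop_input("need at least 2 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("undefined correlation: a score series has zero variance")
  }
  invisible(TRUE)
}

#' Semantic textual similarity evaluation
#'
#' Scores each sentence pair by the cosine similarity of its embeddings and
#' returns the Pearson correlation with the gold judgments (0-5 scale).
#' Only the correlation is reported, so no calibration of the cosine onto
#' the gold scale is performed.
#'
#' @param enc An encoder.
#' @param pairs Data frame with `sentence1`, `sentence2`, `gold` in
#'   `[0, 5]`; at least 2 rows.
#' @return Pearson r in `[-1, 1]`.
#' @export
eval_sts <- function(enc, pairs) {
  if (any(pairs$gold < 0 | pairs$gold > 5)) {
    stop_input("gold STS scores must lie in [0, 5]")
  }
  scores <- pair_scores(enc, pairs$sentence1, pairs$sentence2)
  check_correlation_inputs(scores, pairs$gold)
  stats::cor(scores, pairs$gold, method = "pearson")
}

#' Biomedical concept relatedness evaluation
#'
#' Scores each term pair by cosine similarity and returns the Spearman rank
#' correlation with the gold relatedness ratings (ties receive average
#' ranks).
#'
#' @param enc An encoder.
#' @param pairs Data frame with `term1`, `term2`, `gold`; at least 2 rows.
#' @return Spearman rho in `[-1, 1]`.
#' @export
eval_bcr <- function(enc, pairs) {
  scores <- pair_scores(enc, pairs$term1, pairs$term2)
  check_correlation_inputs(scores, pairs$gold)
  stats::cor(scores, pairs$gold, method = "spearman")
}

#' Dense named-entity linking evaluation
#'
#' Embeds every dictionary name and every mention, scores each concept by
#' its best-scoring name (a concept with several names counts once), and
#' reports the fraction of mentions whose gold concept appears among the
#' `k` highest-scoring concepts. Score ties break deterministically by
#' dictionary row order (earlier rows win).
#'
#' @param enc An encoder.
#' @param examples Data frame with `mention`, `gold_concept_id`.
#' @param dict Data frame with `concept_id`, `name` and (optionally)
#'   `semantic_type`; non-empty.
#' @param k Retrieval depth (>= 1).
#' @return Top-k accuracy in `[0, 1]`, with the per-example hit vector
#'   attached as `attr(, "hits")`.
#' @export
eval_nel_topk <- function(enc, examples, dict, k = 1L) {
  if (is.null(dict) || nrow(dict) == 0L) stop_input("empty dictionary")
  if (k < 1L) stop_input("`k` must be >= 1")
  if (nrow(examples) == 0L) stop_input("no NEL examples")
  E_dict <- encode_texts(enc, dict$name)
  E_m <- encode_texts(enc, examples$mention)
  S <- tcrossprod(E_m, E_dict)  # mentions x dictionary names
  ids <- dict$concept_id
  uniq_ids <- unique(ids)  # first-occurrence order = tie-break order
  hits <- logical(nrow(examples))
  for (i in seq_len(nrow(examples))) {
    # best name per concept, concepts kept in first-occurrence order
    best <- vapply(uniq_ids, function(id) max(S[i, ids == id]), 0)
    topk <- uniq_ids[order(-best)[seq_len(min(k, length(uniq_ids)))]]
    hits[[i]] <- examples$gold_concept_id[[i]] %in% topk
  }
  structure(mean(hits), hits = hits)
}

#' Filter NEL examples by semantic type
#'
#' Removes every example whose gold concept carries one of the excluded
#' semantic types (as recorded in the dictionary). Examples whose gold
#' concept is absent from the dictionary are kept. Counts of kept and
#' removed examples are attached as attributes.
#'
#' @param examples NEL example data frame (`mention`, `gold_concept_id`).
#' @param dict Dictionary data frame carrying `concept_id` and
#'   `semantic_type`.
#' @param excluded_types Character vector of types to exclude.
#' @return The filtered examples with `attr(, "n_kept")` and
#'   `attr(, "n_removed")`.
#' @export
filter_by_semantic_type <- function(examples, dict, excluded_types) {
  type_of <- dict$semantic_type[match(examples$gold_concept_id,
                                      dict$concept_id)]
  drop <- !is.na(type_of) & type_of %in% excluded_types
  out <- examples[!drop, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_kept = sum(!drop), n_removed = sum(drop))
}

# --- benchmark file formats --------------------------------------------------

#' Benchmark file readers and writers
#'
#' All benchmark files are tab-separated with a header and the package's
#' standard escaping. Columns: STS `(sentence1, sentence2, gold)`; BCR
#' `(term1, term2, gold)`; NEL examples `(mention, gold_concept_id)`;
#' dictionary `(concept_id, name, semantic_type)`. Malformed rows are
#' rejected with their 1-based line number; gold scores must be numeric
#' (and in `[0, 5]` for STS).
#'
#' @param path File path.
#' @param pairs,examples,dict Data frames in the column layouts above.
#' @name benchmark_io
NULL

read_gold <- function(x, path) {
  g <- suppressWarnings(as.numeric(x))
  if (anyNA(g)) stop_input("%s: non-numeric gold score '%s'", path,
                           x[which(is.na(g))[1L]])
  g
}

#' @rdname benchmark_io
#' @export
read_sts_file <- function(path) {
  df <- read_tsv_records(path, c("sentence1", "sentence2", "gold"))
  df$gold <- read_gold(df$gold, path)
  if (any(df$gold < 0 | df$gold > 5)) {
    stop_input("%s: gold STS scores must lie in [0, 5]", path)
  }
  df
}

#' @rdname benchmark_io
#' @export
write_sts_file <- function(pairs, path) {
  write_tsv_records(pairs[, c("sentence1", "sentence2", "gold")], path)
}

#' @rdname benchmark_io
#' @export
read_bcr_file <- function(path) {
  df <- read_tsv_records(path, c("term1", "term2", "gold"))
  df$gold <- read_gold(df$gold, path)
  df
}

#' @rdname benchmark_io
#' @export
write_bcr_file <- function(pairs, path) {
  write_tsv_records(pairs[, c("term1", "term2", "gold")], path)
}

#' @rdname benchmark_io
#' @export
read_nel_file <- function(path) {
  read_tsv_records(path, c("mention", "gold_concept_id"))
}

#' @rdname benchmark_io
#' @export
write_nel_file <- function(examples, path) {
  write_tsv_records(examples[, c("mention", "gold_concept_id")], path)
}

#' @rdname benchmark_io
#' @export
read_dictionary_file <- function(path) {
  read_tsv_records(path, c("concept_id", "name", "semantic_type"))
}

#' @rdname benchmark_io
#' @export
write_dictionary_file <- function(dict, path) {
  write_tsv_records(dict[, c("concept_id", "name", "semantic_type")], path)
}
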