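#' Table dialect for knowledge-graph files
#'
#' Describes how the pipe-delimited concept, definition and relation tables
#' are laid out. The default is a deliberately minimal RRF-like subset of the
#' UMLS `MRCONSO` / `MRDEF` / `MRREL` tables: pipe-delimited, no header,
#' with the concept table carrying `(concept_id, language, name)` and an
#' optional fourth column holding a semantic-type tag. Extra trailing columns
#' (real RRF files have up to 18) are ignored; the column-index maps let you
#' point the loader at the right fields of a richer file.
#'
#' @param delimiter Field separator, default `"|"`.
#' @param header Whether files carry a header line to skip. Default `FALSE`.
#' @param concept_cols Named indices `id`, `language`, `name` and optionally
#'   `semantic_type` into the concept table. Set `semantic_type` to `NA` for
#'   files without that column; rows missing the (trailing) semantic-type
#'   field are accepted with an empty tag.
#' @param definition_cols Named indices `id`, `source`, `text`. The source
#'   field must read `"human"` or `"generated"`.
#' @param relation_cols Named indices `subject`, `predicate`, `object`.
#' @return An object of class `kg_dialect`.
#' @export
kg_dialect <- function(delimiter = "|",
                       header = FALSE,
                       concept_cols = c(id = 1L, language = 2L, name = 3L,
                                        semantic_type = 4L),
                       definition_cols = c(id = 1L, source = 2L, text = 3L),
                       relation_cols = c(subject = 1L, predicate = 2L,
                                         object = 3L)) {
  stopifnot(nchar(delimiter) >= 1L)
  structure(
    list(delimiter = delimiter, header = isTRUE(header),
         concept_cols = concept_cols, definition_cols = definition_cols,
         relation_cols = relation_cols),
    class = "kg_dialect"
  )
}

# Split a delimited file into a list of character vectors (one per row),
# enforcing a minimum field count with a file:line parse error.
read_delim_rows <- function(path, delimiter, header, min_fields) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  offset <- 0L
  if (header && length(lines) >= 1L) {
    lines <- lines[-1L]
    offset <- 1L
  }
  if (!length(lines)) return(list())
  keep <- nzchar(lines)
  # append one delimiter so trailing empty fields survive strsplit
  rows <- lapply(strsplit(paste0(lines, delimiter), delimiter, fixed = TRUE),
                 function(r) if (length(r)) r else "")
  for (i in seq_along(rows)) {
    if (keep[i] && length(rows[[i]]) < min_fields) {
      stop_input("%s:%d: expected at least %d fields, found %d",
                 path, i + offset, min_fields, length(rows[[i]]))
    }
  }
  rows[keep]
}

field <- function(row, idx, default = "") {
  if (is.na(idx) || idx > length(row)) default else trimws(row[[idx]])
}

#' Load a knowledge graph from delimited tables
#'
#' Reads a concept synonym table and, optionally, definition and relation
#' tables, validates referential integrity, and returns a
#' `knowledge_graph`. Rows of the definition or relation table that
#' reference a concept id absent from the concept table are dropped and
#' counted in the load report (see [load_report()]), as are empty names,
#' empty definition texts, self-referencing relations and exact duplicate
#' `(concept_id, name, language)` rows. Ingestion is row-order independent:
#' names, definitions and relations are stored in a canonical sort order, so
#' permuting input rows yields the same graph. The first name in canonical
#' order acts as the concept's preferred term (UMLS term-type priorities are
#' intentionally not modelled).
#'
#' @param concept_table Path to the concept table.
#' @param definition_table Optional path to the definition table.
#' @param relation_table Optional path to the relation table.
#' @param dialect A [kg_dialect()].
#' @return A `knowledge_graph` with a load report attached.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("C1|en|ranitidine|drug", "C2|en|aspirin|drug"),
#'            file.path(dir, "concepts.psv"))
#' g <- load_knowledge_graph(file.path(dir, "concepts.psv"))
#' kg_size(g)
#' @export
load_knowledge_graph <- function(concept_table,
                                 definition_table = NULL,
                                 relation_table = NULL,
                                 dialect = kg_dialect()) {
  stopifnot(inherits(dialect, "kg_dialect"))
  cc <- dialect$concept_cols
  # the semantic-type column (if mapped) may be absent from short rows
  min_concept <- max(cc[c("id", "language", "name")])
  rows <- read_delim_rows(concept_table, dialect$delimiter, dialect$header,
                          min_concept)

  dropped <- c(empty_name = 0L, duplicate_names = 0L,
               orphan_definitions = 0L, empty_definitions = 0L,
               bad_source_definitions = 0L,
               orphan_relations = 0L, self_relations = 0L)

  ids <- character(0)
  name_tab <- list()  # id -> data.frame(name, language)
  sem_tab <- list()   # id -> character vector of non-empty tags seen
  for (row in rows) {
    id <- field(row, cc[["id"]])
    nm <- field(row, cc[["name"]])
    lang <- field(row, cc[["language"]], "en")
    if (!nzchar(lang)) lang <- "en"
    st <- if ("semantic_type" %in% names(cc)) field(row, cc[["semantic_type"]], "") else ""
    if (!nzchar(id) || !nzchar(nm)) {
      dropped[["empty_name"]] <- dropped[["empty_name"]] + 1L
      next
    }
    if (is.null(name_tab[[id]])) {
      ids <- c(ids, id)
      name_tab[[id]] <- data.frame(name = nm, language = lang,
                                   stringsAsFactors = FALSE)
      sem_tab[[id]] <- st
    } else {
      dup <- any(name_tab[[id]]$name == nm & name_tab[[id]]$language == lang)
      if (dup) {
        dropped[["duplicate_names"]] <- dropped[["duplicate_names"]] + 1L
      } else {
        name_tab[[id]] <- rbind(name_tab[[id]],
                                data.frame(name = nm, language = lang,
                                           stringsAsFactors = FALSE))
      }
      sem_tab[[id]] <- c(sem_tab[[id]], st)
    }
  }
  for (id in ids) {
    tags <- unique(sem_tab[[id]][nzchar(sem_tab[[id]])])
    if (length(tags) > 1L) {
      stop_input("concept %s carries conflicting semantic types: %s",
                 id, paste(tags, collapse = ", "))
    }
    sem_tab[[id]] <- if (length(tags)) tags else ""
  }

  concepts <- vector("list", length(ids))
  names(concepts) <- ids
  for (id in ids) {
    nt <- name_tab[[id]]
    ord <- order(nt$language, nt$name, method = "radix")
    concepts[[id]] <- new_concept(id, nt$name[ord], nt$language[ord],
                                  semantic_type = sem_tab[[id]])
  }
  concepts <- concepts[order(ids, method = "radix")]

  n_def <- c(human = 0L, generated = 0L)
  if (!is.null(definition_table)) {
    dc <- dialect$definition_cols
    drows <- read_delim_rows(definition_table, dialect$delimiter,
                             dialect$header, max(dc))
    for (row in drows) {
      id <- field(row, dc[["id"]])
      src <- field(row, dc[["source"]])
      txt <- field(row, dc[["text"]])
      if (!nzchar(txt)) {
        dropped[["empty_definitions"]] <- dropped[["empty_definitions"]] + 1L
      } else if (!src %in% c("human", "generated")) {
        dropped[["bad_source_definitions"]] <-
          dropped[["bad_source_definitions"]] + 1L
      } else if (is.null(concepts[[id]])) {
        dropped[["orphan_definitions"]] <- dropped[["orphan_definitions"]] + 1L
      } else {
        concepts[[id]] <- concept_add_definition(concepts[[id]], txt, src)
        n_def[[src]] <- n_def[[src]] + 1L
      }
    }
  }

  relations <- empty_relations()
  if (!is.null(relation_table)) {
    rc <- dialect$relation_cols
    rrows <- read_delim_rows(relation_table, dialect$delimiter,
                             dialect$header, max(rc))
    subj <- vapply(rrows, field, "", rc[["subject"]])
    pred <- vapply(rrows, field, "", rc[["predicate"]])
    obj <- vapply(rrows, field, "", rc[["object"]])
    known <- subj %in% names(concepts) & obj %in% names(concepts)
    dropped[["orphan_relations"]] <- sum(!known)
    self <- known & subj == obj
    dropped[["self_relations"]] <- sum(self)
    keep <- known & !self
    relations <- data.frame(subject_id = subj[keep], predicate = pred[keep],
                            object_id = obj[keep], stringsAsFactors = FALSE)
    relations <- unique(relations)
    relations <- relations[order(relations$subject_id, relations$predicate,
                                 relations$object_id, method = "radix"), ,
                           drop = FALSE]
    rownames(relations) <- NULL
  }

  g <- new_knowledge_graph(concepts, relations)
  attr(g, "load_report") <- list(
    concepts = length(concepts),
    names = sum(vapply(concepts, function(co) length(co$names), 0L)),
    definitions = n_def,
    relations = nrow(relations),
    dropped = as.list(dropped)
  )
  validate_knowledge_graph(g)
}

empty_relations <- function() {
  data.frame(subject_id = character(0), predicate = character(0),
             object_id = character(0), stringsAsFactors = FALSE)
}

new_concept <- function(concept_id, names, languages = rep("en", length(names)),
                        semantic_type = "") {
  stopifnot(length(names) >= 1L, all(nzchar(names)),
            length(languages) == length(names))
  structure(
    list(concept_id = concept_id,
         names = as.character(names),
         languages = as.character(languages),
         definitions = data.frame(text = character(0), source = character(0),
                                  stringsAsFactors = FALSE),
         semantic_type = as.character(semantic_type)),
    class = "kg_concept"
  )
}

concept_add_definition <- function(concept, text, source) {
  df <- concept$definitions
  if (!any(df$text == text & df$source == source)) {
    df <- rbind(df, data.frame(text = text, source = source,
                               stringsAsFactors = FALSE))
    df <- df[order(df$source, df$text, method = "radix"), , drop = FALSE]
    rownames(df) <- NULL
    concept$definitions <- df
  }
  concept
}

new_knowledge_graph <- function(concepts, relations = empty_relations()) {
  structure(list(concepts = concepts, relations = relations),
            class = "knowledge_graph")
}

#' Validate a knowledge graph
#'
#' Checks the structural invariants: unique non-empty concept ids, at least
#' one non-empty name per concept, and referential integrity of every
#' relation endpoint. Returns the graph invisibly on success.
#'
#' @param graph A `knowledge_graph`.
#' @export
validate_knowledge_graph <- function(graph) {
  stopifnot(inherits(graph, "knowledge_graph"))
  ids <- names(graph$concepts)
  if (anyDuplicated(ids)) stop_input("duplicate concept ids in graph")
  for (co in graph$concepts) {
    if (length(co$names) < 1L || any(!nzchar(co$names))) {
      stop_input("concept %s has an empty name", co$concept_id)
    }
  }
  if (nrow(graph$relations)) {
    bad <- !(graph$relations$subject_id %in% ids) |
      !(graph$relations$object_id %in% ids)
    if (any(bad)) {
      stop_input("relation endpoints missing from graph: %s",
                 paste(utils::head(graph$relations$subject_id[bad]), collapse = ", "))
    }
  }
  invisible(graph)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  n_def <- sum(vapply(x$concepts, function(co) nrow(co$definitions), 0L))
  cat(sprintf("<knowledge_graph> %d concepts, %d definitions, %d relations\n",
              length(x$concepts), n_def, nrow(x$relations)))
  invisible(x)
}

#' Load report of an ingested graph
#'
#' Counts of concepts, names, definitions by source and relations retained,
#' plus the number of rows dropped by each filter (orphans, empty fields,
#' duplicates, self-relations).
#'
#' @param graph A graph returned by [load_knowledge_graph()].
#' @return A named list, or `NULL` if the graph was built in memory.
#' @export
load_report <- function(graph) attr(graph, "load_report")

#' @rdname kg_accessors
#' @export
kg_concept_ids <- function(graph) names(graph$concepts)

#' Knowledge-graph accessors
#'
#' `kg_concept_ids()` lists concept ids; `kg_get_concept()` fetches one
#' concept; `preferred_name()` returns its first (canonical-order) name;
#' `kg_size()` counts concepts.
#'
#' @param graph A `knowledge_graph`.
#' @param concept_id A concept id present in the graph.
#' @name kg_accessors
#' @export
kg_get_concept <- function(graph, concept_id) {
  co <- graph$concepts[[concept_id]]
  if (is.null(co)) stop_input("unknown concept id: %s", concept_id)
  co
}

#' @rdname kg_accessors
#' @export
preferred_name <- function(graph, concept_id) {
  kg_get_concept(graph, concept_id)$names[[1L]]
}

#' @rdname kg_accessors
#' @export
kg_size <- function(graph) length(graph$concepts)

#' Write a knowledge graph to canonical delimited tables
#'
#' Serializes the graph back into the three-table dialect read by
#' [load_knowledge_graph()], in canonical order (concepts sorted by id, each
#' concept's names, definitions and the relation list in their stored sort
#' order), so that load-write round trips are byte-identical.
#'
#' @param graph A `knowledge_graph`.
#' @param dir Output directory (created if needed).
#' @param dialect A [kg_dialect()]; only the delimiter is used.
#' @return Invisibly, the paths of the three files written
#'   (`concepts`, `definitions`, `relations`).
#' @export
write_knowledge_graph <- function(graph, dir, dialect = kg_dialect()) {
  validate_knowledge_graph(graph)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dialect$delimiter
  paths <- c(concepts = file.path(dir, "concepts.psv"),
             definitions = file.path(dir, "definitions.psv"),
             relations = file.path(dir, "relations.psv"))
  con_lines <- character(0)
  def_lines <- character(0)
  ord_ids <- names(graph$concepts)[order(names(graph$concepts), method = "radix")]
  for (id in ord_ids) {
    co <- graph$concepts[[id]]
    nord <- order(co$languages, co$names, method = "radix")
    con_lines <- c(con_lines,
                   paste(co$concept_id, co$languages[nord], co$names[nord],
                         co$semantic_type, sep = d))
    if (nrow(co$definitions)) {
      dord <- order(co$definitions$source, co$definitions$text,
                    method = "radix")
      def_lines <- c(def_lines,
                     paste(co$concept_id, co$definitions$source[dord],
                           co$definitions$text[dord], sep = d))
    }
  }
  rel_lines <- if (nrow(graph$relations)) {
    paste(graph$relations$subject_id, graph$relations$predicate,
          graph$relations$object_id, sep = d)
  } else character(0)
  writeLines(con_lines, paths[["concepts"]], useBytes = TRUE)
  writeLines(def_lines, paths[["definitions"]], useBytes = TRUE)
  writeLines(rel_lines, paths[["relations"]], useBytes = TRUE)
  invisible(paths)
}

#' Attach generated definitions from an AGCT-style table
#'
#' Reads a two-column pipe-delimited table mapping `concept_id` to a
#' generated definition text and appends each matching definition to its
#' concept with source `"generated"`. Existing human definitions are never
#' overwritten or removed; rows whose concept id is absent from the graph
#' are skipped and counted, and rows with empty definition text are
#' rejected and counted. The attachment report is available as
#' `attr(graph, "agct_report")`.
#'
#' @param graph A `knowledge_graph`.
#' @param agct_table Path to the `concept_id|definition` table.
#' @param dialect A [kg_dialect()]; only delimiter/header are used.
#' @return The augmented graph.
#' @export
attach_generated_definitions <- function(graph, agct_table,
                                         dialect = kg_dialect()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  rows <- read_delim_rows(agct_table, dialect$delimiter, dialect$header, 2L)
  attached <- 0L; skipped <- 0L; rejected <- 0L
  for (row in rows) {
    id <- field(row, 1L)
    txt <- field(row, 2L)
    if (!nzchar(txt)) {
      rejected <- rejected + 1L
    } else if (is.null(graph$concepts[[id]])) {
      skipped <- skipped + 1L
    } else {
      graph$concepts[[id]] <- concept_add_definition(graph$concepts[[id]],
                                                     txt, "generated")
      attached <- attached + 1L
    }
  }
  attr(graph, "agct_report") <- list(attached = attached,
                                     skipped_unknown = skipped,
                                     rejected_empty = rejected)
  validate_knowledge_graph(graph)
  graph
}
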