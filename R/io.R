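# Line-oriented tab-separated I/O shared by the corpus and benchmark
# readers. Fields are escaped so free text may contain tabs, newlines and
# backslashes: \\ -> backslash, \t -> tab, \n -> newline.

tsv_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

tsv_unescape <- function(x) {
  # decode escaped backslashes via a sentinel so "\\t" is not mistaken for a tab
  x <- gsub("\\\\", "\x01", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  gsub("\x01", "\\", x, fixed = TRUE)
}

write_tsv_records <- function(df, path, header = TRUE) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cols <- lapply(df, function(col) tsv_escape(as.character(col)))
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (header) lines <- c(paste(names(df), collapse = "\t"), lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_tsv_records <- function(path, columns, header = TRUE) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  offset <- 0L
  if (header && length(lines)) {
    lines <- lines[-1L]
    offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(columns)
  out <- vector("list", n)
  names(out) <- columns
  for (j in seq_len(n)) out[[j]] <- character(length(rows))
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n) {
      stop_input("%s:%d: expected %d tab-separated fields, found %d",
                 path, i + offset, n, length(rows[[i]]))
    }
    for (j in seq_len(n)) out[[j]][[i]] <- tsv_unescape(rows[[i]][[j]])
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}
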