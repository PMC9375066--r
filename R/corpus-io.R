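#' Read and write CHEMDNER-dialect corpus files
#'
#' Corpora are stored as two UTF-8 tab-separated files mirroring the public
#' CHEMDNER distribution: an abstracts file (one record per document:
#' identifier, title, abstract) and an annotations file (identifier, section
#' flag `T`/`A`, start offset, end offset, entity surface, entity type).
#' Offsets are 0-based, half-open, counted in characters, per section.
#' Literal tabs, newlines and backslashes inside text fields are escaped as
#' `\t`, `\n`, `\\` so that round-trips are lossless.
#'
#' @param path File path.
#' @return `read_abstracts()`: a list of annotated documents, each a list
#'   with `doc_id`, `title`, `abstract` and a zero-row `spans` data frame.
#' @export
read_abstracts <- function(path) {
  lines <- .read_utf8_lines(path)
  docs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("malformed abstracts line ", i, ": expected at least 3 ",
           "tab-separated fields, got ", length(f))
    }
    docs[[i]] <- new_document(f[1], .unescape_field(f[2]),
                              .unescape_field(f[3]))
  }
  docs[!vapply(docs, is.null, logical(1))]
}

#' @rdname read_abstracts
#' @param documents A list of annotated documents.
#' @export
write_abstracts <- function(documents, path) {
  lines <- vapply(documents, function(d) {
    paste(d$doc_id, .escape_field(d$title), .escape_field(d$abstract),
          sep = "\t")
  }, character(1))
  .write_utf8_lines(lines, path)
  invisible(path)
}

#' @rdname read_abstracts
#' @details `read_annotations()` verifies every span against the document
#'   text: the slice `[start, end)` of the referenced section must equal the
#'   recorded surface string, otherwise it stops with the document id and
#'   offsets.  Unknown entity type strings are rejected.
#' @export
read_annotations <- function(path, documents) {
  lines <- .read_utf8_lines(path)
  byid <- stats::setNames(seq_along(documents),
                          vapply(documents, `[[`, character(1), "doc_id"))
  spans <- vector("list", length(documents))
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) stop("malformed annotations line ", i)
    j <- unname(byid[f[1]])
    if (is.na(j)) stop("annotation line ", i,
                       ": unknown doc_id '", f[1], "'")
    span <- new_entity_span(.section_name(f[2]), as.integer(f[3]),
                            as.integer(f[4]), .unescape_field(f[5]), f[6])
    .check_span(span, documents[[j]], where = paste0("line ", i))
    spans[[j]] <- c(spans[[j]], list(span))
  }
  for (j in seq_along(documents)) {
    if (!is.null(spans[[j]])) {
      documents[[j]]$spans <- do.call(rbind, lapply(spans[[j]], as.data.frame))
    }
  }
  documents
}

#' @rdname read_abstracts
#' @export
write_annotations <- function(documents, path) {
  rows <- character(0)
  for (d in documents) {
    s <- d$spans
    if (nrow(s)) {
      rows <- c(rows, paste(d$doc_id,
                            ifelse(s$section == "TITLE", "T", "A"),
                            s$start, s$end, .escape_field(s$surface),
                            s$etype, sep = "\t"))
    }
  }
  .write_utf8_lines(rows, path)
  invisible(path)
}

#' Annotated document and entity span constructors
#'
#' @param doc_id Non-empty document identifier.
#' @param title,abstract Section texts (newlines normalized to `\n`).
#' @return `new_document()`: a list with class `"cner_document"`.
#' @export
new_document <- function(doc_id, title, abstract) {
  stopifnot(nzchar(doc_id))
  structure(list(doc_id = doc_id,
                 title = .normalize_newlines(title),
                 abstract = .normalize_newlines(abstract),
                 spans = .empty_spans()),
            class = "cner_document")
}

#' @rdname new_document
#' @param section `"TITLE"` or `"ABSTRACT"`.
#' @param start,end 0-based half-open character offsets within the section.
#' @param surface The annotated surface string.
#' @param etype Entity type, one of the CHEMDNER types.
#' @export
new_entity_span <- function(section, start, end, surface, etype) {
  etypes <- c("ABBREVIATION", "FAMILY", "FORMULA", "IDENTIFIER", "MULTIPLE",
              "SYSTEMATIC", "TRIVIAL", "NO_CLASS")
  if (!etype %in% etypes) stop("unknown entity type '", etype, "'")
  stopifnot(section %in% c("TITLE", "ABSTRACT"),
            start >= 0L, end > start)
  data.frame(section = section, start = as.integer(start),
             end = as.integer(end), surface = surface, etype = etype,
             stringsAsFactors = FALSE)
}

.empty_spans <- function() {
  data.frame(section = character(), start = integer(), end = integer(),
             surface = character(), etype = character(),
             stringsAsFactors = FALSE)
}

.check_span <- function(span, doc, where = "") {
  text <- if (span$section == "TITLE") doc$title else doc$abstract
  if (span$end > nchar(text)) {
    stop("annotation ", where, " (", doc$doc_id, "): offsets [", span$start,
         ", ", span$end, ") exceed ", tolower(span$section), " length ",
         nchar(text))
  }
  got <- substr(text, span$start + 1L, span$end)
  if (!identical(got, span$surface)) {
    stop("annotation ", where, " (", doc$doc_id, "): text[", span$start,
         ":", span$end, "] is '", got, "', annotation says '",
         span$surface, "'")
  }
  invisible(TRUE)
}

.section_name <- function(flag) {
  switch(flag, "T" = , "TITLE" = "TITLE", "A" = , "ABSTRACT" = "ABSTRACT",
         stop("unknown section flag '", flag, "'"))
}

#' Write and read extraction result tables
#'
#' Extracted entities are persisted as a plain CSV with columns `doc_id`,
#' `section`, `start`, `end`, `surface`, `score`, ordered by
#' `(doc_id, start)`, with standard CSV quoting so delimiters in surfaces
#' are safe.
#'
#' @param entities Data frame of extracted entities
#'   (see [extract_entities()]); zero rows allowed.
#' @param path Output file path.
#' @export
write_extraction_table <- function(entities, path) {
  cols <- c("doc_id", "section", "start", "end", "surface", "score")
  if (is.null(entities) || nrow(entities) == 0L) {
    entities <- data.frame(doc_id = character(), section = character(),
                           start = integer(), end = integer(),
                           surface = character(), score = numeric(),
                           stringsAsFactors = FALSE)
  }
  entities <- entities[order(entities$doc_id, entities$start), cols,
                       drop = FALSE]
  utils::write.csv(entities, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_extraction_table
#' @export
read_extraction_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = c(doc_id = "character", section = "character",
                                 start = "integer", end = "integer",
                                 surface = "character", score = "numeric"))
}

.normalize_newlines <- function(x) gsub("\r\n?", "\n", x)

.escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

.unescape_field <- function(x) {
  # split on escaped backslashes first so \\t stays a literal backslash + t
  parts <- strsplit(x, "\\\\", fixed = TRUE)[[1]]
  if (length(parts) == 0L) parts <- ""
  parts <- gsub("\\t", "\t", parts, fixed = TRUE)
  parts <- gsub("\\n", "\n", parts, fixed = TRUE)
  paste(parts, collapse = "\\")
}

.read_utf8_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, encoding = "UTF-8")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.write_utf8_lines <- function(lines, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
}
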