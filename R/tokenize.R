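#' Offset-preserving word/punctuation tokenization
#'
#' Splits text into maximal runs of word characters (letters, digits,
#' underscore) or maximal runs of non-word, non-whitespace characters, the
#' behaviour of the classic word-punct tokenizers used for scientific text.
#' Whitespace is skipped but accounted for: token offsets index into the
#' original string, so `substr(text, start + 1, end)` always recovers the
#' surface form.
#'
#' @param text A single character string (one document section).
#' @return A data frame with columns `surface`, `start`, `end`.  Offsets are
#'   0-based, half-open `[start, end)`, counted in characters.
#' @examples
#' wp_tokenize("H2O2 level.")
#' wp_tokenize("2-(acetyloxy)benzoic")
#' @export
wp_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[[:alnum:]_]+|[^[:alnum:]_[:space:]]+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(surface = regmatches(text, list(m))[[1]],
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Build labelled fragments of text (FoTs) for one document section
#'
#' Every token becomes the target of exactly one FoT.  The FoT's class label
#' is the entity type of the span the target character-overlaps, or
#' `"NON_CNE"` when it overlaps none.  When several spans overlap one token
#' the longest wins, ties broken by leftmost start.  Context tokens (the
#' `window` nearest on each side) are truncated at the section boundaries and
#' are recovered positionally from the token table, so this function only
#' records the labels.
#'
#' @param tokens Token table from [wp_tokenize()].
#' @param spans A data frame of entity spans with columns `start`, `end`
#'   (0-based, half-open) and `etype`; may have zero rows.
#' @param map_etype Function mapping an annotation type string to a model
#'   class label; the default maps the five named chemical types to
#'   themselves and everything else (`IDENTIFIER`, `MULTIPLE`, `NO_CLASS`,
#'   ...) to `"NON_CNE"`.
#' @return `tokens` with an added `label` column.
#' @export
label_tokens <- function(tokens, spans, map_etype = default_etype_map) {
  label <- rep("NON_CNE", nrow(tokens))
  if (!is.null(spans) && nrow(spans) > 0L) {
    ord <- order(-(spans$end - spans$start), spans$start)
    spans <- spans[ord, , drop = FALSE]
    for (i in seq_len(nrow(tokens))) {
      hit <- which(spans$start < tokens$end[i] & spans$end > tokens$start[i])
      if (length(hit)) label[i] <- map_etype(spans$etype[hit[1]])
    }
  }
  tokens$label <- label
  tokens
}

#' @rdname label_tokens
#' @param etype An annotation type string.
#' @export
default_etype_map <- function(etype) {
  base <- c("ABBREVIATION", "SYSTEMATIC", "FORMULA", "FAMILY", "TRIVIAL")
  ifelse(etype %in% base, etype, "NON_CNE")
}

#' Build the FoT table for a whole corpus
#'
#' Tokenizes title and abstract of every document independently (context
#' windows never cross the section boundary), attaches class labels from the
#' gold spans, and returns one row per token -- the unit classified by the
#' model.
#'
#' @param corpus A list of annotated documents as returned by
#'   [read_abstracts()] / [generate_corpus()].
#' @param window Context window width w (tokens kept on each side), 0--3.
#' @inheritParams label_tokens
#' @return A data frame with columns `doc_id`, `section`, `surface`, `start`,
#'   `end`, `label` plus a `window` attribute.  Rows are in document order;
#'   FoT contexts are the `window` neighbouring rows within the same
#'   (doc_id, section) group.
#' @export
build_fots <- function(corpus, window = 1L, map_etype = default_etype_map) {
  stopifnot(window %in% 0:3)
  out <- vector("list", 2L * length(corpus))
  j <- 0L
  for (doc in corpus) {
    for (sec in c("TITLE", "ABSTRACT")) {
      text <- if (sec == "TITLE") doc$title else doc$abstract
      tok <- wp_tokenize(text)
      spans <- doc$spans[doc$spans$section == sec, , drop = FALSE]
      tok <- label_tokens(tok, spans, map_etype)
      if (nrow(tok)) {
        tok$doc_id <- doc$doc_id
        tok$section <- sec
        j <- j + 1L
        out[[j]] <- tok
      }
    }
  }
  fots <- if (j) do.call(rbind, out[seq_len(j)]) else
    data.frame(surface = character(), start = integer(), end = integer(),
               label = character(), doc_id = character(),
               section = character(), stringsAsFactors = FALSE)
  fots <- fots[, c("doc_id", "section", "surface", "start", "end", "label")]
  rownames(fots) <- NULL
  attr(fots, "window") <- as.integer(window)
  fots
}

# Integer group id per (doc_id, section) run, used to stop context windows at
# section boundaries.  Assumes fots rows are in document order (as built).
.fot_groups <- function(fots) {
  key <- paste(fots$doc_id, fots$section, sep = "\r")
  cumsum(c(TRUE, key[-1L] != key[-length(key)]))
}
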