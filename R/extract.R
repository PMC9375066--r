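#' Score every token of a document
#'
#' Tokenizes the document's title and abstract, forms each token's FoT with
#' the model's context window, and returns the per-token B-statistics and
#' calibrated probabilities -- the input of [extract_entities()].
#'
#' @param model A fitted, calibrated [cner()] model.
#' @param document A single annotated document ([new_document()]) or plain
#'   text (treated as an abstract).
#' @return Data frame with one row per token: `doc_id`, `section`,
#'   `surface`, `start`, `end`, `label`, `b_CNE`, `b_NON_CNE`, `pc`, `pnc`.
#' @export
score_tokens <- function(model, document) {
  corpus <- .as_corpus(document)
  fots <- build_fots(corpus, window = model$window)
  .score_fots(model, fots)
}

#' Extract whole chemical named entities from token scores
#'
#' Tokens with `pc - pnc` strictly above `threshold` that survive the
#' token-level filters are grouped into maximal runs of consecutive tokens
#' (within one document section).  Each run becomes a candidate entity whose
#' surface is the original document text from the first token's start to the
#' last token's end -- intervening text such as spaces and hyphens is
#' preserved -- and whose score is the mean `pc - pnc` of its member tokens.
#' Entity-level filters then remove whole candidates.
#'
#' @param scores Per-token score table from [score_tokens()] /
#'   [predict.cner_model()] (columns `doc_id`, `section`, `surface`,
#'   `start`, `end`, `pc`, `pnc`).
#' @param corpus The documents the scores refer to (needed to reconstruct
#'   entity surfaces from the original text).
#' @param threshold Decision threshold on `pc - pnc` (default 0.3; strict
#'   `>`).
#' @param filters List of filter rules, see [default_filters()]; use
#'   `list()` for none.
#' @return Data frame of extracted entities: `doc_id`, `section`, `start`,
#'   `end`, `surface`, `score`, `n_tokens`.
#' @export
extract_entities <- function(scores, corpus, threshold = 0.3,
                             filters = default_filters()) {
  docs <- .as_corpus(corpus)
  names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
  out <- list()
  if (nrow(scores)) {
    d <- scores$pc - scores$pnc
    keep <- d > threshold & apply_filters(scores$surface, filters, "TOKEN")
    grp <- .fot_groups(scores)
    run_id <- cumsum(keep & !c(FALSE, keep[-length(keep)] &
                                 grp[-length(grp)] == grp[-1L]))
    for (r in split(which(keep), run_id[keep])) {
      first <- r[1L]; last <- r[length(r)]
      doc <- docs[[scores$doc_id[first]]]
      text <- if (scores$section[first] == "TITLE") doc$title else doc$abstract
      s <- scores$start[first]; e <- scores$end[last]
      out[[length(out) + 1L]] <- data.frame(
        doc_id = scores$doc_id[first], section = scores$section[first],
        start = s, end = e,
        surface = substr(text, s + 1L, e),
        score = mean(d[r]), n_tokens = length(r),
        stringsAsFactors = FALSE)
    }
  }
  ents <- if (length(out)) do.call(rbind, out) else
    data.frame(doc_id = character(), section = character(), start = integer(),
               end = integer(), surface = character(), score = numeric(),
               n_tokens = integer(), stringsAsFactors = FALSE)
  ents <- ents[apply_filters(ents$surface, filters, "ENTITY"), , drop = FALSE]
  ents <- ents[order(ents$doc_id, ents$start), , drop = FALSE]
  rownames(ents) <- NULL
  ents
}

#' Exclusion filters for extraction
#'
#' A filter rule excludes candidate tokens (before run grouping) or whole
#' candidate entities (after).  The defaults approximate the exclusion list
#' used with the published model: tokens that are purely numeric, tokens of
#' punctuation only, and single unmatched brackets are dropped at the token
#' level; entities containing replacement or non-printable characters
#' ("incorrect encoding"), entities with unbalanced brackets, and
#' single-character non-alphanumeric entities are dropped at the entity
#' level.  Rules are deterministic and order-independent within a level.
#'
#' @param name Rule name.
#' @param level `"TOKEN"` or `"ENTITY"`.
#' @param pattern Regular expression; a candidate matching it is excluded.
#' @param test Alternatively a vectorized predicate returning TRUE where
#'   the candidate must be excluded.
#' @return `filter_rule()`: a rule object; `default_filters()`: a list of
#'   rules; `apply_filters()`: logical vector, TRUE where the candidate is
#'   kept.
#' @export
filter_rule <- function(name, level = c("TOKEN", "ENTITY"), pattern = NULL,
                        test = NULL) {
  level <- match.arg(level)
  if (is.null(test) == is.null(pattern)) {
    stop("give exactly one of pattern or test")
  }
  if (is.null(test)) {
    force(pattern)
    test <- function(x) grepl(pattern, x, perl = TRUE)
  }
  structure(list(name = name, level = level, pattern = pattern, test = test),
            class = "cner_filter")
}

#' @rdname filter_rule
#' @export
default_filters <- function() {
  list(
    filter_rule("numeric", "TOKEN", "^[0-9]+([.,][0-9]+)*$"),
    filter_rule("punctuation_only", "TOKEN", "^[^[:alnum:]]+$"),
    filter_rule("single_bracket", "TOKEN", "^[](){}[]$"),
    filter_rule("bad_encoding", "ENTITY",
                test = function(x) grepl("�", x, fixed = TRUE) |
                  grepl("[[:cntrl:]]", x)),
    filter_rule("unbalanced_brackets", "ENTITY", test = .unbalanced_brackets),
    filter_rule("single_char_symbol", "ENTITY",
                test = function(x) nchar(x) == 1L & !grepl("^[[:alnum:]]$", x))
  )
}

#' @rdname filter_rule
#' @param x Character vector of candidate surfaces.
#' @param rules List of filter rules.
#' @export
apply_filters <- function(x, rules, level = c("TOKEN", "ENTITY")) {
  level <- match.arg(level)
  keep <- rep(TRUE, length(x))
  for (r in rules) {
    if (inherits(r, "cner_filter") && r$level == level) {
      keep <- keep & !r$test(x)
    }
  }
  keep
}

.unbalanced_brackets <- function(x) {
  vapply(x, function(s) {
    for (pair in list(c("(", ")"), c("[", "]"), c("{", "}"))) {
      n_open <- lengths(regmatches(s, gregexpr(pair[1], s, fixed = TRUE)))
      n_close <- lengths(regmatches(s, gregexpr(pair[2], s, fixed = TRUE)))
      if (n_open != n_close) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

#' Read filter rules from a plain-text config file
#'
#' One rule per line: `LEVEL NAME REGEX`, whitespace-separated (the regex is
#' the rest of the line).  Lines starting with `#` and blank lines are
#' ignored.
#'
#' @param path Config file path.
#' @return List of filter rules.
#' @export
read_filters <- function(path) {
  lines <- .read_utf8_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, function(l) {
    parts <- strsplit(trimws(l), "[[:space:]]+")[[1]]
    if (length(parts) < 3L) stop("malformed filter line: ", l)
    filter_rule(parts[2], match.arg(parts[1], c("TOKEN", "ENTITY")),
                pattern = paste(parts[-(1:2)], collapse = " "))
  })
}
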