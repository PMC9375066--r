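#' Parameters for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the recognizer relies
#' on: chemical names whose character n-gram distribution is distinct from
#' background prose, heavy class imbalance (entity tokens are a small
#' fraction of all tokens), entities of one to several tokens, and frequent
#' cue words ("inhibitor", "compound", "treated", ...) adjacent to chemical
#' mentions, as is typical of pharmacological abstracts.
#'
#' @param n_docs Number of documents (default 200).
#' @param tokens_min,tokens_max Abstract length range in tokens (default
#'   40--80; titles get 5--9 tokens).
#' @param entity_rate Target fraction of tokens inside entity spans
#'   (default 0.06, reproducing the roughly 1:14 CNE imbalance of the
#'   merged class in expert-annotated corpora).
#' @param class_mix Entity class weights, by default proportional to the
#'   per-class training sizes of the reference corpus (ABBREVIATION 12506,
#'   FORMULA 13466, FAMILY 19017, SYSTEMATIC 32510, TRIVIAL 25140).
#' @param cue_prob Probability that an entity is flanked by a cue word on
#'   each side (default 0.3).  Cue words also occur throughout ordinary
#'   background prose (about a tenth of word draws), so flanking is a mild
#'   enrichment, not a marker.
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of it (default 42).
#' @return A `"generator_params"` list.
#' @export
generator_params <- function(n_docs = 200L, tokens_min = 40L,
                             tokens_max = 80L, entity_rate = 0.06,
                             class_mix = c(ABBREVIATION = 12506,
                                           SYSTEMATIC = 32510,
                                           FORMULA = 13466,
                                           FAMILY = 19017,
                                           TRIVIAL = 25140),
                             cue_prob = 0.3, seed = 42L) {
  stopifnot(n_docs >= 1L, tokens_min >= 1L, tokens_max >= tokens_min,
            entity_rate > 0, entity_rate < 1,
            all(class_mix >= 0), sum(class_mix) > 0,
            cue_prob >= 0, cue_prob <= 1)
  class_mix <- class_mix / sum(class_mix)
  if (!setequal(names(class_mix), .cner_base_classes)) {
    stop("class_mix must name exactly the five base entity classes")
  }
  structure(list(n_docs = as.integer(n_docs),
                 tokens_min = as.integer(tokens_min),
                 tokens_max = as.integer(tokens_max),
                 entity_rate = entity_rate,
                 class_mix = class_mix[.cner_base_classes],
                 cue_prob = cue_prob, seed = as.integer(seed)),
            class = "generator_params")
}

# ---- lexicons ------------------------------------------------------------

.bg_words <- c(
  "the", "of", "and", "in", "to", "with", "for", "was", "were", "is",
  "are", "that", "this", "study", "results", "effects", "effect",
  "analysis", "observed", "showed", "using", "based", "levels", "level",
  "increased", "decreased", "significant", "patients", "cells", "cell",
  "protein", "gene", "expression", "clinical", "model", "models", "data",
  "values", "value", "between", "after", "before", "during", "under",
  "response", "responses", "control", "controls", "group", "groups",
  "higher", "lower", "total", "found", "compared", "present", "report",
  "tests", "test", "evaluated", "measured", "performed", "obtained",
  "important", "different", "several", "various", "within", "human",
  "tissue", "plasma", "serum", "blood", "liver", "brain", "skin", "water",
  "samples", "sample", "days", "hours", "time", "rates", "rate",
  "changes", "change", "role", "function", "pathway", "processes",
  "process", "growth", "development", "factors", "factor", "induced",
  "related", "associated", "potential", "possible", "known", "novel",
  "specific", "common", "major", "minor", "first", "second", "three",
  "further", "however", "therefore", "also", "both", "each", "well",
  "been", "have", "has", "can", "may", "which", "these", "those",
  "other", "their", "its", "from", "into", "through", "against",
  "among", "more", "most", "some", "all", "one", "two", "new", "high",
  "low", "long", "short", "small", "large")

.cue_words <- c(
  "inhibitor", "inhibitors", "compound", "compounds", "derivative",
  "derivatives", "agent", "agents", "treated", "treatment", "activity",
  "synthesis", "concentration", "solution", "dose", "binding", "assay",
  "receptor")

.sys_prefixes <- c("meth", "eth", "prop", "but", "pent", "hex", "hept",
                   "oct", "cyclo", "benz", "phen", "chloro", "bromo",
                   "fluoro", "iodo", "nitro", "amino", "hydroxy", "oxo",
                   "keto", "di", "tri", "tetra", "iso", "thio", "sulfo",
                   "carb")
.sys_suffixes <- c("ane", "ene", "yne", "ol", "al", "one", "ate", "ide",
                   "ine", "yl", "oate", "amide", "ylene", "anol", "anone")
.sys_second <- c("acid", "ester", "anhydride", "amide", "chloride",
                 "oxide", "sulfate", "nitrate", "phosphate", "carboxylate")

.trivial_lexicon <- c(
  "aspirin", "caffeine", "morphine", "codeine", "quinine", "ibuprofen",
  "paracetamol", "naproxen", "penicillin", "ampicillin", "taxol",
  "menthol", "camphor", "urea", "glycerol", "acetone", "ethanol",
  "glucose", "fructose", "sucrose", "citric acid", "ascorbic acid",
  "salicylic acid", "folic acid", "lactic acid")

.family_stems <- c("flavon", "terpen", "alkal", "ster", "polyphen",
                   "benzodiazep", "sulfonam", "barbitur", "quinol",
                   "porphyr", "coumar", "saponin", "xanth", "caroten",
                   "glycos")
.family_suffixes <- c("oids", "ines", "ides", "ols", "ones", "osides")

.formula_elements <- c("C", "H", "N", "O", "S", "P", "Cl", "Br", "Na",
                       "K", "Ca", "Fe", "Mg", "Zn")

.abbrev_lexicon <- c("DMSO", "EDTA", "ATP", "ADP", "AMP", "NADH", "NADPH",
                     "THF", "DMF", "GABA", "DDT", "TNT", "PVC", "PEG",
                     "SDS", "TRIS", "HEPES", "CTAB")

# mean token counts per entity class, matching the grammars below; used to
# set the entity insertion probability for a target entity_rate
.entity_mean_tokens <- c(ABBREVIATION = 1, SYSTEMATIC = 1.95, FORMULA = 1,
                         FAMILY = 1, TRIVIAL = 1.2)

# ---- entity grammars -----------------------------------------------------

.gen_systematic <- function() {
  word1 <- paste0(paste(sample(.sys_prefixes, sample(2:4, 1L),
                               replace = TRUE), collapse = ""),
                  sample(.sys_suffixes, 1L))
  n_words <- sample(1:3, 1L, prob = c(0.3, 0.45, 0.25))
  if (n_words == 1L) return(word1)
  paste(c(word1, sample(.sys_second, n_words - 1L)), collapse = " ")
}

.gen_formula <- function() {
  n <- sample(2:4, 1L)
  paste(vapply(seq_len(n), function(i) {
    el <- sample(.formula_elements, 1L)
    cnt <- sample(1:12, 1L)
    if (cnt == 1L && stats::runif(1) < 0.5) el else paste0(el, cnt)
  }, character(1)), collapse = "")
}

.gen_entity <- function(class) {
  switch(class,
         SYSTEMATIC = .gen_systematic(),
         FORMULA = .gen_formula(),
         ABBREVIATION = sample(.abbrev_lexicon, 1L),
         FAMILY = paste0(sample(.family_stems, 1L),
                         sample(.family_suffixes, 1L)),
         TRIVIAL = sample(.trivial_lexicon, 1L))
}

.gen_background <- function() {
  u <- stats::runif(1)
  if (u < 0.06) return(sample(c(",", "."), 1L, prob = c(0.6, 0.4)))
  if (u < 0.08) return(as.character(sample(1:500, 1L)))
  if (u < 0.17) return(sample(.cue_words, 1L))
  sample(.bg_words, 1L)
}

# ---- generator -----------------------------------------------------------

#' Generate a synthetic annotated corpus with gold entity spans
#'
#' Builds `n_docs` documents of background prose with chemical named
#' entities planted at exact character offsets.  Entities are produced by
#' per-class grammars: SYSTEMATIC names are chains of chemical morphemes
#' ("cyclo", "meth", "chloro", ... plus a suffix), optionally followed by
#' head words such as "acid" or "sulfate"; FORMULA entities are
#' element-symbol/digit strings; ABBREVIATION, TRIVIAL and FAMILY entities
#' come from small fixed lexicons.  Each entity is flanked by a cue word
#' with probability `cue_prob` per side and always followed by at least one
#' background token, so gold spans never touch.  The corpus is a
#' deterministic function of `params$seed`.
#'
#' @param params A [generator_params()] object.
#' @return A list of annotated documents with gold `spans`; the parameters
#'   are attached as attribute `"params"`.
#' @examples
#' corpus <- generate_corpus(generator_params(n_docs = 5, seed = 7))
#' corpus[[1]]$spans
#' @export
generate_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  L <- sum(params$class_mix * .entity_mean_tokens[names(params$class_mix)])
  S <- 2 * params$cue_prob + 1        # cue tokens + forced separator
  r <- params$entity_rate
  q <- r / (L - r * (L + S - 1))      # entity insertion probability
  docs <- .with_seed(params$seed, {
    lapply(seq_len(params$n_docs), function(i) {
      doc_id <- sprintf("SYN%05d", i)
      title <- .gen_section(sample(5:9, 1L), q, params)
      abstract <- .gen_section(sample(params$tokens_min:params$tokens_max, 1L),
                               q, params)
      d <- new_document(doc_id, title$text, abstract$text)
      spans <- rbind(.span_df(title$spans, "TITLE"),
                     .span_df(abstract$spans, "ABSTRACT"))
      d$spans <- spans
      d
    })
  })
  attr(docs, "params") <- params
  docs
}

# one section: returns list(text, spans = list of (start, end, surface, etype))
.gen_section <- function(n_tokens, q, params) {
  pieces <- character(0)
  len <- 0L
  count <- 0L
  spans <- list()
  add <- function(w) {
    if (len > 0L) len <<- len + 1L
    start <- len
    pieces[[length(pieces) + 1L]] <<- w
    len <<- len + nchar(w)
    count <<- count + length(strsplit(w, " ", fixed = TRUE)[[1]])
    c(start, len)
  }
  while (count < n_tokens) {
    if (stats::runif(1) < q) {
      if (stats::runif(1) < params$cue_prob) add(sample(.cue_words, 1L))
      class <- sample(names(params$class_mix), 1L, prob = params$class_mix)
      ent <- .gen_entity(class)
      pos <- add(ent)
      spans[[length(spans) + 1L]] <- list(start = pos[1], end = pos[2],
                                          surface = ent, etype = class)
      if (stats::runif(1) < params$cue_prob) add(sample(.cue_words, 1L))
      add(sample(.bg_words, 1L))      # entities never touch
    } else {
      add(.gen_background())
    }
  }
  list(text = paste(pieces, collapse = " "), spans = spans)
}

.span_df <- function(spans, section) {
  if (!length(spans)) return(.empty_spans())
  do.call(rbind, lapply(spans, function(s) {
    new_entity_span(section, s$start, s$end, s$surface, s$etype)
  }))
}

#' Corpus summary statistics
#'
#' Token (FoT) counts per class and the imbalance ratio R (all tokens over
#' class tokens), the per-class layout used to report training-set
#' composition.
#'
#' @param corpus A list of annotated documents.
#' @return Data frame with columns `class`, `N`, `R`; classes with zero
#'   tokens get `R = NA`.  Total token and document counts are attached as
#'   attributes `"n_tokens"` and `"n_docs"`.
#' @export
corpus_stats <- function(corpus) {
  fots <- build_fots(corpus, window = 0L)
  total <- nrow(fots)
  memb <- .class_membership(fots$label)
  N <- colSums(memb)
  out <- data.frame(class = colnames(memb), N = as.integer(N),
                    R = ifelse(N > 0, total / N, NA_real_),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_tokens") <- total
  attr(out, "n_docs") <- length(corpus)
  out
}
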