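# Independent brute-force oracles.  These deliberately share no code with
# the package internals: plain loops, no vectorized counting, no shared
# helpers, so agreement is evidence and not tautology.

# all distinct uppercase substrings of length 1..n_max, by double loop
oracle_ngrams <- function(token, n_max) {
  token <- toupper(token)
  L <- nchar(token)
  out <- character(0)
  if (L == 0) return(out)
  for (s in 1:L) {
    for (e in s:min(L, s + n_max - 1)) {
      out <- c(out, substr(token, s, e))
    }
  }
  unique(out)
}

# a random FoT table usable both by cner() and by the oracle below:
# single-character-alphabet tokens so gram collisions are frequent
random_fots <- function(n_fot, seed, alphabet = letters[1:4],
                        labels = c("TRIVIAL", "SYSTEMATIC", "NON_CNE"),
                        max_len = 6, window = 0L) {
  set.seed(seed)
  surf <- vapply(seq_len(n_fot), function(i) {
    paste(sample(alphabet, sample(1:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  ends <- cumsum(nchar(surf) + 1L)
  fots <- data.frame(doc_id = "d1", section = "ABSTRACT", surface = surf,
                     start = ends - nchar(surf) - 1L, end = ends - 1L,
                     label = sample(labels, n_fot, replace = TRUE),
                     stringsAsFactors = FALSE)
  attr(fots, "window") <- as.integer(window)
  fots
}

# descriptor set of FoT i (target token plus window context), by loops
oracle_fot_set <- function(surfaces, i, window, n_max) {
  lo <- max(1, i - window)
  hi <- min(length(surfaces), i + window)
  out <- character(0)
  for (j in lo:hi) out <- c(out, oracle_ngrams(surfaces[j], n_max))
  unique(out)
}

# B-statistic recomputed from scratch: priors, conditionals, centred
# arcsine mean, sine, Moebius ratio.  `grams` is the query descriptor set;
# training = surfaces + labels forming single-section FoTs.
oracle_b <- function(surfaces, labels, window, n_max, grams, class) {
  n <- length(surfaces)
  sets <- lapply(seq_len(n), function(i)
    oracle_fot_set(surfaces, i, window, n_max))
  in_class <- function(lab) {
    if (class == "CNE") lab != "NON_CNE" else lab == class
  }
  Nk <- sum(vapply(labels, in_class, logical(1)))
  s0 <- 2 * Nk / n - 1
  if (s0 > 1) s0 <- 1
  if (s0 < -1) s0 <- -1
  terms <- c()
  for (g in unique(toupper(grams))) {
    Ni <- 0; Nik <- 0
    for (i in seq_len(n)) {
      if (g %in% sets[[i]]) {
        Ni <- Ni + 1
        if (in_class(labels[i])) Nik <- Nik + 1
      }
    }
    if (Ni > 0) {
      p <- Nik / Ni
      terms <- c(terms, asin(2 * p - 1) - asin(s0))
    }
  }
  m <- if (length(terms)) mean(terms) else 0
  sk <- sin(asin(s0) + m)
  b <- (sk - s0) / (1 - sk * s0)
  if (!is.finite(b)) 0 else b
}

# strict-inequality pairwise ranking accuracy by full enumeration
oracle_ia <- function(pos, neg) {
  hits <- 0
  for (p in pos) for (q in neg) if (p > q) hits <- hits + 1
  hits / (length(pos) * length(neg))
}

# rank-based AUC (Mann-Whitney, midrank convention)
oracle_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# tiny deterministic training corpus with one planted systematic name,
# used by extraction and per-position tests
micro_corpus <- function(n_docs = 40, seed = 11) {
  generate_corpus(generator_params(n_docs = n_docs, tokens_min = 20,
                                   tokens_max = 30, seed = seed))
}
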