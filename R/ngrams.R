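#' Multi-n-gram descriptor sets
#'
#' A token is represented by the set of all distinct contiguous character
#' substrings ("multi-n-grams") of length 1 to `n_max`, uppercased.  Set
#' semantics: a gram occurring several times in a token is kept once.
#'
#' @param token A character string (one token surface).
#' @param n_max Maximum gram length (default 5).
#' @return Character vector of distinct uppercase grams (a descriptor set).
#' @examples
#' token_ngrams("ab")           # "A" "B" "AB"
#' length(token_ngrams("cyclohexane"))
#' @export
token_ngrams <- function(token, n_max = 5L) {
  stopifnot(n_max >= 1L)
  token <- toupper(token)
  L <- nchar(token)
  if (L == 0L) return(character())
  grams <- character(0)
  for (n in seq_len(min(n_max, L))) {
    grams <- c(grams, substring(token, 1:(L - n + 1L), n:L))
  }
  unique(grams)
}

#' @describeIn token_ngrams Descriptor set of the grams covering one
#'   character position: all distinct uppercase substrings of length
#'   1..`n_max` whose interval contains `index` (0-based).  For an interior
#'   position this is the n(n+1)/2 grams the per-character scorer uses.
#' @param index 0-based character position within `token`.
#' @export
position_ngrams <- function(token, index, n_max = 5L) {
  stopifnot(n_max >= 1L)
  token <- toupper(token)
  L <- nchar(token)
  if (index < 0L || index >= L) {
    stop("position index ", index, " out of range for token of length ", L)
  }
  grams <- character(0)
  for (n in seq_len(min(n_max, L))) {
    # 0-based start s covers index iff s <= index <= s+n-1, and fits in token
    s <- max(0L, index - n + 1L):min(index, L - n)
    grams <- c(grams, substring(token, s + 1L, s + n))
  }
  unique(grams)
}

#' @describeIn token_ngrams Descriptor set of a whole FoT: the union of
#'   `token_ngrams` over the target token and its context tokens.  Grams
#'   never span token boundaries and no separator symbol is introduced.
#' @param surfaces Character vector of token surfaces (target plus contexts,
#'   in any order -- the result is a set).
#' @export
fot_descriptors <- function(surfaces, n_max = 5L) {
  if (length(surfaces) == 0L) return(character())
  unique(unlist(lapply(surfaces, token_ngrams, n_max = n_max),
                use.names = FALSE))
}

# Descriptor sets for all FoTs of a corpus at once, as a long index pair.
# Returns list(gram = chr vector, fot = int vector parallel to gram,
# n_fot = number of FoTs).  Descriptor sets are computed once per unique
# token surface and unioned over each FoT's context range within its
# (doc_id, section) group -- the hot path of fitting and prediction.
.fot_gram_long <- function(fots, window, n_max) {
  n <- nrow(fots)
  if (n == 0L) return(list(gram = character(), fot = integer(), n_fot = 0L))
  up <- toupper(fots$surface)
  uniq <- unique(up)
  sets <- lapply(uniq, token_ngrams, n_max = n_max)
  set_of <- match(up, uniq)
  grp <- .fot_groups(fots)
  per_fot <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- i
    hi <- i
    w <- window
    while (w > 0L && lo > 1L && grp[lo - 1L] == grp[i]) { lo <- lo - 1L; w <- w - 1L }
    w <- window
    while (w > 0L && hi < n && grp[hi + 1L] == grp[i]) { hi <- hi + 1L; w <- w - 1L }
    idx <- unique(set_of[lo:hi])
    g <- if (length(idx) == 1L) sets[[idx]] else
      unique(unlist(sets[idx], use.names = FALSE))
    per_fot[[i]] <- g
  }
  list(gram = unlist(per_fot, use.names = FALSE),
       fot = rep.int(seq_len(n), lengths(per_fot)),
       n_fot = n)
}
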