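#' Fit a chemical named-entity naive Bayes model
#'
#' `cner()` is the fitting front end of the package.  Every token of the
#' training corpus becomes one classified fragment of text (FoT): the token
#' itself plus up to `window` context tokens on each side, represented as the
#' set of uppercase character n-grams of length 1..`n_max` of its member
#' tokens.  The model is the table of sufficient statistics
#' \deqn{N, N_k, N_i, N_{ik}}
#' (total FoTs, FoTs per class, FoTs containing gram i, FoTs of class k
#' containing gram i), from which class priors \eqn{P(C_k) = N_k/N} and
#' per-gram conditionals \eqn{P(C_k|g_i) = N_{ik}/N_i} follow directly --
#' no iterative optimization is involved.
#'
#' Scoring uses the bounded B-statistic
#' \deqn{S_{0k} = 2P(C_k) - 1, \quad
#'       B_k = \frac{S_k - S_{0k}}{1 - S_k S_{0k}},}
#' where \eqn{S_k} aggregates the arcsine-transformed conditionals
#' \eqn{\arcsin(2P(C_k|g_i) - 1)} of the FoT's grams.  The arcsine transform
#' bounds each gram's contribution by \eqn{\pm\pi/2}, so conditionals of
#' exactly 0 or 1 cannot dominate the score.  With the default
#' `aggregate = "mean"` the contributions are centred on the prior and
#' averaged: \eqn{S_k = \sin(\arcsin(S_{0k}) + \overline{t})} with
#' \eqn{t_i = \arcsin(2P(C_k|g_i)-1) - \arcsin(S_{0k})}, so a gram carrying
#' no information (\eqn{P(C_k|g_i) = P(C_k)}) contributes exactly zero and an
#' empty descriptor set yields \eqn{B_k = 0}.  `aggregate = "sum"` instead
#' uses the plain sum \eqn{S_k = \sin(\sum_i \arcsin(2P(C_k|g_i)-1))} for
#' comparison.
#'
#' The five base entity classes (ABBREVIATION, SYSTEMATIC, FORMULA, FAMILY,
#' TRIVIAL) are scored alongside the merged class CNE (their union) and
#' NON_CNE.  After counting, a probability calibration maps B-statistics to
#' the calibrated probabilities Pc and Pnc used for extraction (see
#' [calibrate_b()]).  The calibration is fitted on the target-token scale:
#' each training token is scored by its own descriptor set, under
#' leave-one-out exclusion of its full FoT contribution, so no token is
#' calibrated against counts it produced itself.  Target-token scoring is
#' also what the extractor thresholds: the windowed FoT union is shared
#' between an entity token and its immediate neighbours, so it separates
#' entity regions from the rest of the text but cannot delimit them, while
#' the token's own grams can.  The context window still shapes every
#' conditional through the training counts.
#'
#' @param corpus A list of annotated documents (from [generate_corpus()],
#'   [read_abstracts()] + [read_annotations()]), or a prebuilt FoT table
#'   from [build_fots()].
#' @param window Context tokens kept on each side of the target (0--3;
#'   default 1, the configuration with the best accuracy/complexity
#'   trade-off).
#' @param n_max Maximum n-gram length (default 5).
#' @param aggregate `"mean"` (default) or `"sum"`; see Details.
#' @param alpha Optional Laplace smoothing for conditionals,
#'   \eqn{(N_{ik}+\alpha)/(N_i+2\alpha)}; default 0 (no smoothing).
#' @param calibrate Fit the Pc/Pnc calibration (default TRUE).
#' @param calib_method `"binned"` (equal-frequency bins + piecewise-linear
#'   interpolation, the default) or `"poly"` (least-squares polynomial).
#' @param calib_bins Number of equal-frequency calibration bins.
#' @param calib_degree Polynomial degree for `calib_method = "poly"`.
#' @param map_etype Annotation-type to class-label mapping; see
#'   [default_etype_map()].
#' @return An object of class `"cner_model"`.
#' @seealso [predict.cner_model()], [b_statistic()], [loo_predict()],
#'   [extract_entities()], [kfold_cv()]
#' @examples
#' corpus <- generate_corpus(generator_params(n_docs = 20, seed = 1))
#' m <- cner(corpus, window = 1, n_max = 5)
#' m
#' @export
cner <- function(corpus, window = 1L, n_max = 5L,
                 aggregate = c("mean", "sum"), alpha = 0,
                 calibrate = TRUE, calib_method = c("binned", "poly"),
                 calib_bins = 20L, calib_degree = 5L,
                 map_etype = default_etype_map) {
  aggregate <- match.arg(aggregate)
  calib_method <- match.arg(calib_method)
  stopifnot(n_max >= 1L, alpha >= 0)
  fots <- if (is.data.frame(corpus)) corpus else
    build_fots(corpus, window = window, map_etype = map_etype)
  if (is.data.frame(corpus) && !is.null(attr(corpus, "window"))) {
    window <- attr(corpus, "window")
  }
  if (nrow(fots) == 0L) stop("cannot fit a model on an empty corpus")

  long <- .fot_gram_long(fots, window = window, n_max = n_max)
  levels <- unique(long$gram)
  idx <- match(long$gram, levels)
  nlev <- length(levels)

  memb <- .class_membership(fots$label)          # n_fot x 7 logical
  Nk <- colSums(memb)
  Nik <- matrix(0L, nrow = nlev, ncol = length(.cner_classes),
                dimnames = list(NULL, .cner_classes))
  for (k in .cner_classes) {
    sel <- memb[long$fot, k]
    Nik[, k] <- tabulate(idx[sel], nbins = nlev)
  }

  model <- structure(list(
    levels = levels,
    Ni = tabulate(idx, nbins = nlev),
    Nik = Nik,
    N = nrow(fots),
    Nk = Nk,
    n_max = as.integer(n_max),
    window = as.integer(window),
    aggregate = aggregate,
    alpha = alpha,
    fots = fots,
    long = list(idx = idx, fot = long$fot),
    calibration = NULL
  ), class = "cner_model")

  if (calibrate) {
    # calibrate on the scale extraction thresholds: each training token
    # scored by its own descriptor set, under leave-one-out exclusion of
    # its full FoT contribution
    tlong <- .fot_gram_long(fots, window = 0L, n_max = n_max)
    idx_t <- match(tlong$gram, levels)
    b_cne <- .b_batch(model, idx_t, tlong$fot, model$N, "CNE",
                      loo_labels = fots$label)
    b_ncne <- .b_batch(model, idx_t, tlong$fot, model$N, "NON_CNE",
                       loo_labels = fots$label)
    model$calibration <- calibrate_b(
      b_cne, b_ncne, is_cne = fots$label != "NON_CNE",
      method = calib_method, bins = calib_bins, degree = calib_degree)
  }
  model
}

.cner_base_classes <- c("ABBREVIATION", "SYSTEMATIC", "FORMULA", "FAMILY",
                        "TRIVIAL")
.cner_classes <- c(.cner_base_classes, "CNE", "NON_CNE")

# n x 7 logical membership matrix; CNE is the union of the base classes
.class_membership <- function(labels) {
  m <- vapply(.cner_base_classes, function(k) labels == k,
              logical(length(labels)))
  if (length(labels) == 1L) m <- matrix(m, nrow = 1L,
                                        dimnames = list(NULL, .cner_base_classes))
  cbind(m, CNE = labels != "NON_CNE", NON_CNE = labels == "NON_CNE")
}

.in_class <- function(labels, class) {
  if (class == "CNE") labels != "NON_CNE" else labels == class
}

.clamp1 <- function(x) pmin(1, pmax(-1, x))

# Batch B-statistic over many FoTs given their descriptor index pairs.
#   idx: indices into model$levels (NA = gram unseen in training)
#   fot: parallel FoT ids in 1..n_fot
#   loo_labels: when non-NULL (length n_fot), each FoT's own contributions
#   are excluded from all counts before scoring (leave-one-out arithmetic:
#   N-1; Nk-1 when the FoT belongs to the class; Ni-1 for each of its grams;
#   Nik-1 for its grams when it belongs).
.b_batch <- function(model, idx, fot, n_fot, class, loo_labels = NULL) {
  alpha <- model$alpha
  loo <- !is.null(loo_labels)
  if (loo) {
    own <- .in_class(loo_labels, class)              # per fot
    N <- model$N - 1
    Nk <- model$Nk[class] - as.numeric(own)          # per fot
    s0 <- .clamp1(2 * Nk / N - 1)
    a0 <- asin(s0)                                   # per fot
  } else {
    N <- model$N
    s0 <- .clamp1(2 * model$Nk[class] / N - 1)
    a0 <- rep.int(asin(s0), 1L)
  }

  keep <- !is.na(idx)
  idx_k <- idx[keep]
  fot_k <- fot[keep]
  Ni <- model$Ni[idx_k]
  Nik <- model$Nik[idx_k, class]
  if (loo) {
    Ni <- Ni - 1
    Nik <- Nik - own[fot_k]
    bad <- Ni < 0 | Nik < 0
    if (any(bad)) stop("leave-one-out exclusion of a FoT that was not in training")
  }
  inf <- Ni + 2 * alpha > 0
  idx_k <- idx_k[inf]; fot_k <- fot_k[inf]
  p <- (Nik[inf] + alpha) / (Ni[inf] + 2 * alpha)
  t_i <- asin(.clamp1(2 * p - 1))

  if (model$aggregate == "mean") {
    a0_f <- if (loo) a0 else rep.int(a0, n_fot)
    t_i <- t_i - a0_f[fot_k]
    s <- numeric(n_fot)
    if (length(t_i)) {
      rs <- rowsum(t_i, group = fot_k)
      s[as.integer(rownames(rs))] <- rs[, 1L]
    }
    cnt <- tabulate(fot_k, nbins = n_fot)
    agg <- ifelse(cnt > 0L, s / pmax(cnt, 1L), 0)
    Sk <- sin(a0_f + agg)
  } else {
    s <- numeric(n_fot)
    if (length(t_i)) {
      rs <- rowsum(t_i, group = fot_k)
      s[as.integer(rownames(rs))] <- rs[, 1L]
    }
    Sk <- sin(s)
    if (loo) a0_f <- a0 else a0_f <- rep.int(a0, n_fot)
  }
  s0_f <- if (loo) s0 else rep.int(s0, n_fot)
  b <- (Sk - s0_f) / (1 - Sk * s0_f)
  b[!is.finite(b)] <- 0
  b
}

#' Low-level B-statistic for one descriptor set
#'
#' Computes \eqn{B_k} for a single descriptor set against a fitted model;
#' the building block behind all prediction functions.  Grams unseen in
#' training are uninformative and are skipped (equivalently, they contribute
#' the a-priori value, which the prior-centred aggregation maps to zero).
#'
#' @param model A fitted [cner()] model.
#' @param grams Character vector of descriptors (a descriptor set), e.g.
#'   from [token_ngrams()] or [fot_descriptors()]; may be empty.
#' @param class One of `"ABBREVIATION"`, `"SYSTEMATIC"`, `"FORMULA"`,
#'   `"FAMILY"`, `"TRIVIAL"`, `"CNE"`, `"NON_CNE"`.
#' @return A single value in \eqn{[-1, 1]}.
#' @export
b_statistic <- function(model, grams, class = "CNE") {
  stopifnot(inherits(model, "cner_model"), class %in% .cner_classes)
  grams <- unique(toupper(grams))
  idx <- match(grams, model$levels)
  .b_batch(model, idx, rep.int(1L, length(idx)), 1L, class)
}

#' Per-gram conditional probability
#'
#' \eqn{P(C_k|g_i) = N_{ik}/N_i} for a single descriptor, or `NA` when the
#' descriptor never occurred in training (`Ni = 0`): such grams are
#' uninformative and contribute nothing to the B-statistic.
#'
#' @inheritParams b_statistic
#' @param gram A single descriptor string.
#' @export
conditional <- function(model, gram, class = "CNE") {
  stopifnot(class %in% .cner_classes)
  i <- match(toupper(gram), model$levels)
  if (is.na(i) || model$Ni[i] + 2 * model$alpha == 0) return(NA_real_)
  (model$Nik[i, class] + model$alpha) / (model$Ni[i] + 2 * model$alpha)
}

#' Leave-one-out B-statistic for a training FoT
#'
#' Scores training FoT `i` with its own contributions removed from the
#' sufficient statistics (N-1; Nk-1 for its classes; Ni and Nik decremented
#' for each gram of its descriptor set) -- exactly equivalent to refitting
#' the model without that FoT, at constant cost.
#'
#' @inheritParams b_statistic
#' @param i Row index of the FoT in `model$fots`.
#' @export
loo_predict <- function(model, i, class = "CNE") {
  stopifnot(inherits(model, "cner_model"), class %in% .cner_classes,
            i >= 1L, i <= model$N)
  if (is.null(model$long)) stop("model was loaded without training FoTs; ",
                                "leave-one-out scoring is unavailable")
  sel <- model$long$fot == i
  idx <- model$long$idx[sel]
  .b_batch(model, idx, rep.int(1L, length(idx)), 1L, class,
           loo_labels = model$fots$label[i])
}

# Leave-one-out B for every training FoT at once (used by loo_cv and the
# fit-time calibration).
.loo_b_all <- function(model, class) {
  .b_batch(model, model$long$idx, model$long$fot, model$N, class,
           loo_labels = model$fots$label)
}

#' @export
print.cner_model <- function(x, ...) {
  cat("Naive Bayes chemical NER model (B-statistics)\n")
  cat(sprintf("  FoTs: %d   descriptors: %d   window: %d   n_max: %d\n",
              x$N, length(x$levels), x$window, x$n_max))
  cat(sprintf("  aggregate: %s   alpha: %g   calibration: %s\n",
              x$aggregate, x$alpha,
              if (is.null(x$calibration)) "none" else
                paste0(x$calibration$method, " (", x$calibration$bins,
                       " bins)")))
  nk <- x$Nk
  cat("  class counts:\n")
  for (k in names(nk)) cat(sprintf("    %-13s %8d\n", k, nk[[k]]))
  invisible(x)
}

#' @export
summary.cner_model <- function(object, ...) {
  nk <- object$Nk
  ratio <- ifelse(nk > 0, object$N / nk, NA_real_)
  out <- list(
    n_fots = object$N,
    n_descriptors = length(object$levels),
    window = object$window,
    n_max = object$n_max,
    class_counts = data.frame(class = names(nk), N = as.integer(nk),
                              R = round(ratio, 2),
                              row.names = NULL,
                              stringsAsFactors = FALSE),
    calibration = object$calibration
  )
  class(out) <- "summary.cner_model"
  out
}

#' @export
print.summary.cner_model <- function(x, ...) {
  cat("Naive Bayes chemical NER model\n")
  cat(sprintf("  %d FoTs, %d distinct descriptors, window %d, n_max %d\n\n",
              x$n_fots, x$n_descriptors, x$window, x$n_max))
  cat("Class counts (N) and imbalance ratio (R = all FoTs / class FoTs):\n")
  print(x$class_counts, row.names = FALSE)
  if (!is.null(x$calibration)) {
    cat(sprintf("\nCalibration: %s, %d bins\n", x$calibration$method,
                x$calibration$bins))
  }
  invisible(x)
}

#' Predict token scores for new text
#'
#' Tokenizes `newdata`, builds FoTs with the model's window, and scores each
#' token.  `type = "b"` returns the raw per-class B-statistics (`b_*` for
#' the windowed FoT descriptor set, `bt_*` for the token's own grams);
#' `type = "prob"` adds the calibrated probabilities `pc` and `pnc`
#' (functions of the target-token B);
#' `type = "entities"` runs the full extraction pipeline
#' ([extract_entities()]) with threshold `threshold` and `filters`.
#'
#' @param object A fitted [cner()] model.
#' @param newdata A character string, a single annotated document, or a list
#'   of annotated documents.
#' @param type `"prob"` (default), `"b"`, or `"entities"`.
#' @param threshold Extraction threshold on `pc - pnc` (default 0.3).
#' @param filters Extraction filter rules (default [default_filters()]).
#' @param classes Classes to score for `type = "b"`.
#' @param ... Unused.
#' @return A data frame of per-token scores, or of extracted entities for
#'   `type = "entities"`.
#' @export
predict.cner_model <- function(object, newdata, type = c("prob", "b", "entities"),
                               threshold = 0.3, filters = default_filters(),
                               classes = c("CNE", "NON_CNE"), ...) {
  type <- match.arg(type)
  corpus <- .as_corpus(newdata)
  fots <- build_fots(corpus, window = object$window)
  scores <- .score_fots(object, fots,
                        classes = if (type == "b") classes
                                  else c("CNE", "NON_CNE"),
                        probs = type != "b")
  if (type == "entities") {
    return(extract_entities(scores, corpus, threshold = threshold,
                            filters = filters))
  }
  scores
}

# Score a FoT table against a model.  Two scales are computed:
#   b_<class>  -- FoT-level B (target + context window), the recognizer
#                 output used for IA and class comparison;
#   bt_<class> -- target-token B (the token's own grams only), the scale
#                 the Pc/Pnc calibration and extraction thresholds live on.
# Context grams shape both through the training counts; the windowed union
# is deliberately not used for pc/pnc because an entity's immediate
# neighbours share it, which would make them indistinguishable.
.score_fots <- function(model, fots, classes = c("CNE", "NON_CNE"),
                        probs = TRUE) {
  long <- .fot_gram_long(fots, window = model$window, n_max = model$n_max)
  idx <- match(long$gram, model$levels)
  tlong <- .fot_gram_long(fots, window = 0L, n_max = model$n_max)
  idx_t <- match(tlong$gram, model$levels)
  for (k in classes) {
    fots[[paste0("b_", k)]] <- .b_batch(model, idx, long$fot, long$n_fot, k)
    fots[[paste0("bt_", k)]] <-
      .b_batch(model, idx_t, tlong$fot, tlong$n_fot, k)
  }
  if (probs) {
    if (is.null(model$calibration)) {
      stop("model has no calibration; refit with calibrate = TRUE")
    }
    fots$pc <- calib_pc(model$calibration, fots$bt_CNE)
    fots$pnc <- calib_pnc(model$calibration, fots$bt_NON_CNE)
  }
  attr(fots, "window") <- model$window
  fots
}

.as_corpus <- function(newdata) {
  if (is.character(newdata)) {
    lapply(seq_along(newdata), function(i)
      new_document(paste0("doc", i), "", newdata[i]))
  } else if (inherits(newdata, "cner_document")) {
    list(newdata)
  } else if (is.list(newdata)) {
    newdata
  } else {
    stop("newdata must be text, a document, or a list of documents")
  }
}

#' Per-character prediction within a token
#'
#' Scores one character position of a token using only the n-grams that
#' cover that position ([position_ngrams()]), returning the calibrated
#' `(pc, pnc)` pair used for colour rendering.
#'
#' @inheritParams b_statistic
#' @param token Token surface string.
#' @param index 0-based character position within the token.
#' @return Named numeric vector with elements `pc`, `pnc`, `b_CNE`,
#'   `b_NON_CNE`.
#' @export
predict_position <- function(model, token, index) {
  grams <- position_ngrams(token, index, n_max = model$n_max)
  b_c <- b_statistic(model, grams, "CNE")
  b_n <- b_statistic(model, grams, "NON_CNE")
  if (is.null(model$calibration)) stop("model has no calibration")
  c(pc = calib_pc(model$calibration, b_c),
    pnc = calib_pnc(model$calibration, b_n),
    b_CNE = b_c, b_NON_CNE = b_n)
}

#' @export
plot.cner_model <- function(x, ...) {
  if (is.null(x$calibration)) stop("model has no calibration to plot")
  plot(x$calibration, ...)
  invisible(x)
}
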