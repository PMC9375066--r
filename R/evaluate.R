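#' Invariant accuracy (pairwise ranking accuracy)
#'
#' The fraction of (positive, negative) score pairs in which the positive
#' example receives the strictly greater score:
#' \deqn{IA = \#[E(FoT_+) > E(FoT_-)] / (\#[FoT_+] \cdot \#[FoT_-]).}
#' On tie-free scores this coincides with the ROC AUC; with
#' `ties = "midrank"` tied pairs count 1/2, giving the usual Mann-Whitney
#' AUC on tied data.
#'
#' @param pos_scores Scores of the positive examples (nonempty).
#' @param neg_scores Scores of the negative examples (nonempty).
#' @param ties `"strict"` (default; ties count 0, the printed definition) or
#'   `"midrank"` (ties count 1/2, AUC convention).
#' @return A value in `[0, 1]`.
#' @examples
#' invariant_accuracy(c(0.7, 0.2), c(0.5, 0.1))  # 0.75
#' @export
invariant_accuracy <- function(pos_scores, neg_scores,
                               ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  if (!length(pos_scores) || !length(neg_scores)) {
    stop("invariant accuracy needs at least one positive and one negative")
  }
  srt <- sort(neg_scores)
  n_lt <- findInterval(pos_scores, srt, left.open = TRUE)  # neg < pos
  gt <- sum(as.numeric(n_lt))
  if (ties == "strict") {
    return(gt / (length(pos_scores) * length(neg_scores)))
  }
  n_le <- findInterval(pos_scores, srt)                    # neg <= pos
  (gt + 0.5 * sum(as.numeric(n_le - n_lt))) /
    (length(pos_scores) * length(neg_scores))
}

#' Confusion-matrix metrics
#'
#' Standard binary metrics from true/false positive/negative counts:
#' sensitivity (recall) `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)`, balanced accuracy (mean of sensitivity and specificity)
#' and F1.  A metric with a zero denominator is reported as `NA`, never as
#' zero.
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return One-row data frame with columns `sensitivity`, `specificity`,
#'   `precision`, `balanced_accuracy`, `f1`.
#' @examples
#' confusion_metrics(tp = 95, fp = 12, tn = 88, fn = 5)
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  ba <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  data.frame(sensitivity = sens, specificity = spec, precision = prec,
             balanced_accuracy = ba, f1 = f1)
}

#' Metric sweep over decision thresholds
#'
#' Classifies `scores > t` as positive for each threshold `t` on a grid and
#' tabulates the confusion metrics at every point, the table behind the
#' threshold-selection step of entity extraction.
#'
#' @param scores Per-example decision scores (e.g. `pc - pnc` or B values).
#' @param labels Logical (or 0/1) true-positive indicators, parallel to
#'   `scores`.
#' @param thresholds Threshold grid; default 41 equally spaced points over
#'   the score range, widened by one step on each side so the sweep spans
#'   sensitivity 1 down to 0.
#' @return Data frame with one row per threshold: `threshold`, `tp`, `fp`,
#'   `tn`, `fn`, the [confusion_metrics()] columns, and `ia` (the overall
#'   strict invariant accuracy of `scores`, constant across rows).
#' @export
threshold_sweep <- function(scores, labels, thresholds = NULL) {
  stopifnot(length(scores) == length(labels), length(scores) > 0L)
  labels <- as.logical(labels)
  if (is.null(thresholds)) {
    r <- range(scores)
    step <- if (diff(r) > 0) diff(r) / 40 else 1
    thresholds <- seq(r[1] - step, r[2] + step, length.out = 43L)
  }
  ia <- if (any(labels) && any(!labels)) {
    invariant_accuracy(scores[labels], scores[!labels])
  } else NA_real_
  rows <- lapply(thresholds, function(t) {
    pred <- scores > t
    m <- confusion_metrics(tp = sum(pred & labels), fp = sum(pred & !labels),
                           tn = sum(!pred & !labels), fn = sum(!pred & labels))
    cbind(data.frame(threshold = t, tp = sum(pred & labels),
                     fp = sum(pred & !labels), tn = sum(!pred & !labels),
                     fn = sum(!pred & labels)), m, data.frame(ia = ia))
  })
  do.call(rbind, rows)
}

#' Leave-one-out cross-validated invariant accuracy per class
#'
#' Scores every training FoT by its leave-one-out B-statistic
#' ([loo_predict()], computed in batch) and reports the one-vs-rest
#' invariant accuracy for each class.  A class with no positive (or no
#' negative) FoTs gets `NA`.
#'
#' @param model A fitted [cner()] model (with training FoTs retained).
#' @param classes Classes to evaluate (default all seven).
#' @param ties Tie convention for [invariant_accuracy()].
#' @return Named numeric vector of IA values.
#' @export
loo_cv <- function(model, classes = .cner_classes,
                   ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  stopifnot(inherits(model, "cner_model"))
  out <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (k in classes) {
    b <- .loo_b_all(model, k)
    pos <- .in_class(model$fots$label, k)
    if (any(pos) && any(!pos)) {
      out[k] <- invariant_accuracy(b[pos], b[!pos], ties = ties)
    }
  }
  out
}

#' k-fold cross-validation of recognition and extraction
#'
#' Partitions the *documents* (never individual FoTs, so no context leaks
#' between folds) into `k` folds by a seeded shuffle.  For each fold a model
#' is fitted on the remaining documents, every held-out token is scored, and
#' whole entities are extracted at threshold `threshold`.  Token-level
#' scores are pooled over folds for the IA and confusion metrics;
#' entity-level precision/recall use exact span matching against the gold
#' annotations (or overlap matching with `match = "overlap"`).
#'
#' @param corpus List of annotated documents (at least `k`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @param window,n_max,... Passed to [cner()].
#' @param threshold Extraction threshold on `pc - pnc` (default 0.3).
#' @param filters Extraction filters (default [default_filters()]).
#' @param match `"exact"` (default) or `"overlap"` entity matching.
#' @return An object of class `"cner_cv"`: a list with pooled `token_ia`
#'   (invariant accuracy of the per-token target-gram B score), `fot_ia`
#'   (the same for the windowed FoT-level B), `token_metrics` (at
#'   `threshold`), `entity_metrics` (precision, recall, f1, counts),
#'   per-fold assignments, and the pooled per-token score table.
#' @export
kfold_cv <- function(corpus, k = 5L, seed = 42L, window = 1L, n_max = 5L,
                     threshold = 0.3, filters = default_filters(),
                     match = c("exact", "overlap"), ...) {
  match <- match.arg(match)
  if (k < 2L) stop("k must be at least 2")
  if (length(corpus) < k) stop("need at least k documents")
  ids <- vapply(corpus, `[[`, character(1), "doc_id")
  rng <- .with_seed(seed, sample.int(length(corpus)))
  # assign folds round-robin along the shuffled document order
  fold <- stats::setNames(integer(length(corpus)), ids)
  fold[rng] <- rep(seq_len(k), length.out = length(corpus))

  score_all <- vector("list", k)
  gold_all <- vector("list", k)
  extr_all <- vector("list", k)
  for (f in seq_len(k)) {
    train <- corpus[fold != f]
    test <- corpus[fold == f]
    model <- cner(train, window = window, n_max = n_max, ...)
    fots <- build_fots(test, window = window)
    sc <- .score_fots(model, fots)
    sc$fold <- f
    score_all[[f]] <- sc
    extr_all[[f]] <- extract_entities(sc, test, threshold = threshold,
                                      filters = filters)
    gold_all[[f]] <- .gold_entities(test)
  }
  scores <- do.call(rbind, score_all)
  pos <- scores$label != "NON_CNE"
  # token_ia ranks tokens by the per-token estimate the extractor assigns
  # (target-token B); fot_ia uses the windowed FoT-level B for comparison
  token_ia <- if (any(pos) && any(!pos)) {
    invariant_accuracy(scores$bt_CNE[pos], scores$bt_CNE[!pos])
  } else NA_real_
  fot_ia <- if (any(pos) && any(!pos)) {
    invariant_accuracy(scores$b_CNE[pos], scores$b_CNE[!pos])
  } else NA_real_
  d <- scores$pc - scores$pnc
  token_metrics <- confusion_metrics(tp = sum(d > threshold & pos),
                                     fp = sum(d > threshold & !pos),
                                     tn = sum(d <= threshold & !pos),
                                     fn = sum(d <= threshold & pos))
  extracted <- do.call(rbind, extr_all)
  gold <- do.call(rbind, gold_all)
  entity_metrics <- .entity_match_metrics(extracted, gold, match)
  structure(list(k = k, seed = seed, window = window, n_max = n_max,
                 threshold = threshold, folds = fold,
                 token_ia = token_ia, fot_ia = fot_ia,
                 token_metrics = token_metrics,
                 entity_metrics = entity_metrics, scores = scores,
                 extracted = extracted, gold = gold),
            class = "cner_cv")
}

# gold spans of a document list as one entity table (merged CNE class)
.gold_entities <- function(corpus) {
  rows <- lapply(corpus, function(d) {
    s <- d$spans
    if (!nrow(s)) return(NULL)
    s$doc_id <- d$doc_id
    s[, c("doc_id", "section", "start", "end", "surface", "etype")]
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(doc_id = character(), section = character(),
                      start = integer(), end = integer(),
                      surface = character(), etype = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

.entity_match_metrics <- function(extracted, gold, match = "exact") {
  if (match == "exact") {
    key <- function(df) paste(df$doc_id, df$section, df$start, df$end,
                              sep = "\r")
    hit <- key(extracted) %in% key(gold)
    tp <- sum(hit)
    fp <- nrow(extracted) - tp
    fn <- sum(!(key(gold) %in% key(extracted)))
  } else {
    gkey <- paste(gold$doc_id, gold$section, sep = "\r")
    ekey <- paste(extracted$doc_id, extracted$section, sep = "\r")
    hit_e <- logical(nrow(extracted))
    hit_g <- logical(nrow(gold))
    for (i in seq_len(nrow(extracted))) {
      j <- which(gkey == ekey[i] & gold$start < extracted$end[i] &
                   gold$end > extracted$start[i])
      if (length(j)) { hit_e[i] <- TRUE; hit_g[j] <- TRUE }
    }
    tp <- sum(hit_e); fp <- sum(!hit_e); fn <- sum(!hit_g)
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  data.frame(precision = prec, recall = rec, f1 = f1,
             tp = tp, fp = fp, fn = fn, n_gold = nrow(gold),
             n_extracted = nrow(extracted))
}

#' @export
print.cner_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d, window %d, n_max %d)\n",
              x$k, x$seed, x$window, x$n_max))
  cat(sprintf("  token-level CNE IA: %.4f (FoT-level: %.4f)\n",
              x$token_ia, x$fot_ia))
  tm <- x$token_metrics
  cat(sprintf("  token metrics at pc - pnc > %.2f: sens %.3f  spec %.3f  prec %.3f  BA %.3f\n",
              x$threshold, tm$sensitivity, tm$specificity, tm$precision,
              tm$balanced_accuracy))
  em <- x$entity_metrics
  cat(sprintf("  entity extraction: recall %.3f  precision %.3f  F1 %.3f (%d gold, %d extracted)\n",
              em$recall, em$precision, em$f1, em$n_gold, em$n_extracted))
  invisible(x)
}

# evaluate expr with a temporary RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
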