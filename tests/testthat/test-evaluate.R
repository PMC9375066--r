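test_that("invariant accuracy counts strictly ordered pairs", {
  expect_equal(invariant_accuracy(c(0.9, 0.8), 0.1), 1)
  expect_equal(invariant_accuracy(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(invariant_accuracy(c(0.7, 0.2), c(0.5, 0.1)), 0.75)
  expect_error(invariant_accuracy(numeric(), 1), "at least one")
})

test_that("invariant accuracy equals AUC on tie-free scores", {
  set.seed(44)
  for (rep in 1:30) {
    pos <- stats::rnorm(sample(2:20, 1), mean = 0.5)
    neg <- stats::rnorm(sample(2:20, 1))
    expect_equal(invariant_accuracy(pos, neg), oracle_ia(pos, neg))
    expect_equal(invariant_accuracy(pos, neg), oracle_auc(pos, neg))
    # complement identity on tie-free data
    expect_equal(invariant_accuracy(pos, neg) + invariant_accuracy(neg, pos),
                 1)
  }
})

test_that("with ties the strict value is below the midrank value", {
  set.seed(45)
  for (rep in 1:20) {
    pos <- sample(1:4, 10, replace = TRUE)
    neg <- sample(1:4, 12, replace = TRUE)
    strict <- invariant_accuracy(pos, neg)
    mid <- invariant_accuracy(pos, neg, ties = "midrank")
    expect_lte(strict, mid)
    expect_equal(strict, oracle_ia(pos, neg))
    expect_equal(mid, oracle_auc(pos, neg))
  }
})

test_that("confusion metrics follow the standard formulas", {
  m <- confusion_metrics(tp = 95, fp = 12, tn = 88, fn = 5)
  expect_equal(m$sensitivity, 0.95)
  expect_equal(m$specificity, 0.88)
  expect_equal(m$balanced_accuracy, 0.915)
  expect_equal(m$precision, 95 / 107)
  # zero denominators report missing, not zero
  expect_true(is.na(confusion_metrics(0, 0, 10, 5)$precision))
  expect_true(is.na(confusion_metrics(0, 3, 0, 0)$sensitivity))
  set.seed(46)
  for (rep in 1:20) {
    cts <- sample(1:50, 4)
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$sensitivity, cts[1] / (cts[1] + cts[4]))
    expect_equal(m$specificity, cts[3] / (cts[3] + cts[2]))
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                   (m$precision + m$sensitivity))
  }
})

test_that("threshold sweep spans the full sensitivity range", {
  set.seed(47)
  scores <- stats::rnorm(200)
  labels <- stats::runif(200) < 0.4
  sw <- threshold_sweep(scores, labels)
  expect_equal(sw$sensitivity[1], 1)
  expect_equal(sw$sensitivity[nrow(sw)], 0)
  expect_equal(sw$specificity[nrow(sw)], 1)
  # TPR and FPR are non-increasing in the threshold
  fpr <- 1 - sw$specificity
  expect_true(all(diff(sw$sensitivity) <= 1e-12))
  expect_true(all(diff(fpr) <= 1e-12))
})

test_that("ROC area from a sweep at all cut points equals the IA", {
  set.seed(48)
  scores <- sample(seq(-1, 1, length.out = 400), 120)  # tie-free
  labels <- stats::runif(120) < 0.5
  if (!any(labels)) labels[1] <- TRUE
  if (all(labels)) labels[1] <- FALSE
  sw <- threshold_sweep(scores, labels,
                        thresholds = c(min(scores) - 1, sort(scores)))
  tpr <- sw$sensitivity
  fpr <- 1 - sw$specificity
  auc <- sum(-diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  expect_equal(auc, invariant_accuracy(scores[labels], scores[!labels]),
               tolerance = 1e-12)
})

test_that("LOO CV separates disjoint-gram classes perfectly", {
  f <- data.frame(doc_id = "d", section = "ABSTRACT",
                  surface = c("aaa", "aab", "xxy", "xyy"),
                  start = c(0L, 4L, 8L, 12L), end = c(3L, 7L, 11L, 15L),
                  label = c("TRIVIAL", "TRIVIAL", "NON_CNE", "NON_CNE"),
                  stringsAsFactors = FALSE)
  attr(f, "window") <- 0L
  m <- cner(f, window = 0L, n_max = 2L, calibrate = FALSE)
  ia <- loo_cv(m, classes = c("TRIVIAL", "CNE", "NON_CNE"))
  expect_equal(unname(ia["CNE"]), 1)
  expect_equal(unname(ia["NON_CNE"]), 1)
  expect_true(is.na(loo_cv(m, classes = "FORMULA")[["FORMULA"]]))
})

test_that("LOO CV equals the naive retrain-per-sample procedure", {
  fots <- random_fots(50, seed = 55, window = 0L)
  m <- cner(fots, window = 0L, n_max = 3L, calibrate = FALSE)
  ia <- loo_cv(m, classes = "CNE")
  b <- vapply(seq_len(nrow(fots)), function(i) {
    rest <- fots[-i, ]; attr(rest, "window") <- 0L
    mm <- cner(rest, window = 0L, n_max = 3L, calibrate = FALSE)
    b_statistic(mm, token_ngrams(fots$surface[i], 3L), "CNE")
  }, numeric(1))
  pos <- fots$label != "NON_CNE"
  expect_equal(unname(ia["CNE"]), invariant_accuracy(b[pos], b[!pos]),
               tolerance = 1e-12)
})

test_that("LOO CV on shuffled labels sits at chance level", {
  set.seed(56)
  fots <- random_fots(400, seed = 57, window = 0L, max_len = 5)
  fots$label <- sample(fots$label)   # break any surface-label association
  attr(fots, "window") <- 0L
  m <- cner(fots, window = 0L, n_max = 2L, calibrate = FALSE)
  ia <- loo_cv(m, classes = "CNE", ties = "midrank")
  expect_lt(abs(ia[["CNE"]] - 0.5), 0.08)
})

test_that("k-fold CV partitions documents and is seed-deterministic", {
  corpus <- micro_corpus()
  cv1 <- kfold_cv(corpus, k = 4, seed = 9)
  cv2 <- kfold_cv(corpus, k = 4, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$token_ia, cv2$token_ia)
  expect_identical(cv1$entity_metrics, cv2$entity_metrics)
  expect_equal(sort(unique(cv1$folds)), 1:4)
  expect_equal(length(cv1$folds), length(corpus))
  expect_equal(sum(table(cv1$folds)), length(corpus))
  # every document's tokens are scored in exactly one test fold
  expect_equal(sort(unique(cv1$scores$doc_id)),
               sort(vapply(corpus, `[[`, character(1), "doc_id")))
  expect_error(kfold_cv(corpus, k = 1), "at least 2")
  # k = number of documents is leave-one-document-out
  small <- corpus[1:6]
  cv3 <- kfold_cv(small, k = 6, seed = 1)
  expect_equal(sort(as.integer(table(cv3$folds))), rep(1L, 6))
})
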