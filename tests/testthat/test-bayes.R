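# two-token corpus used by the direct-counting checks
tiny_fots <- function() {
  f <- data.frame(doc_id = "d", section = "ABSTRACT",
                  surface = c("a", "b"), start = c(0L, 2L), end = c(1L, 3L),
                  label = c("TRIVIAL", "NON_CNE"), stringsAsFactors = FALSE)
  attr(f, "window") <- 0L
  f
}

test_that("fit counts sufficient statistics with set semantics", {
  m <- cner(tiny_fots(), window = 0L, n_max = 5L, calibrate = FALSE)
  expect_equal(m$N, 2L)
  expect_equal(unname(m$Nk["TRIVIAL"]), 1)
  expect_equal(unname(m$Nk["CNE"]), 1)
  expect_equal(unname(m$Nk["NON_CNE"]), 1)
  expect_equal(m$Ni[match("A", m$levels)], 1L)
  expect_equal(unname(m$Nik[match("A", m$levels), "TRIVIAL"]), 1L)
  expect_equal(unname(m$Nik[match("A", m$levels), "NON_CNE"]), 0L)

  # a token with repeated grams increments Ni once
  f <- tiny_fots()
  f$surface <- c("aa", "b")
  m2 <- cner(f, window = 0L, calibrate = FALSE)
  expect_equal(m2$Ni[match("A", m2$levels)], 1L)
  expect_error(cner(f[0, ], calibrate = FALSE), "empty")
})

test_that("fit is invariant to the order of training FoTs", {
  fots <- random_fots(60, seed = 21)
  m1 <- cner(fots, window = 0L, n_max = 3L, calibrate = FALSE)
  perm <- fots[sample(nrow(fots)), ]
  attr(perm, "window") <- 0L
  m2 <- cner(perm, window = 0L, n_max = 3L, calibrate = FALSE)
  o <- match(m1$levels, m2$levels)
  expect_false(any(is.na(o)))
  expect_equal(m1$Ni, m2$Ni[o])
  expect_equal(m1$Nik, m2$Nik[o, ])
  expect_equal(m1$Nk, m2$Nk)
})

test_that("counts equal a brute-force recount on a random corpus", {
  fots <- random_fots(200, seed = 22, window = 1L)
  m <- cner(fots, window = 1L, n_max = 3L, calibrate = FALSE)
  sets <- lapply(seq_len(nrow(fots)), function(i)
    oracle_fot_set(fots$surface, i, 1L, 3L))
  for (g in sample(m$levels, 25)) {
    Ni <- sum(vapply(sets, function(s) g %in% s, logical(1)))
    Nik <- sum(vapply(seq_along(sets), function(i) {
      g %in% sets[[i]] && fots$label[i] != "NON_CNE"
    }, logical(1)))
    expect_equal(m$Ni[match(g, m$levels)], Ni)
    expect_equal(unname(m$Nik[match(g, m$levels), "CNE"]), Nik)
  }
})

test_that("conditional is Nik/Ni, NA when the gram is uninformative", {
  fots <- random_fots(50, seed = 23)
  m <- cner(fots, window = 0L, n_max = 3L, calibrate = FALSE)
  g <- m$levels[1]
  i <- match(g, m$levels)
  expect_equal(conditional(m, g, "CNE"), m$Nik[i, "CNE"] / m$Ni[i])
  expect_true(is.na(conditional(m, "ZZZZ", "CNE")))
})

test_that("B-statistic degenerate cases behave as specified", {
  # balanced prior, every gram conditional equal to the prior -> B = 0
  f <- data.frame(doc_id = "d", section = "ABSTRACT",
                  surface = c("ax", "ay"), start = c(0L, 3L), end = c(2L, 5L),
                  label = c("TRIVIAL", "NON_CNE"), stringsAsFactors = FALSE)
  attr(f, "window") <- 0L
  m <- cner(f, window = 0L, n_max = 1L, calibrate = FALSE)
  # gram "A" occurs in both FoTs: P(CNE|A) = 1/2 = P(CNE)
  expect_equal(b_statistic(m, "A", "CNE"), 0)
  # gram "X" occurs only in the CNE FoT: P = 1, prior 1/2 -> B = 1
  expect_equal(b_statistic(m, "X", "CNE"), 1)
  # empty descriptor set carries no information -> B = 0
  expect_equal(b_statistic(m, character(), "CNE"), 0)
  # unseen grams are skipped -> also no information
  expect_equal(b_statistic(m, c("Q", "ZZ"), "CNE"), 0)
})

test_that("B-statistic agrees with the brute-force oracle", {
  for (case in 1:30) {
    n <- sample(5:40, 1)
    w <- sample(0:2, 1)
    fots <- random_fots(n, seed = 300 + case, window = w)
    m <- cner(fots, window = w, n_max = 3L, calibrate = FALSE)
    set.seed(600 + case)
    for (class in c("CNE", "NON_CNE", "TRIVIAL")) {
      grams <- unique(c(sample(m$levels, min(5, length(m$levels))),
                        "QQQ"))  # include an unseen gram
      got <- b_statistic(m, grams, class)
      want <- oracle_b(fots$surface, fots$label, w, 3L, grams, class)
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(got >= -1 && got <= 1)
    }
  }
})

test_that("B is monotone in the aggregated conditional evidence", {
  # five single-letter grams engineered with conditionals 0, 1/4, 1/2,
  # 3/4, 1 under prior 1/2; single-gram B must increase strictly with the
  # conditional (B is increasing in Sk for fixed S0k)
  surf <- rep(c("a", "b", "c", "d", "e"), each = 4)
  n_cne <- c(a = 4, b = 3, c = 2, d = 1, e = 0)
  lab <- unlist(lapply(names(n_cne), function(g) {
    rep(c("TRIVIAL", "NON_CNE"), c(n_cne[[g]], 4 - n_cne[[g]]))
  }))
  f <- data.frame(doc_id = "d", section = "ABSTRACT", surface = surf,
                  start = seq(0, 38, 2), end = seq(1, 39, 2), label = lab,
                  stringsAsFactors = FALSE)
  attr(f, "window") <- 0L
  m <- cner(f, window = 0L, n_max = 1L, calibrate = FALSE)
  chain <- c("E", "D", "C", "B", "A")
  ps <- vapply(chain, function(g) conditional(m, g, "CNE"), numeric(1))
  expect_equal(unname(ps), c(0, 0.25, 0.5, 0.75, 1))
  bs <- vapply(chain, function(g) b_statistic(m, g, "CNE"), numeric(1))
  expect_true(all(diff(bs) > 0))
  expect_equal(unname(bs[c(1, 5)]), c(-1, 1))
})

test_that("leave-one-out scoring equals full retraining without the FoT", {
  # the two-FoT corpus reduces to a model fitted on the other FoT alone
  f <- tiny_fots()
  m <- cner(f, window = 0L, calibrate = FALSE)
  other <- f[2, ]; attr(other, "window") <- 0L
  m_other <- cner(other, window = 0L, calibrate = FALSE)
  expect_equal(loo_predict(m, 1L, "CNE"),
               b_statistic(m_other, token_ngrams("a"), "CNE"),
               tolerance = 1e-12)

  # window 0, where removing a FoT's contributions is exactly removing the
  # FoT (no re-windowing of neighbours): LOO must equal a full retrain
  for (case in 1:20) {
    n <- sample(5:30, 1)
    fots <- random_fots(n, seed = 900 + case, window = 0L)
    m <- cner(fots, window = 0L, n_max = 3L, calibrate = FALSE)
    i <- sample(n, 1)
    for (class in c("CNE", "NON_CNE")) {
      got <- loo_predict(m, i, class)
      grams <- oracle_fot_set(fots$surface, i, 0L, 3L)
      want <- oracle_b(fots$surface[-i], fots$label[-i], 0L, 3L, grams, class)
      expect_equal(got, want, tolerance = 1e-12)
      expect_true(got >= -1 && got <= 1)
    }
  }
})

test_that("leave-one-out matches count-level retraining with windows", {
  # with a context window, retraining must remove the FoT's *contributions*
  # (not the token, which would reshape neighbouring FoTs); verify against
  # a manual count-decrement oracle
  for (case in 1:10) {
    fots <- random_fots(20, seed = 950 + case, window = 1L)
    m <- cner(fots, window = 1L, n_max = 3L, calibrate = FALSE)
    i <- sample(20, 1)
    grams <- oracle_fot_set(fots$surface, i, 1L, 3L)
    in_cne <- fots$label[i] != "NON_CNE"
    s0 <- 2 * (m$Nk[["CNE"]] - in_cne) / (m$N - 1) - 1
    terms <- c()
    for (g in grams) {
      j <- match(g, m$levels)
      Ni <- m$Ni[j] - 1
      Nik <- m$Nik[j, "CNE"] - in_cne
      if (Ni > 0) terms <- c(terms, asin(2 * Nik / Ni - 1) - asin(s0))
    }
    mn <- if (length(terms)) mean(terms) else 0
    sk <- sin(asin(s0) + mn)
    want <- (sk - s0) / (1 - sk * s0)
    if (!is.finite(want)) want <- 0
    expect_equal(loo_predict(m, i, "CNE"), unname(want), tolerance = 1e-12)
  }
})

test_that("predict_fot style scoring is deterministic and class-consistent", {
  corpus <- micro_corpus()
  m <- cner(corpus)
  sc1 <- score_tokens(m, corpus[[1]])
  sc2 <- score_tokens(m, corpus[[1]])
  expect_identical(sc1, sc2)
  # grams seen only in CNE examples score CNE above NON_CNE
  f <- tiny_fots()
  mm <- cner(f, window = 0L, calibrate = FALSE)
  expect_gt(b_statistic(mm, "A", "CNE"), b_statistic(mm, "A", "NON_CNE"))
})

test_that("per-position prediction uses only covering grams", {
  corpus <- micro_corpus()
  m <- cner(corpus)
  # a systematic-entity morpheme position scores clearly chemical
  sys_tok <- NULL
  for (d in corpus) {
    s <- d$spans
    hit <- which(s$etype == "SYSTEMATIC" & !grepl(" ", s$surface))
    if (length(hit)) { sys_tok <- s$surface[hit[1]]; break }
  }
  expect_false(is.null(sys_tok))
  p <- predict_position(m, sys_tok, nchar(sys_tok) %/% 2)
  # a background word position scores clearly non-chemical
  q <- predict_position(m, "between", 3L)
  expect_lt(q[["pc"]], q[["pnc"]])
  # the morpheme position carries far more chemical evidence
  expect_gt(p[["b_CNE"]], q[["b_CNE"]])
  expect_gte(p[["pc"]], q[["pc"]])
  expect_error(predict_position(m, "abc", 7L), "out of range")
})

test_that("the sum aggregation mode reproduces the uncentred literal form", {
  f <- data.frame(doc_id = "d", section = "ABSTRACT",
                  surface = c("ax", "ay"), start = c(0L, 3L), end = c(2L, 5L),
                  label = c("TRIVIAL", "NON_CNE"), stringsAsFactors = FALSE)
  attr(f, "window") <- 0L
  m <- cner(f, window = 0L, calibrate = FALSE, aggregate = "sum")
  # gram X: P(CNE|X) = 1 -> sum of arcsin terms = pi/2, Sk = 1, B = 1
  expect_equal(b_statistic(m, "X", "CNE"), 1)
  # two grams A (p = 1/2) and X (p = 1): sum = 0 + pi/2 -> Sk = 1, B = 1
  expect_equal(b_statistic(m, c("A", "X"), "CNE"), 1)
})
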