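test_that("document-term construction counts, prunes and drops correctly", {
  rec <- make_records("D", "apple apple banana")
  dtm <- build_dtm(rec, stopwords = character())
  expect_equal(as.integer(doc_term_counts(dtm, 1)[c("apple", "banana")]),
               c(2L, 1L))
  # ubiquitous term pruned at max_doc_prop
  rec2 <- make_records("D", c("covid alpha", "covid beta", "covid gamma",
                              "delta epsilon"))
  dtm2 <- build_dtm(rec2, stopwords = character(), max_doc_prop = 0.5)
  expect_false("covid" %in% dtm2$vocab)
  # document emptied by pruning is dropped and logged
  rec3 <- make_records("D", c("covid", "covid zeta", "covid eta", "theta iota"))
  expect_message(dtm3 <- build_dtm(rec3, stopwords = character(),
                                   max_doc_prop = 0.5),
                 "dropped")
  expect_equal(dtm3$dropped_ids, "x001")
  expect_error(build_dtm(make_records("D", "one"), stopwords = character(),
                         min_k = 2), "smaller")
})

test_that("planted vocabulary survives the default pruning", {
  sim <- generate_corpus(small_benchmark_spec(seed = 51))
  dtm <- build_dtm(sim$records)
  planted_seen <- intersect(colnames(sim$truth$phi),
                            unique(unlist(strsplit(sim$records$text, " "))))
  expect_true(all(planted_seen %in% dtm$vocab))
})

test_that("degenerate one-word corpus yields forced normalization", {
  rec <- make_records("D", "apple")
  dtm <- build_dtm(rec, stopwords = character(), min_k = 1)
  fit <- suppressWarnings(fit_lda(dtm, 1, n_iter = 20, seed = 1))
  expect_equal(unname(fit$phi[1, 1]), 1)
  expect_equal(unname(fit$theta[1, 1]), 1)
})

test_that("separable corpus concentrates topics on their planted words", {
  # K documents each repeating one of K distinct words
  words <- c("alpha", "bravo", "charlie")
  rec <- make_records("D", rep(vapply(words, function(w)
    paste(rep(w, 20), collapse = " "), character(1)), each = 15))
  rec$id <- sprintf("d%03d", seq_len(nrow(rec)))
  dtm <- build_dtm(rec, stopwords = character())
  fit <- fit_lda(dtm, 3, alpha = 0.1, n_iter = 200, seed = 8)
  # match topics to words by argmax phi
  for (t in 1:3) {
    expect_gt(max(fit$phi[t, ]), 0.9)
    expect_equal(top_words(fit, t, 1),
                 names(which.max(fit$phi[t, ])))
  }
  expect_setequal(vapply(1:3, function(t) top_words(fit, t, 1), character(1)),
                  words)
  expect_true(all(apply(fit$theta, 1, max) > 0.9))
})

test_that("fits are row-stochastic, seed-deterministic, with rising trace", {
  sim <- generate_corpus(small_benchmark_spec(seed = 52))
  dtm <- build_dtm(sim$records)
  f1 <- fit_lda(dtm, 3, n_iter = 120, seed = 99)
  f2 <- fit_lda(dtm, 3, n_iter = 120, seed = 99)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$theta, f2$theta)
  expect_lt(max(abs(rowSums(f1$phi) - 1)), 1e-8)
  expect_lt(max(abs(rowSums(f1$theta) - 1)), 1e-8)
  tr <- f1$log_likelihood_trace
  n10 <- max(1, floor(length(tr) / 10))
  expect_gte(mean(tail(tr, n10)), mean(head(tr, n10)))
  expect_error(fit_lda(dtm, 3, n_iter = 50, burn_in = 50), "burn_in")
})

test_that("planted topics are recovered on a small benchmark", {
  sim <- generate_corpus(small_benchmark_spec(seed = 53, n_tweets = 600))
  dtm <- build_dtm(sim$records)
  fit <- fit_lda(dtm, 3, n_iter = 300, seed = 53)
  m <- match_topics(fit$phi, sim$truth$phi)
  expect_gt(m$mean_cosine, 0.8)
})

test_that("UMass coherence matches closed forms on constructed corpora", {
  # top words always cooccur: every pair contributes log((d+1)/d)
  rec <- make_records("D", rep("alpha bravo charlie", 12))
  rec$id <- sprintf("d%03d", seq_len(nrow(rec)))
  dtm <- build_dtm(rec, stopwords = character())
  fit <- fit_lda(dtm, 2, n_iter = 60, seed = 4)
  coh <- coherence_score(fit, dtm, top_n = 3)
  expected <- 3 * log(13 / 12)    # 3 ordered pairs, d = 12
  expect_equal(coh, rep(expected, 2), tolerance = 1e-10)

  # top words that never cooccur: each pair contributes log(1 / D(w_j))
  rec2 <- make_records("D", c(rep("alpha alpha", 6), rep("bravo bravo", 6)))
  rec2$id <- sprintf("d%03d", seq_len(nrow(rec2)))
  dtm2 <- build_dtm(rec2, stopwords = character())
  fit2 <- fit_lda(dtm2, 2, alpha = 0.1, n_iter = 150, seed = 5)
  coh2 <- coherence_score(fit2, dtm2, top_n = 2)
  expect_equal(coh2, rep(log(1 / 6), 2), tolerance = 1e-10)
})

test_that("planted top words outscore random word sets in coherence", {
  # needs a realistically sparse corpus: chance cooccurrence must be low
  # for document-based coherence to separate structure from noise
  sim <- generate_corpus(corpus_spec(n_tweets = 1000, n_topics = 5,
                                     vocab_size = 300, doc_length_mean = 15,
                                     mixture_concentration = 1, seed = 55))
  dtm <- build_dtm(sim$records)
  doc_sets <- lapply(dtm$tokens, unique)
  score_set <- function(widx) {
    present <- vapply(doc_sets, function(s) widx %in% s,
                      logical(length(widx)))
    sc <- 0
    for (i in 2:length(widx)) for (j in 1:(i - 1)) {
      co <- sum(present[i, ] & present[j, ])
      sc <- sc + log((co + 1) / sum(present[j, ]))
    }
    sc
  }
  phi_true <- sim$truth$phi
  true_mean <- mean(vapply(1:5, function(t) {
    w <- names(sort(phi_true[t, ], decreasing = TRUE))[1:10]
    score_set(match(intersect(w, dtm$vocab), dtm$vocab))
  }, numeric(1)))
  planted_idx <- which(dtm$vocab %in% colnames(phi_true))
  set.seed(55)
  wins <- vapply(1:100, function(r) {
    true_mean > score_set(sample(planted_idx, 10))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("k selection recommends the planted count and skips infeasible k", {
  sim <- generate_corpus(small_benchmark_spec(seed = 56, n_tweets = 600))
  dtm <- build_dtm(sim$records)
  sel1 <- select_k(dtm, 3, n_iter = 150)
  expect_equal(sel1$recommended_k, 3)
  v <- length(dtm$vocab)
  sel2 <- select_k(dtm, c(3, v + 10), n_iter = 150)
  expect_match(sel2$report$note[sel2$report$k == v + 10], "skipped")
  expect_equal(sel2$recommended_k, 3)
})

test_that("top tweets and sampled tweets are deterministic and bounded", {
  rec <- make_records("D", c("alpha alpha alpha", "alpha bravo bravo",
                             "bravo bravo bravo", "alpha alpha bravo"))
  rec$id <- c("d4", "d2", "d3", "d1")
  dtm <- build_dtm(rec, stopwords = character())
  fit <- fit_lda(dtm, 2, alpha = 0.1, n_iter = 150, seed = 2)
  expect_error(top_tweets(fit, 3), "out of range")
  expect_length(top_tweets(fit, 1, n = 10), 4)    # n > D returns all
  # K = 1: all theta equal, order falls back to ids
  fit1 <- suppressWarnings(fit_lda(dtm, 1, n_iter = 30, seed = 2))
  expect_equal(top_tweets(fit1, 1, 4), c("d1", "d2", "d3", "d4"))
  s1 <- sample_tweets(fit, 1, n = 2, seed = 7)
  s2 <- sample_tweets(fit, 1, n = 2, seed = 7)
  expect_identical(s1, s2)
  arg <- max.col(fit$theta, ties.method = "first")
  expect_true(all(s1 %in% rownames(fit$theta)[arg == 1]))
})
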