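test_that("frequency floor keeps 0.1% terms and counts document frequency", {
  texts_D <- c(rep("vaccine plan today", 1998), rep("warp speed vaccine", 2))
  texts_R <- rep("vaccine plan tomorrow", 50)
  rec <- rbind(make_records("D", texts_D), make_records("R", texts_R))
  rec$id <- sprintf("t%05d", seq_len(nrow(rec)))
  tab <- build_term_table(rec)
  expect_true("warp speed" %in% tab$term)      # 2/2000 = 0.1% boundary kept
  row <- tab[tab$term == "warp speed", ]
  expect_equal(row$n_D, 2); expect_equal(row$n_R, 0)

  texts_D2 <- c(rep("vaccine plan today", 1999), "warp speed vaccine")
  rec2 <- rbind(make_records("D", texts_D2), make_records("R", texts_R))
  rec2$id <- sprintf("t%05d", seq_len(nrow(rec2)))
  tab2 <- build_term_table(rec2)
  expect_false("warp speed" %in% tab2$term)    # 0.05% < floor dropped

  # duplicating a token within one tweet changes no proportion
  rec3 <- rec
  rec3$text[1] <- "vaccine vaccine plan plan today today vaccine"
  rec3$tokens <- NULL
  tab3 <- build_term_table(rec3)
  shared <- intersect(tab$term, tab3$term)
  expect_equal(tab[match(c("plan", "today"), tab$term), "prop_D"],
               tab3[match(c("plan", "today"), tab3$term), "prop_D"])

  expect_error(build_term_table(make_records(c("D", "R"), c("a", "b"))),
               "at least 10")
})

test_that("bigrams never cross sentence-final punctuation", {
  rec <- rbind(
    make_records("D", rep("warp speed. record time", 20)),
    make_records("R", rep("warp speed. record time", 20)))
  rec$id <- sprintf("t%03d", seq_len(nrow(rec)))
  tab <- build_term_table(rec)
  expect_true(all(c("warp speed", "record time") %in% tab$term))
  expect_false("speed record" %in% tab$term)
})

test_that("term tests flag planted enrichment with correct direction", {
  set.seed(31)
  sim <- generate_corpus(corpus_spec(n_tweets = 4000, seed = 31))
  rec <- plant_term(sim$records, "warpspeed", c(D = 0.01, R = 0.05))
  res <- test_terms(build_term_table(rec))
  row <- res[res$term == "warpspeed", ]
  expect_equal(row$direction, "R")
  expect_lt(row$p, 0.001 / attr(res, "m"))
  expect_true(row$significant)
  # equal-proportion term is never significant
  eq <- res[res$prop_D == res$prop_R & res$n_D > 0, ]
  if (nrow(eq) > 0) expect_false(any(eq$significant))
  # per-test cutoff arithmetic: alpha / m
  expect_equal(attr(res, "alpha") / attr(res, "m"), 0.001 / nrow(res))
})

test_that("Bonferroni significance is monotone in the family size", {
  set.seed(32)
  sim <- generate_corpus(corpus_spec(n_tweets = 2000, seed = 32))
  rec <- plant_term(sim$records, "warpspeed", c(D = 0.005, R = 0.06))
  res_full <- test_terms(build_term_table(rec))
  # shrink the family: restrict to a subset that includes the planted term
  sub <- build_term_table(rec)
  keep <- sub$term == "warpspeed" | seq_len(nrow(sub)) <= 50
  sub2 <- sub[keep, , drop = FALSE]
  attr(sub2, "party_totals") <- attr(sub, "party_totals")
  res_sub <- test_terms(sub2)
  sig_full <- res_full$term[res_full$significant]
  sig_sub <- res_sub$term[res_sub$significant]
  expect_true(all(intersect(sig_full, res_sub$term) %in% sig_sub))
})

test_that("label shuffles produce no more significant terms than chance", {
  sim <- generate_corpus(corpus_spec(n_tweets = 600,
                                     party_split = c(D = .5, R = .5, I = 0),
                                     n_topics = 3, vocab_size = 40,
                                     seed = 33))
  rec <- sim$records
  set.seed(33)
  counts <- vapply(1:200, function(i) {
    rec$party <- sample(rec$party)
    sum(test_terms(build_term_table(rec, ngram_max = 1))$significant)
  }, numeric(1))
  m_typ <- nrow(build_term_table(rec, ngram_max = 1))
  # expected false positives under Bonferroni at alpha = .001 is ~ .001;
  # allow generous Monte-Carlo slack
  expect_lte(mean(counts), 0.001 * 1 + 0.05)
})

test_that("scatter data maps zeros to the pseudo-floor and keeps geometry", {
  tab <- data.frame(term = c("even", "right"), n_D = c(5, 0), n_R = c(5, 8),
                    prop_D = c(0.05, 0), prop_R = c(0.05, 0.08),
                    stringsAsFactors = FALSE)
  attr(tab, "party_totals") <- c(D = 100, R = 100)
  res <- test_terms(tab)
  sc <- scatter_data(res)
  expect_equal(sc$log_prop_D[1], sc$log_prop_R[1])   # diagonal
  expect_equal(sc$log_prop_D[2], log10(1e-4))        # pseudo-floor
  expect_lt(sc$log_prop_D[2], sc$log_prop_R[2])      # R side of diagonal
  empty <- res[0, , drop = FALSE]
  expect_equal(nrow(scatter_data(empty)), 0)
})

test_that("per-wave analysis localizes a wave-specific term", {
  months <- month_seq("2020-02", "2020-07")
  sim <- generate_corpus(corpus_spec(n_tweets = 3000, months = months,
                                     seed = 35))
  rec <- sim$records
  # plant a D term only inside 2020-04/2020-05 (wave 2)
  set.seed(35)
  in_w2 <- rec$month %in% c("2020-04", "2020-05")
  hit <- in_w2 & rec$party == "D" & runif(nrow(rec)) < 0.2
  rec$text[hit] <- paste(rec$text[hit], "maskuppa")
  rec$tokens <- NULL
  boundaries <- as.Date(c("2020-04-01", "2020-06-01"))
  res <- per_wave_analysis(rec, boundaries, ngram_max = 1)
  expect_length(res, 3)
  sig2 <- res$wave2$term[res$wave2$significant]
  expect_true("maskuppa" %in% sig2)
  for (w in c("wave1", "wave3")) {
    tab <- res[[w]]
    expect_false("maskuppa" %in% tab$term[tab$significant])
  }
  # a single wave covering everything reproduces the overall analysis
  res_all <- per_wave_analysis(rec, as.Date(character(0)), ngram_max = 1)
  overall <- test_terms(build_term_table(rec, ngram_max = 1))
  expect_equal(res_all$wave1$term, overall$term)
  expect_equal(res_all$wave1$p, overall$p)
})
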