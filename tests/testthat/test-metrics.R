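test_that("mean topic representation is the stratum mean times 100", {
  expect_equal(unname(mean_topic_representation(c(0.5, 0.5))), c(50, 50))
  expect_equal(unname(mean_topic_representation(rbind(c(1, 0), c(0, 1)))),
               c(50, 50))
  expect_equal(unname(mean_topic_representation(rbind(c(0.2, 0.8),
                                                      c(0.4, 0.6)))),
               c(30, 70))
  expect_error(mean_topic_representation(matrix(0, 0, 2)), "empty")
  # sums to 100 for stochastic rows
  set.seed(1)
  th <- polarlex:::rdirichlet(20, rep(1, 6))
  expect_equal(sum(mean_topic_representation(th)), 100, tolerance = 1e-9)
})

test_that("polarization index hits its closed-form and boundary values", {
  mk <- function(thD, thR) {
    n <- nrow(thD) + nrow(thR)
    rec <- make_records(c(rep("D", nrow(thD)), rep("R", nrow(thR))),
                        rep("vaccine", n))
    rec$id <- sprintf("p%03d", seq_len(n))
    rec$month <- "2020-05"
    list(theta = rbind(thD, thR), rec = rec)
  }
  # identical representation -> 0
  x <- mk(rbind(c(0.6, 0.4)), rbind(c(0.6, 0.4)))
  expect_equal(polarization_series(x$theta, x$rec)$value, 0)
  # disjoint point masses -> 200
  x <- mk(rbind(c(1, 0)), rbind(c(0, 1)))
  expect_equal(polarization_series(x$theta, x$rec)$value, 200)
  # |60-30| + |40-70| = 60
  x <- mk(rbind(c(0.6, 0.4)), rbind(c(0.3, 0.7)))
  expect_equal(polarization_series(x$theta, x$rec)$value, 60)
})

test_that("polarization is symmetric, bounded, monotone under topic subsets", {
  sim <- generate_corpus(corpus_spec(n_tweets = 3000, seed = 61))
  ps <- polarization_series(sim$truth$theta, sim$records)
  expect_true(all(ps$value >= 0 & ps$value <= 200, na.rm = TRUE))
  swapped <- sim$records
  swapped$party <- chartr("DR", "RD", swapped$party)
  ps2 <- polarization_series(sim$truth$theta, swapped)
  expect_equal(ps$value, ps2$value)
  # restricting included topics can only decrease or preserve the value
  ps_sub <- polarization_series(sim$truth$theta, sim$records,
                                included_topics = c(1, 3))
  expect_true(all(ps_sub$value <= ps$value + 1e-12, na.rm = TRUE))
})

test_that("months missing a party yield NA, never zero", {
  rec <- make_records(c("D", "D", "R"), rep("vaccine", 3))
  rec$month <- c("2020-03", "2020-04", "2020-03")
  th <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_message(ps <- polarization_series(th, rec), "missing")
  expect_equal(ps$value[ps$month == "2020-03"], 200)
  expect_true(is.na(ps$value[ps$month == "2020-04"]))
  expect_equal(ps$n_R[ps$month == "2020-04"], 0)
})

test_that("trend summary captures sign pattern and monotone runs", {
  s <- data.frame(month = month_seq("2020-02", "2020-06"),
                  value = c(50, 40, 30, 45, 60))
  tc <- polarization_trend_check(s)
  expect_equal(unname(tc$signs), c(-1, -1, 1, 1))
  expect_equal(tc$longest_decreasing, 3)
  expect_equal(tc$longest_increasing, 3)
  s3 <- data.frame(month = month_seq("2020-02", "2020-04"),
                   value = c(1, 2, 3))
  expect_equal(polarization_trend_check(s3)$longest_increasing, 3)
  expect_error(polarization_trend_check(data.frame(month = "a", value = 1)),
               "3 non-missing")
})

test_that("planted V-shaped polarization trend is recovered", {
  hits <- vapply(1:5, function(r) {
    sp <- corpus_spec(n_tweets = 22000, seed = 700 + r)
    sim <- generate_corpus(sp)
    ps <- polarization_series(sim$truth$theta, sim$records)
    est <- sign(diff(ps$value))
    planted <- sign(diff(sim$truth$planted_polarization$value))
    all(est == planted)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("party topic comparisons detect planted enrichment", {
  # exact two-sided rank-sum enumeration: {1,2,3} vs {4,5,6} -> p = 0.1
  rec <- make_records(c(rep("D", 3), rep("R", 3)), rep("vaccine", 6))
  th <- cbind(c(1, 2, 3, 4, 5, 6) / 10, 1 - c(1, 2, 3, 4, 5, 6) / 10)
  res <- compare_party_topics(th, rec)
  expect_equal(res$p[1], 0.1)
  expect_equal(res$direction[1], "R")
  # identical distributions -> p = 1
  rec2 <- make_records(c("D", "D", "R", "R"), rep("vaccine", 4))
  th2 <- cbind(c(0.3, 0.7, 0.3, 0.7), c(0.7, 0.3, 0.7, 0.3))
  expect_equal(compare_party_topics(th2, rec2)$p, c(1, 1))
  # planted D-enriched topic at scale
  sim <- generate_corpus(corpus_spec(n_tweets = 10000, seed = 63))
  res3 <- compare_party_topics(sim$truth$theta, sim$records)
  # topic 1 planted D-leaning, topic 5 R-leaning (polarized axis)
  expect_true(res3$significant[res3$topic == 1])
  expect_equal(res3$direction[res3$topic == 1], "D")
  expect_equal(res3$direction[res3$topic == 5], "R")
})

test_that("paired monthly signed-rank variant runs and agrees on nulls", {
  sim <- generate_corpus(corpus_spec(n_tweets = 4000, seed = 64))
  res <- compare_party_topics(sim$truth$theta, sim$records,
                              method = "signedrank_monthly")
  expect_equal(nrow(res), 5)
  expect_true(all(res$p >= 0 & res$p <= 1))
  # middle topic of the polarized axis is planted non-partisan
  expect_false(res$significant[res$topic == 3])
})

test_that("topic representation table covers party-period cells", {
  sim <- generate_corpus(corpus_spec(n_tweets = 2000, seed = 65))
  tab <- topic_representation(sim$truth$theta, sim$records)
  sums <- tapply(tab$value, list(tab$party, tab$period), sum)
  expect_true(all(abs(sums - 100) < 0.01))
})
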