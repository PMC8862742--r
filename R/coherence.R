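#' UMass topic coherence
#'
#' Intrinsic coherence of each topic's top words based on document
#' cooccurrence in the modeled corpus:
#' \deqn{C_t = \sum_{i=2}^{N}\sum_{j<i} \log\frac{D(w_i, w_j) + 1}{D(w_j)}}
#' where `D(w)` counts documents containing `w` and `D(w_i, w_j)`
#' documents containing both, and words are ordered by topic
#' probability. Values are nonpositive; closer to zero means the top
#' words genuinely cooccur and the topic is more interpretable. Top
#' words with zero document frequency are excluded from the pairs with
#' a warning.
#'
#' @param model an `"lda_model"`.
#' @param dtm the `"lda_dtm"` the model was fitted on.
#' @param top_n number of top words per topic.
#' @return numeric vector of per-topic coherence values.
#' @export
coherence_score <- function(model, dtm, top_n = 10) {
  stopifnot(inherits(model, "lda_model"), inherits(dtm, "lda_dtm"))
  doc_sets <- lapply(dtm$tokens, unique)
  df_count <- setNames(dtm$doc_freq, dtm$vocab)
  vapply(seq_len(model$k), function(t) {
    words <- top_words(model, t, top_n)
    dfs <- df_count[words]
    if (any(dfs == 0 | is.na(dfs))) {
      warning("topic ", t, ": top word(s) with zero document frequency excluded")
      words <- words[!is.na(dfs) & dfs > 0]
    }
    if (length(words) < 2) return(NA_real_)
    widx <- match(words, dtm$vocab)
    present <- vapply(doc_sets, function(s) widx %in% s,
                      logical(length(widx)))   # |words| x D
    score <- 0
    for (i in 2:length(words)) {
      for (j in 1:(i - 1)) {
        co <- sum(present[i, ] & present[j, ])
        score <- score + log((co + 1) / sum(present[j, ]))
      }
    }
    score
  }, numeric(1))
}

#' Select the number of topics over a grid
#'
#' Fits one model per candidate `k` (each with the same seed policy so
#' runs are comparable and reproducible), scores mean UMass coherence,
#' and recommends the `k` with the highest mean coherence. Because
#' automated coherence is only half the story, the report also carries
#' a human-review sheet: top words and top document ids per topic for
#' every candidate, for manual interpretability checks. Candidates
#' larger than the vocabulary are skipped with a note; fit errors are
#' recorded and the grid continues.
#'
#' @param dtm an `"lda_dtm"`.
#' @param k_grid candidate topic counts.
#' @param seed seed applied to every fit.
#' @param top_n words/documents per topic in the review sheet.
#' @param ... passed to [fit_lda()] (e.g. `n_iter`).
#' @return an object of class `"k_selection"`: data frame `report`
#'   (`k`, `mean_coherence`, `log_likelihood`, `note`),
#'   `recommended_k`, and `review_sheet` (per-k list of per-topic top
#'   words and documents).
#' @export
select_k <- function(dtm, k_grid, seed = 1L, top_n = 10, ...) {
  if (length(k_grid) == 0) stop("empty k grid")
  v <- length(dtm$vocab)
  rows <- list(); review <- list()
  for (k in k_grid) {
    key <- paste0("k", k)
    if (k > v) {
      rows[[key]] <- data.frame(k = k, mean_coherence = NA_real_,
                                log_likelihood = NA_real_,
                                note = "skipped: k exceeds vocabulary size",
                                stringsAsFactors = FALSE)
      next
    }
    fit <- tryCatch(fit_lda(dtm, k, seed = seed, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[key]] <- data.frame(k = k, mean_coherence = NA_real_,
                                log_likelihood = NA_real_,
                                note = paste("error:", conditionMessage(fit)),
                                stringsAsFactors = FALSE)
      next
    }
    coh <- coherence_score(fit, dtm, top_n = top_n)
    rows[[key]] <- data.frame(k = k, mean_coherence = mean(coh, na.rm = TRUE),
                              log_likelihood =
                                fit$log_likelihood_trace[fit$n_iter],
                              note = "", stringsAsFactors = FALSE)
    review[[key]] <- lapply(seq_len(k), function(t) {
      list(topic = t, coherence = coh[t],
           top_words = top_words(fit, t, top_n),
           top_tweets = top_tweets(fit, t, top_n))
    })
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  ok <- !is.na(report$mean_coherence)
  recommended <- if (any(ok)) report$k[ok][which.max(report$mean_coherence[ok])]
                 else NA_integer_
  structure(list(report = report, recommended_k = recommended,
                 review_sheet = review),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Topic-count selection\n")
  print(x$report, row.names = FALSE)
  cat("Recommended k (max mean coherence):", x$recommended_k, "\n")
  cat("Review the per-topic word/tweet sheet before accepting.\n")
  invisible(x)
}
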