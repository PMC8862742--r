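#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Fits an LDA topic model: each document mixes `k` topics
#' (document-topic distribution `theta`) and each topic is a
#' distribution over the vocabulary (`phi`). Inference integrates out
#' `theta` and `phi` and resamples per-token topic assignments from
#' the collapsed conditional; the reported `phi` and `theta` are
#' posterior means over thinned post-burn-in count snapshots with
#' Dirichlet smoothing, which is more stable than a single final
#' state.
#'
#' Defaults follow common LDA practice: `alpha = 50 / k`,
#' `beta = 0.01`. The sampler uses R's random number generator, so a
#' fixed `seed` makes the fit bit-reproducible.
#'
#' @param dtm an `"lda_dtm"` from [build_dtm()].
#' @param k number of topics (at least 2 unless the corpus is a single
#'   degenerate document).
#' @param alpha document-topic Dirichlet concentration.
#' @param beta topic-word Dirichlet concentration.
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before averaging
#'   (default `n_iter / 2`); must be below `n_iter`.
#' @param thin snapshot spacing after burn-in.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an object of class `"lda_model"`: `phi` (`k x V`, rows sum
#'   to 1, columns named by vocabulary), `theta` (`D x k`, rows sum to
#'   1, rownames are document ids), `vocabulary`, `doc_ids`,
#'   `log_likelihood_trace`, the parameters, and the matched call.
#' @examples
#' sim <- generate_corpus(corpus_spec(n_tweets = 80, n_topics = 2,
#'                                    vocab_size = 40, seed = 3))
#' dtm <- build_dtm(sim$records)
#' fit <- fit_lda(dtm, k = 2, n_iter = 50, seed = 3)
#' terms(fit, n = 3)
#' @export
fit_lda <- function(dtm, k, alpha = 50 / k, beta = 0.01, n_iter = 500,
                    burn_in = floor(n_iter / 2), thin = 10, seed = NULL) {
  stopifnot(inherits(dtm, "lda_dtm"))
  k <- as.integer(k)
  if (k < 1) stop("k must be positive")
  if (burn_in >= n_iter) stop("burn_in must be below n_iter")
  v <- length(dtm$vocab)
  if (v < k) stop("vocabulary smaller than the number of topics")
  d <- length(dtm$tokens)
  if (d == 0) stop("degenerate document-term data: no documents")
  if (k > d) warning("more topics than documents; expect degenerate topics")
  if (!is.null(seed)) set.seed(seed)
  res <- lda_gibbs_cpp(dtm$tokens, k, v, alpha, beta,
                       as.integer(n_iter), as.integer(burn_in),
                       as.integer(thin))
  phi <- res$phi
  colnames(phi) <- dtm$vocab
  theta <- res$theta
  rownames(theta) <- dtm$doc_ids
  structure(list(phi = phi, theta = theta, vocabulary = dtm$vocab,
                 doc_ids = dtm$doc_ids, k = k, alpha = alpha, beta = beta,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed, n_snapshots = res$n_snapshots,
                 log_likelihood_trace = res$log_likelihood,
                 call = match.call()),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("LDA topic model (collapsed Gibbs)\n")
  cat("  topics:     ", x$k, "\n")
  cat("  vocabulary: ", length(x$vocabulary), " terms\n", sep = "")
  cat("  documents:  ", nrow(x$theta), "\n", sep = "")
  cat("  iterations: ", x$n_iter, " (burn-in ", x$burn_in, ", ",
      x$n_snapshots, " snapshots)\n", sep = "")
  invisible(x)
}

#' @export
summary.lda_model <- function(object, n = 10, dtm = NULL, ...) {
  tw <- lapply(seq_len(object$k), function(t) top_words(object, t, n))
  coh <- if (!is.null(dtm)) coherence_score(object, dtm, top_n = n) else NULL
  out <- list(k = object$k, top_words = tw, coherence = coh,
              log_likelihood = tail_value(object$log_likelihood_trace))
  class(out) <- "summary.lda_model"
  out
}

tail_value <- function(x) x[length(x)]

#' @export
print.summary.lda_model <- function(x, ...) {
  cat("LDA model with", x$k, "topics; final joint log-likelihood",
      format(x$log_likelihood, digits = 8), "\n")
  for (t in seq_len(x$k)) {
    coh <- if (!is.null(x$coherence)) {
      paste0(" (coherence ", format(x$coherence[t], digits = 3), ")")
    } else ""
    cat(sprintf("  topic %2d%s: %s\n", t, coh,
                paste(x$top_words[[t]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.lda_model <- function(object, which = c("phi", "theta"), ...) {
  which <- match.arg(which)
  object[[which]]
}

#' @export
logLik.lda_model <- function(object, ...) {
  structure(tail_value(object$log_likelihood_trace),
            df = object$k * (length(object$vocabulary) - 1),
            class = "logLik")
}

#' @export
plot.lda_model <- function(x, ...) {
  plot.default(seq_along(x$log_likelihood_trace), x$log_likelihood_trace,
               type = "l", xlab = "Gibbs iteration",
               ylab = "joint log-likelihood", ...)
  abline(v = x$burn_in, lty = 3)
  invisible(x)
}

#' Top words of a topic
#'
#' Terms ordered by topic-word probability, ties broken
#' alphabetically for determinism.
#'
#' @param model an `"lda_model"`.
#' @param topic topic index in `1..k`.
#' @param n number of words.
#' @return character vector of terms.
#' @export
top_words <- function(model, topic, n = 10) {
  if (topic < 1 || topic > model$k) stop("topic index out of range")
  p <- model$phi[topic, ]
  ord <- order(-p, names(p))
  names(p)[head(ord, n)]
}

#' @export
terms.lda_model <- function(x, topic = NULL, n = 10, ...) {
  topics <- if (is.null(topic)) seq_len(x$k) else topic
  out <- sapply(topics, function(t) top_words(x, t, n))
  if (is.matrix(out)) colnames(out) <- paste0("topic", topics)
  out
}

#' Tweets most associated with a topic
#'
#' Document ids ordered by the topic's probability in `theta`,
#' descending, ties broken by id.
#'
#' @param model an `"lda_model"`.
#' @param topic topic index.
#' @param n number of documents (capped at the corpus size).
#' @return character vector of document ids.
#' @export
top_tweets <- function(model, topic, n = 10) {
  if (topic < 1 || topic > model$k) stop("topic index out of range")
  p <- model$theta[, topic]
  ids <- rownames(model$theta)
  ord <- order(-p, ids)
  ids[head(ord, n)]
}

#' Random tweets whose dominant topic matches
#'
#' Draws uniformly among documents whose highest-probability topic is
#' `topic` — the spot-check used to confirm topic interpretability
#' against fresh examples.
#'
#' @param model an `"lda_model"`.
#' @param topic topic index.
#' @param n sample size (capped at the number of matching documents).
#' @param seed integer seed.
#' @return character vector of document ids.
#' @export
sample_tweets <- function(model, topic, n = 20, seed = 1L) {
  if (topic < 1 || topic > model$k) stop("topic index out of range")
  arg <- max.col(model$theta, ties.method = "first")
  ids <- rownames(model$theta)[arg == topic]
  set.seed(seed)
  if (length(ids) <= n) return(sort(ids))
  sort(sample(ids, n))
}
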