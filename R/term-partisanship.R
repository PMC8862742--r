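#' Per-tweet term sets (unigrams and bigrams)
#'
#' Each tweet contributes the set of distinct unigrams and adjacent
#' bigrams (space-joined, formed within sentences so phrases never
#' cross sentence-final punctuation) appearing in its text. Document
#' frequency — not token count — is the unit throughout: repeating a
#' word inside one tweet changes nothing.
#'
#' @param records tweet record data frame.
#' @param ngram_max 1 for unigrams only, 2 to add bigrams.
#' @return list of character vectors, one per tweet.
#' @keywords internal
tweet_term_sets <- function(records, ngram_max = 2) {
  sent <- tokenize_sentences(records$text)
  lapply(sent, function(sentences) {
    unis <- unlist(sentences, use.names = FALSE)
    terms <- unis
    if (ngram_max >= 2) {
      bis <- unlist(lapply(sentences, function(s) {
        if (length(s) < 2) return(character())
        paste(s[-length(s)], s[-1])
      }), use.names = FALSE)
      terms <- c(terms, bis)
    }
    unique(terms)
  })
}

#' Build the partisan term-frequency table
#'
#' Counts, for every unigram and 2-word phrase, the number of D and R
#' tweets containing it, and keeps terms whose document frequency
#' reaches `floor` (0.1% by default) in either party (`"per_party"`
#' denominator) or in the pooled D+R corpus (`"pooled"`).
#'
#' @param records tweet record data frame (parties other than D/R are
#'   ignored).
#' @param ngram_max maximum n-gram length (1 or 2).
#' @param floor minimum document-frequency proportion to retain a term.
#' @param denominator `"per_party"` (retain if `prop_D >= floor` OR
#'   `prop_R >= floor`) or `"pooled"`.
#' @return a `data.frame`: `term`, `n_D`, `n_R`, `prop_D`, `prop_R`.
#' @export
build_term_table <- function(records, ngram_max = 2, floor = 0.001,
                             denominator = c("per_party", "pooled")) {
  denominator <- match.arg(denominator)
  dr <- records[records$party %in% c("D", "R"), , drop = FALSE]
  n_D <- sum(dr$party == "D"); n_R <- sum(dr$party == "R")
  if (n_D < 10 || n_R < 10) {
    stop("need at least 10 tweets per party for stable proportions")
  }
  sets <- tweet_term_sets(dr, ngram_max)
  party <- rep(dr$party, lengths(sets))
  term <- unlist(sets, use.names = FALSE)
  cnt_D <- table(term[party == "D"])
  cnt_R <- table(term[party == "R"])
  terms <- union(names(cnt_D), names(cnt_R))
  kD <- as.integer(cnt_D[terms]); kD[is.na(kD)] <- 0L
  kR <- as.integer(cnt_R[terms]); kR[is.na(kR)] <- 0L
  pD <- kD / n_D; pR <- kR / n_R
  keep <- if (denominator == "per_party") {
    pD >= floor | pR >= floor
  } else {
    (kD + kR) / (n_D + n_R) >= floor
  }
  out <- data.frame(term = terms, n_D = kD, n_R = kR,
                    prop_D = pD, prop_R = pR,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "party_totals") <- c(D = n_D, R = n_R)
  out
}

#' Test terms for partisan differential use
#'
#' Per-term Pearson chi-square on the 2x2 table
#' (contains / does not contain) x (D / R), with Bonferroni control:
#' a term is significant when its raw p-value is below
#' `alpha / m`, `m` being the number of terms tested (all terms
#' passing the frequency floor). Direction is the party with the
#' higher document-frequency proportion; exact ties give `NA`.
#'
#' @param table output of [build_term_table()].
#' @param alpha family-wise significance level (default 0.001).
#' @return the table with added columns `chi2`, `p`, `significant`,
#'   `direction`; attribute `m` records the family size.
#' @export
test_terms <- function(table, alpha = 0.001) {
  totals <- attr(table, "party_totals")
  if (is.null(totals)) stop("table lacks party totals; use build_term_table()")
  m <- nrow(table)
  chi2 <- p <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    tab <- matrix(c(table$n_D[i], totals["D"] - table$n_D[i],
                    table$n_R[i], totals["R"] - table$n_R[i]),
                  nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- chi2_2x2(tab)
    chi2[i] <- res$statistic; p[i] <- res$p
  }
  table$chi2 <- chi2
  table$p <- p
  table$significant <- !is.na(p) & p < alpha / max(1, m)
  table$direction <- ifelse(table$prop_D > table$prop_R, "D",
                            ifelse(table$prop_R > table$prop_D, "R", NA))
  attr(table, "m") <- m
  attr(table, "alpha") <- alpha
  table
}

#' Plot-ready partisan term scatter data
#'
#' One row per retained term with log10-scaled per-party proportions
#' (zeros mapped to a pseudo-floor for display), significance and
#' direction — the data behind the classic D-vs-R word frequency
#' scatter.
#'
#' @param results output of [test_terms()].
#' @param pseudo_floor value substituted for zero proportions before
#'   taking logs.
#' @return a `data.frame`: `term`, `log_prop_D`, `log_prop_R`,
#'   `significant`, `direction`.
#' @export
scatter_data <- function(results, pseudo_floor = 1e-4) {
  if (nrow(results) == 0) {
    return(data.frame(term = character(), log_prop_D = numeric(),
                      log_prop_R = numeric(), significant = logical(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  data.frame(term = results$term,
             log_prop_D = log10(pmax(results$prop_D, pseudo_floor)),
             log_prop_R = log10(pmax(results$prop_R, pseudo_floor)),
             significant = results$significant,
             direction = results$direction,
             stringsAsFactors = FALSE)
}

#' Plot the partisan term scatter
#'
#' @param results output of [test_terms()].
#' @param ... passed to [graphics::plot.default()].
#' @return the scatter data, invisibly.
#' @export
plot_term_scatter <- function(results, ...) {
  sc <- scatter_data(results)
  col <- ifelse(!sc$significant, "grey60",
                ifelse(sc$direction == "D", "blue3", "red3"))
  plot.default(sc$log_prop_R, sc$log_prop_D, col = col, pch = 16,
               xlab = "log10 share of Republican tweets",
               ylab = "log10 share of Democratic tweets", ...)
  abline(0, 1, lty = 2)
  invisible(sc)
}

#' Per-wave differential term analysis
#'
#' Repeats [build_term_table()] + [test_terms()] inside each pandemic
#' wave; the frequency floor and the Bonferroni family are computed
#' per wave. Waves with fewer than 10 tweets in either party are
#' skipped with a warning.
#'
#' @param records tweet record data frame.
#' @param waves a `"wave_boundaries"` object or vector of boundary
#'   dates (see [segment_waves()]).
#' @param ... passed to [build_term_table()].
#' @param alpha family-wise level per wave.
#' @return named list of per-wave tested term tables (`wave1`,
#'   `wave2`, ...); skipped waves hold `NULL`.
#' @export
per_wave_analysis <- function(records, waves, alpha = 0.001, ...) {
  idx <- assign_waves(records, waves)
  n_waves <- max(idx)
  out <- vector("list", n_waves)
  names(out) <- paste0("wave", seq_len(n_waves))
  for (w in seq_len(n_waves)) {
    sub <- records[idx == w, , drop = FALSE]
    res <- tryCatch(test_terms(build_term_table(sub, ...), alpha = alpha),
                    error = function(e) {
                      warning("wave ", w, " skipped: ", conditionMessage(e))
                      NULL
                    })
    out[[w]] <- res
  }
  out
}
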