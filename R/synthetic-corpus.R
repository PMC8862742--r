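#' Specify a synthetic partisan tweet corpus
#'
#' Defines the generative model for a corpus with known ground truth:
#' two major parties (plus a small third-party share) authoring short
#' mixed-topic documents whose topic mixtures are party- and
#' month-specific, planting a polarization trend that downstream
#' estimators must recover. Defaults emulate a legislator vaccine-tweet
#' corpus: a roughly 62/37/1 D/R/I volume split, ~40% retweets,
#' COVID-19 mentions in just over half of tweets and non-COVID disease
#' mentions in a small partisan-skewed minority.
#'
#' @param n_tweets number of tweets to generate.
#' @param party_split named proportions over `c(D, R, I)`, summing to 1.
#' @param n_topics number of planted topics `K*` (at least 2).
#' @param vocab_size planted vocabulary size `V` (at least `10 * K*`).
#' @param topic_word_concentration symmetric Dirichlet parameter for
#'   each planted topic's word distribution; small values give sparse,
#'   separable topics.
#' @param party_topic_mixtures a `months x 3 x K*` array (parties in
#'   order D, R, I) of planted mean topic mixtures, or `NULL` to build
#'   a V-shaped polarization trend with [polarized_mixtures()].
#' @param mixture_concentration precision of per-document
#'   `Dirichlet(conc * mixture)` draws around the planted mean.
#' @param doc_length_mean Poisson mean tokens per tweet (minimum 3
#'   tokens is enforced so bigram extraction stays nondegenerate).
#' @param months ordered `"YYYY-MM"` labels.
#' @param month_weights sampling weights over months (default uniform).
#' @param retweet_prob,covid_tag_prob,noncovid_tag_prob named per-party
#'   probabilities (`D`, `R`, `I`).
#' @param polarization_profile planted polarization value per month
#'   (0-200 scale), used only when `party_topic_mixtures` is `NULL`.
#' @param seed integer seed; identical specs and seeds give identical
#'   corpora.
#' @return an object of class `"corpus_spec"`.
#' @seealso [generate_corpus()]
#' @export
corpus_spec <- function(n_tweets = 2000,
                        party_split = c(D = 0.618, R = 0.372, I = 0.010),
                        n_topics = 5,
                        vocab_size = 500,
                        topic_word_concentration = 0.05,
                        party_topic_mixtures = NULL,
                        mixture_concentration = 50,
                        doc_length_mean = 15,
                        months = month_seq("2020-02", "2020-12"),
                        month_weights = NULL,
                        retweet_prob = c(D = 0.403, R = 0.369, I = 0.386),
                        covid_tag_prob = c(D = 0.532, R = 0.583, I = 0.551),
                        noncovid_tag_prob = c(D = 0.144, R = 0.075, I = 0.118),
                        polarization_profile = NULL,
                        seed = 1L) {
  if (n_tweets < 1) stop("invalid field `n_tweets`: must be positive")
  if (abs(sum(party_split) - 1) > 1e-9) {
    stop("invalid field `party_split`: proportions must sum to 1")
  }
  if (n_topics < 2) stop("invalid field `n_topics`: K* must be at least 2")
  if (vocab_size < 10 * n_topics) {
    stop("invalid field `vocab_size`: need V >= 10 * K* for separable topics")
  }
  if (topic_word_concentration <= 0 || mixture_concentration <= 0) {
    stop("invalid field: concentrations must be positive")
  }
  if (is.null(month_weights)) month_weights <- rep(1, length(months))
  if (length(month_weights) != length(months)) {
    stop("invalid field `month_weights`: length mismatch with months")
  }
  if (is.null(party_topic_mixtures)) {
    party_topic_mixtures <- polarized_mixtures(n_topics, months,
                                               polarization_profile)
  }
  dm <- dim(party_topic_mixtures)
  if (length(dm) != 3 || dm[1] != length(months) || dm[2] != 3 ||
      dm[3] != n_topics) {
    stop("invalid field `party_topic_mixtures`: need a months x 3 x K* array")
  }
  dimnames(party_topic_mixtures) <- list(months, c("D", "R", "I"), NULL)
  sums <- apply(party_topic_mixtures, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("invalid field `party_topic_mixtures`: mixtures must sum to 1")
  }
  for (p in list(party_split, retweet_prob, covid_tag_prob, noncovid_tag_prob)) {
    if (any(p < 0 | p > 1)) stop("invalid field: probabilities outside [0, 1]")
  }
  structure(list(n_tweets = as.integer(n_tweets), party_split = party_split,
                 n_topics = as.integer(n_topics),
                 vocab_size = as.integer(vocab_size),
                 topic_word_concentration = topic_word_concentration,
                 party_topic_mixtures = party_topic_mixtures,
                 mixture_concentration = mixture_concentration,
                 doc_length_mean = doc_length_mean, months = months,
                 month_weights = month_weights / sum(month_weights),
                 retweet_prob = retweet_prob, covid_tag_prob = covid_tag_prob,
                 noncovid_tag_prob = noncovid_tag_prob,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat("Synthetic corpus spec: ", x$n_tweets, " tweets, K* = ", x$n_topics,
      ", V = ", x$vocab_size, ", ", length(x$months), " months (",
      x$months[1], " .. ", x$months[length(x$months)], ")\n", sep = "")
  pol <- planted_polarization_of(x$party_topic_mixtures, x$months)
  cat("Planted polarization range: ", round(min(pol$value), 1), " - ",
      round(max(pol$value), 1), "\n", sep = "")
  invisible(x)
}

#' Build party topic mixtures with a planted polarization trend
#'
#' Constructs per-month D and R mixtures as symmetric displacements
#' from the uniform mixture along a fixed partisan axis: the first half
#' of the topics lean Democratic, the last half Republican. The
#' displacement is scaled so the planted polarization index (sum of
#' absolute representation differences, 0-200) equals the requested
#' per-month profile exactly. Third-party mixtures are the uniform
#' baseline. The default profile is V-shaped — polarization falls from
#' February to an April nadir, rises through November, and dips
#' slightly in December — mirroring the trajectory reported for
#' legislator vaccine discourse in 2020.
#'
#' @param n_topics number of topics (at least 2).
#' @param months month labels.
#' @param profile planted polarization per month on the 0-200 scale;
#'   `NULL` gives the default V shape (interpolated to the number of
#'   months supplied).
#' @return a `months x 3 x n_topics` array (D, R, I).
#' @export
polarized_mixtures <- function(n_topics, months, profile = NULL) {
  if (is.null(profile)) {
    anchor <- c(60, 40, 25, 35, 45, 55, 65, 75, 85, 95, 90)
    profile <- if (length(months) == length(anchor)) anchor else {
      stats::approx(seq_along(anchor), anchor,
                    xout = seq(1, length(anchor),
                               length.out = length(months)))$y
    }
  }
  if (length(profile) != length(months)) {
    stop("profile length must match months")
  }
  if (any(profile < 0 | profile > 200)) stop("profile outside [0, 200]")
  k <- n_topics
  half <- floor(k / 2)
  delta <- numeric(k)
  delta[seq_len(half)] <- 1
  delta[(k - half + 1):k] <- -1
  delta <- delta / sum(abs(delta)) * 0.5   # sum |delta| = 0.5
  # polarization = 100 * sum |2 d * delta| = 200 d sum|delta| = 100 d
  base <- rep(1 / k, k)
  max_d <- (1 / k) / max(abs(delta))
  out <- array(0, dim = c(length(months), 3, k),
               dimnames = list(months, c("D", "R", "I"), NULL))
  for (m in seq_along(months)) {
    d <- profile[m] / 100
    if (d > max_d + 1e-12) {
      stop("profile value ", profile[m], " not representable with K = ", k,
           " (max ", round(100 * max_d, 1), ")")
    }
    out[m, "D", ] <- base + d * delta
    out[m, "R", ] <- base - d * delta
    out[m, "I", ] <- base
  }
  out
}

# Planted polarization per month from a mixtures array
planted_polarization_of <- function(mixtures, months) {
  value <- vapply(seq_along(months), function(m) {
    100 * sum(abs(mixtures[m, "D", ] - mixtures[m, "R", ]))
  }, numeric(1))
  data.frame(month = months, value = value, stringsAsFactors = FALSE)
}

# Tokens guaranteed to satisfy the vaccine lexicon in both match modes
VACCINE_ANCHOR_TOKENS <- c("vaccine", "vaccination", "vax")

#' Generate a synthetic tweet corpus with ground truth
#'
#' Draws `n_tweets` short documents from the generative model in a
#' [corpus_spec()]: each tweet gets a party (from the volume split), a
#' month, a document-topic mixture `theta ~ Dirichlet(conc * planted
#' mean)`, a Poisson length (minimum 3) and tokens sampled
#' topic-by-topic from planted topic-word distributions over an
#' abstract vocabulary (`w001`, `w002`, ...). Every document is
#' guaranteed to contain a vaccine-lexicon token: one is appended when
#' sampling produced none, so the planted topic structure is not
#' distorted. COVID-19 and other-disease marker tokens are inserted
#' with per-party probabilities, and retweet flags are drawn per party.
#'
#' @param spec a [corpus_spec()].
#' @return a list with `records` (tweet data frame, one row per tweet)
#'   and `truth` (class `"corpus_truth"`: per-document `theta`, planted
#'   `phi` with vocabulary column names, the mixtures array, and the
#'   planted monthly polarization computed from the mixtures).
#' @examples
#' sim <- generate_corpus(corpus_spec(n_tweets = 50, seed = 42))
#' head(sim$records$text, 2)
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  n <- spec$n_tweets
  k <- spec$n_topics
  v <- spec$vocab_size
  vocab <- sprintf("w%04d", seq_len(v))
  parties <- c("D", "R", "I")

  phi <- rdirichlet(k, rep(spec$topic_word_concentration, v))
  colnames(phi) <- vocab

  party <- sample(parties, n, replace = TRUE, prob = spec$party_split)
  month_idx <- sample(seq_along(spec$months), n, replace = TRUE,
                      prob = spec$month_weights)
  month <- spec$months[month_idx]

  theta <- matrix(0, n, k)
  lens <- pmax(3L, rpois(n, spec$doc_length_mean))
  texts <- character(n)
  for (i in seq_len(n)) {
    mix <- spec$party_topic_mixtures[month_idx[i], party[i], ]
    th <- rdirichlet(1, spec$mixture_concentration * mix)[1, ]
    theta[i, ] <- th
    z <- sample.int(k, lens[i], replace = TRUE, prob = th)
    tab <- tabulate(z, k)
    words <- character(lens[i])
    for (t in which(tab > 0L)) {
      words[z == t] <- vocab[sample.int(v, tab[t], replace = TRUE,
                                        prob = phi[t, ])]
    }
    if (!any(words %in% VACCINE_ANCHOR_TOKENS)) {
      words <- c(words, sample(VACCINE_ANCHOR_TOKENS, 1))
    }
    if (runif(1) < spec$covid_tag_prob[party[i]]) words <- c(words, "covid")
    if (runif(1) < spec$noncovid_tag_prob[party[i]]) words <- c(words, "flu")
    texts[i] <- paste(words, collapse = " ")
  }

  is_retweet <- runif(n) < spec$retweet_prob[party]
  chamber <- sample(c("state", "federal"), n, replace = TRUE,
                    prob = c(0.737, 0.263))
  n_authors <- max(20L, round(n / 8))
  author_id <- paste0(party, "_", sprintf("a%04d",
                                          sample.int(n_authors, n, replace = TRUE)))
  timestamp <- random_time_in_month(month)
  records <- data.frame(id = sprintf("t%06d", seq_len(n)),
                        timestamp = timestamp, author_id = author_id,
                        party = party, chamber = chamber,
                        is_retweet = is_retweet, text = texts, month = month,
                        stringsAsFactors = FALSE)
  truth <- structure(list(theta = theta, phi = phi,
                          mixtures = spec$party_topic_mixtures,
                          months = spec$months,
                          planted_polarization =
                            planted_polarization_of(spec$party_topic_mixtures,
                                                    spec$months)),
                     class = "corpus_truth")
  list(records = records, truth = truth)
}

# Uniform timestamps inside each "YYYY-MM" month label (UTC)
random_time_in_month <- function(month) {
  start <- as.POSIXct(paste0(month, "-01 00:00:00"), tz = "UTC")
  nxt <- as.POSIXct(sapply(month, function(m) {
    format(seq(as.Date(paste0(m, "-01")), by = "month", length.out = 2)[2])
  }), tz = "UTC")
  secs <- as.numeric(nxt) - as.numeric(start)
  out <- start + floor(runif(length(month)) * secs)
  attr(out, "tzone") <- "UTC"
  out
}

#' Write corpus ground truth as JSON
#'
#' @param truth a `"corpus_truth"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(theta = truth$theta, phi = truth$phi, months = truth$months,
         mixtures = truth$mixtures,
         planted_polarization = truth$planted_polarization),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Plant a marker term differentially by party
#'
#' Appends `term` to each tweet's text with party-specific
#' probabilities — a controlled enrichment used to validate the
#' differential term-frequency tests.
#'
#' @param records tweet record data frame.
#' @param term token to plant.
#' @param prob named per-party insertion probabilities (e.g.
#'   `c(D = 0.05, R = 0.01)`); parties absent from `prob` are never
#'   given the term.
#' @return the records with modified `text` (tokens dropped; retokenize
#'   downstream).
#' @export
plant_term <- function(records, term, prob) {
  p <- prob[records$party]
  p[is.na(p)] <- 0
  hit <- runif(nrow(records)) < p
  records$text[hit] <- paste(records$text[hit], term)
  records$tokens <- NULL
  records
}
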