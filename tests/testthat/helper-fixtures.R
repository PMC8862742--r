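# Small fixtures built in code, shared across test files.

# A minimal hand-built record frame (no generator involved)
make_records <- function(party, text, is_retweet = FALSE,
                         timestamp = "2020-03-15T12:00:00") {
  n <- length(text)
  df <- data.frame(
    id = sprintf("x%03d", seq_len(n)),
    timestamp = as.POSIXct(rep_len(timestamp, n),
                           format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    author_id = rep_len("a1", n),
    party = rep_len(party, n),
    chamber = rep_len("state", n),
    is_retweet = rep_len(is_retweet, n),
    text = text,
    stringsAsFactors = FALSE)
  toks <- normalize_text(df$text)
  if (!is.list(toks)) toks <- list(toks)
  df$tokens <- toks
  df
}

# Write a few JSONL tweet lines to a temp file; returns the path
write_jsonl_fixture <- function(rows) {
  path <- tempfile(fileext = ".jsonl")
  writeLines(vapply(rows, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
  }, character(1)), path)
  path
}

jsonl_row <- function(id, party = "D", text = "vaccine update",
                      timestamp = "2020-06-01T10:00:00", chamber = "state",
                      is_retweet = FALSE, author_id = "a1") {
  list(id = id, timestamp = timestamp, author_id = author_id, party = party,
       chamber = chamber, is_retweet = is_retweet, text = text)
}

# Small planted-topic corpus spec used by several topic-model tests
small_benchmark_spec <- function(seed, n_tweets = 400, n_topics = 3,
                                 vocab_size = 60) {
  corpus_spec(n_tweets = n_tweets, n_topics = n_topics,
              vocab_size = vocab_size, doc_length_mean = 12,
              mixture_concentration = 1, seed = seed)
}
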