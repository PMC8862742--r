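#' Standard English stopword list
#'
#' A compact list of common English function words removed before
#' topic modeling ("excluding common words"). Exposed so analyses can
#' extend or replace it.
#'
#' @return character vector of lowercase stopwords.
#' @export
english_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "arent", "as", "at", "be", "because", "been",
    "before", "being", "below", "between", "both", "but", "by", "cant",
    "cannot", "could", "couldnt", "did", "didnt", "do", "does", "doesnt",
    "doing", "dont", "down", "during", "each", "few", "for", "from",
    "further", "had", "hadnt", "has", "hasnt", "have", "havent", "having",
    "he", "hed", "hell", "hes", "her", "here", "heres", "hers", "herself",
    "him", "himself", "his", "how", "hows", "i", "id", "ill", "im", "ive",
    "if", "in", "into", "is", "isnt", "it", "its", "itself", "lets", "me",
    "more", "most", "mustnt", "my", "myself", "no", "nor", "not", "of",
    "off", "on", "once", "only", "or", "other", "ought", "our", "ours",
    "ourselves", "out", "over", "own", "same", "shant", "she", "shed",
    "shell", "shes", "should", "shouldnt", "so", "some", "such", "than",
    "that", "thats", "the", "their", "theirs", "them", "themselves", "then",
    "there", "theres", "these", "they", "theyd", "theyll", "theyre",
    "theyve", "this", "those", "through", "to", "too", "under", "until",
    "up", "very", "was", "wasnt", "we", "wed", "well", "were", "weve",
    "werent", "what", "whats", "when", "whens", "where", "wheres", "which",
    "while", "who", "whos", "whom", "why", "whys", "with", "wont", "would",
    "wouldnt", "you", "youd", "youll", "youre", "youve", "your", "yours",
    "yourself", "yourselves")
}

#' Build a document-term representation for topic modeling
#'
#' Tokenizes the records, removes stopwords, prunes rare terms (below
#' `min_doc_freq` documents) and ubiquitous terms (in more than
#' `max_doc_prop` of documents), and drops documents emptied by the
#' pruning (their ids are logged via a message and kept in the result).
#'
#' @param records tweet record data frame.
#' @param stopwords character vector to exclude; default
#'   [english_stopwords()].
#' @param min_doc_freq minimum number of documents containing a term.
#' @param max_doc_prop maximum share of documents containing a term.
#' @param min_k vocabulary must not fall below this (error otherwise).
#' @return an object of class `"lda_dtm"`: list with `tokens` (per
#'   document, integer word indices with repetition), `vocab`,
#'   `doc_ids`, `dropped_ids`, `doc_freq`.
#' @export
build_dtm <- function(records, stopwords = english_stopwords(),
                      min_doc_freq = 1, max_doc_prop = 1, min_k = 2) {
  if (0 > max_doc_prop || max_doc_prop > 1) stop("max_doc_prop outside [0, 1]")
  toks <- if (!is.null(records$tokens)) records$tokens else
    normalize_list(records$text)
  toks <- lapply(toks, function(t) t[!t %in% stopwords])
  n_docs <- length(toks)
  df <- table(unlist(lapply(toks, unique), use.names = FALSE))
  keep_terms <- names(df)[df >= min_doc_freq & df <= max_doc_prop * n_docs]
  vocab <- sort(keep_terms)
  if (length(vocab) < min_k) {
    stop("vocabulary (", length(vocab), " terms) smaller than required ",
         min_k, " after pruning")
  }
  idx <- lapply(toks, function(t) {
    m <- match(t, vocab)
    as.integer(m[!is.na(m)])
  })
  nonempty <- lengths(idx) > 0
  dropped <- records$id[!nonempty]
  if (length(dropped) > 0) {
    message(length(dropped), " document(s) emptied by pruning were dropped")
  }
  structure(list(tokens = idx[nonempty], vocab = vocab,
                 doc_ids = records$id[nonempty], dropped_ids = dropped,
                 doc_freq = as.integer(df[vocab])),
            class = "lda_dtm")
}

#' @export
print.lda_dtm <- function(x, ...) {
  cat("Document-term data: ", length(x$tokens), " documents, ",
      length(x$vocab), " terms, ", sum(lengths(x$tokens)), " tokens\n",
      sep = "")
  invisible(x)
}

# Term counts of one document as a named vector (used in examples/tests)
#' Term counts for one document
#' @param dtm an `"lda_dtm"`.
#' @param doc document index.
#' @return named integer vector of counts.
#' @export
doc_term_counts <- function(dtm, doc) {
  tab <- table(factor(dtm$vocab[dtm$tokens[[doc]]], levels = dtm$vocab))
  tab[tab > 0]
}
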