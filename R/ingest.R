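#' Build a lexicon of vaccine, COVID-19 and other disease terms
#'
#' A lexicon bundles the three term sets used to include and tag tweets:
#' vaccine terms (the inclusion filter), COVID-19 terms and
#' non-COVID-19 infectious-disease terms. Parenthetical spelling
#' variants written as `"vax(x)"` are expanded to both spellings.
#'
#' Two matching modes are supported. `"exact_word"` requires a token to
#' equal a listed term; `"stem_prefix"` matches any token that begins
#' with a listed stem, so `"vaccin"` covers vaccine, vaccines,
#' vaccination, vaccinated and so on. The default mode is
#' `"stem_prefix"`: short political texts use many inflections of the
#' same word and an exact list demonstrably under-includes.
#'
#' @param vaccine_terms,covid_terms,noncovid_disease_terms character
#'   vectors of lowercase terms or stems. Defaults cover the standard
#'   vaccine-discourse vocabulary.
#' @param exclusion_terms optional terms whose presence excludes a
#'   record from the vaccine subset (e.g. veterinary vaccination);
#'   default none.
#' @param match_mode `"stem_prefix"` (default) or `"exact_word"`.
#' @return an object of class `"lexicon"`.
#' @examples
#' lex <- lexicon()
#' match_lexicon(normalize_text("Get vaccinated today!"), lex$vaccine_terms,
#'               lex$match_mode)
#' @export
lexicon <- function(vaccine_terms = NULL,
                    covid_terms = NULL,
                    noncovid_disease_terms = NULL,
                    exclusion_terms = character(),
                    match_mode = c("stem_prefix", "exact_word")) {
  match_mode <- match.arg(match_mode)
  if (is.null(vaccine_terms)) {
    vaccine_terms <- if (match_mode == "stem_prefix") {
      c("vaccin", "vax", "immuniz", "immunis", "inoculat", "innoculat",
        "antivax", "anti-vax")
    } else {
      c("vaccine", "vaccination", "immunization", "vax(x)", "antivax(x)",
        "anti-vax(x)", "antivax(x)er", "anti-vax(x)er", "vax(x)ine",
        "in(n)oculate", "in(n)oculation")
    }
  }
  if (is.null(covid_terms)) {
    covid_terms <- c("covid", "covid19", "covid-19", "coronavirus",
                     "sars-cov-2", "sarscov2")
  }
  if (is.null(noncovid_disease_terms)) {
    noncovid_disease_terms <- c("flu", "influenza", "measles", "mmr", "hpv",
                                "polio", "smallpox", "fluseason")
  }
  vaccine_terms <- expand_variants(tolower(vaccine_terms))
  covid_terms <- expand_variants(tolower(covid_terms))
  noncovid_disease_terms <- expand_variants(tolower(noncovid_disease_terms))
  if (length(vaccine_terms) == 0 || length(covid_terms) == 0 ||
      length(noncovid_disease_terms) == 0) {
    stop("lexicon term sets must be nonempty")
  }
  overlap <- intersect(covid_terms, noncovid_disease_terms)
  if (length(overlap) > 0) {
    stop("covid_terms and noncovid_disease_terms overlap: ",
         paste(overlap, collapse = ", "))
  }
  structure(list(vaccine_terms = vaccine_terms,
                 covid_terms = covid_terms,
                 noncovid_disease_terms = noncovid_disease_terms,
                 exclusion_terms = expand_variants(tolower(exclusion_terms)),
                 match_mode = match_mode),
            class = "lexicon")
}

# "vax(x)" -> c("vax", "vaxx"); terms without parentheses pass through
expand_variants <- function(terms) {
  out <- lapply(terms, function(t) {
    if (!grepl("\\(", t)) return(t)
    with_opt <- gsub("\\(([^)]*)\\)", "\\1", t)
    without <- gsub("\\([^)]*\\)", "", t)
    unique(c(without, with_opt))
  })
  unique(unlist(out))
}

#' @export
print.lexicon <- function(x, ...) {
  cat("Lexicon (match mode: ", x$match_mode, ")\n", sep = "")
  cat("  vaccine terms:            ", length(x$vaccine_terms), "\n")
  cat("  COVID-19 terms:           ", length(x$covid_terms), "\n")
  cat("  non-COVID disease terms:  ", length(x$noncovid_disease_terms), "\n")
  if (length(x$exclusion_terms) > 0)
    cat("  exclusion terms:          ", length(x$exclusion_terms), "\n")
  invisible(x)
}

#' Normalize a text string into tokens
#'
#' Lowercases, removes URLs and @-handles, drops a leading retweet
#' marker (`"RT"`), strips `#` from hashtags while keeping the tag
#' word, and splits on punctuation. Hyphenated compounds are indexed
#' both ways: the compound token is kept and its parts are appended, so
#' `"anti-vaxxers"` yields `"anti-vaxxers"`, `"anti"` and `"vaxxers"`.
#'
#' @param text character vector of raw texts.
#' @return for a single string, a character vector of tokens; for a
#'   vector of texts, a list of token vectors.
#' @examples
#' normalize_text("RT @rep: https://t.co/x Vaccines work")
#' @export
normalize_text <- function(text) {
  out <- lapply(tokenize_sentences(text), function(s) unlist(s, use.names = FALSE))
  out <- lapply(out, function(x) if (is.null(x)) character() else x)
  if (length(text) == 1) out[[1]] else out
}

#' Tokenize into sentences of tokens
#'
#' Like [normalize_text()] but preserves sentence boundaries
#' (`.`, `!`, `?`), which bigram extraction must not cross.
#'
#' @param text character vector.
#' @return a list (one element per input text) of lists of token
#'   vectors, one per sentence.
#' @export
tokenize_sentences <- function(text) {
  lapply(as.character(text), function(t) {
    if (is.na(t) || !nzchar(t)) return(list())
    x <- tolower(t)
    x <- gsub("https?://\\S+|www\\.\\S+|\\bt\\.co/\\S+", " ", x)
    x <- gsub("@\\w+", " ", x)
    x <- sub("^\\s*rt\\b:?", " ", x)
    x <- gsub("#", "", x, fixed = TRUE)
    x <- gsub("[’'`´]", "", x)   # apostrophes removed, not split
    sentences <- strsplit(x, "[.!?]+")[[1]]
    toks <- lapply(sentences, function(s) {
      raw <- strsplit(s, "[^a-z0-9-]+")[[1]]
      raw <- raw[nzchar(raw)]
      raw <- gsub("^-+|-+$", "", raw)     # trim stray hyphens
      raw <- raw[nzchar(raw)]
      if (length(raw) == 0) return(character())
      unlist(lapply(raw, function(tok) {
        if (grepl("-", tok, fixed = TRUE)) {
          parts <- strsplit(tok, "-+")[[1]]
          c(tok, parts[nzchar(parts)])
        } else tok
      }), use.names = FALSE)
    })
    toks[vapply(toks, length, 1L) > 0]
  })
}

#' Test whether a token list matches a term set
#'
#' @param tokens normalized token vector (see [normalize_text()]).
#' @param terms character vector of terms (exact mode) or stems
#'   (prefix mode); parenthetical variants are expanded.
#' @param mode `"exact_word"` or `"stem_prefix"`.
#' @return logical scalar.
#' @export
match_lexicon <- function(tokens, terms, mode = c("stem_prefix", "exact_word")) {
  mode <- match.arg(mode)
  if (length(tokens) == 0) return(FALSE)
  terms <- expand_variants(tolower(terms))
  tokens <- tolower(tokens)
  if (mode == "exact_word") {
    any(tokens %in% terms)
  } else {
    any(vapply(terms, function(s) any(startsWith(tokens, s)), logical(1)))
  }
}

# Party and chamber alias tables -------------------------------------------

PARTY_ALIASES <- c(
  "d" = "D", "dem" = "D", "democrat" = "D", "democratic" = "D",
  "r" = "R", "rep" = "R", "republican" = "R",
  "i" = "I", "ind" = "I", "independent" = "I"
)

CHAMBER_ALIASES <- c(
  "state" = "state", "federal" = "federal",
  "house" = "federal", "senate" = "federal"
)

canonical_party <- function(x) {
  out <- unname(PARTY_ALIASES[tolower(trimws(as.character(x)))])
  bad <- is.na(out)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unrecognized party mapped to 'unknown'")
    out[bad] <- "unknown"
  }
  out
}

canonical_chamber <- function(x) {
  out <- unname(CHAMBER_ALIASES[tolower(trimws(as.character(x)))])
  out[is.na(out)] <- "unknown"
  out
}

#' Load tweet records from JSONL or CSV
#'
#' Expected fields/columns: `id`, `timestamp` (ISO 8601), `author_id`,
#' `party`, `chamber`, `is_retweet`, `text`. Party and chamber values
#' are mapped through an alias table (`Democrat`, `Rep`, ... ); values
#' that cannot be mapped become `"unknown"` with a warning.
#'
#' @param path file path.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension when
#'   omitted.
#' @return a `data.frame` of tweet records with UTC `POSIXct`
#'   timestamps and a `tokens` list-column of normalized tokens.
#' @export
load_tweets <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, jsonlite::fromJSON)
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r[c("id", "timestamp", "author_id", "party", "chamber",
                        "is_retweet", "text")], stringsAsFactors = FALSE)
    }))
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  required <- c("id", "timestamp", "author_id", "party", "chamber",
                "is_retweet", "text")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$id)) stop("duplicate tweet ids in ", path)
  df$is_retweet <- as.logical(df$is_retweet)
  df$timestamp <- parse_timestamp(df$timestamp)
  df$party <- canonical_party(df$party)
  df$chamber <- canonical_chamber(df$chamber)
  df$tokens <- normalize_text(df$text)
  if (length(df$tokens) == 1 && !is.list(df$tokens)) df$tokens <- list(df$tokens)
  message("loaded ", nrow(df), " tweet records from ", path)
  df
}

parse_timestamp <- function(x) {
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%d"))
  if (anyNA(ts)) stop("unparseable timestamp(s), e.g. ",
                      x[which(is.na(ts))[1]])
  ts
}

#' Write tweet records as JSONL
#'
#' @param records tweet record data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    row <- list(id = records$id[i],
                timestamp = format(records$timestamp[i], "%Y-%m-%dT%H:%M:%SZ",
                                   tz = "UTC"),
                author_id = records$author_id[i],
                party = records$party[i],
                chamber = records$chamber[i],
                is_retweet = records$is_retweet[i],
                text = records$text[i])
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Tag records with lexicon flags
#'
#' Sets three independent logical columns: `is_vaccine` (matches the
#' vaccine term set and no exclusion term), `mentions_covid` and
#' `mentions_noncovid_disease`. A tweet may carry both disease flags.
#'
#' @param records tweet record data frame (tokens are computed from
#'   `text` if absent).
#' @param lexicon a [lexicon()] object.
#' @return the records with flag columns set.
#' @export
apply_flags <- function(records, lexicon) {
  stopifnot(inherits(lexicon, "lexicon"))
  if (is.null(records$tokens)) records$tokens <- normalize_list(records$text)
  mode <- lexicon$match_mode
  records$is_vaccine <- vapply(records$tokens, match_lexicon,
                               logical(1), terms = lexicon$vaccine_terms,
                               mode = mode)
  if (length(lexicon$exclusion_terms) > 0) {
    excl <- vapply(records$tokens, match_lexicon, logical(1),
                   terms = lexicon$exclusion_terms, mode = mode)
    records$is_vaccine <- records$is_vaccine & !excl
  }
  records$mentions_covid <- vapply(records$tokens, match_lexicon, logical(1),
                                   terms = lexicon$covid_terms,
                                   mode = "exact_word")
  records$mentions_noncovid_disease <-
    vapply(records$tokens, match_lexicon, logical(1),
           terms = lexicon$noncovid_disease_terms, mode = "exact_word")
  records
}

normalize_list <- function(text) {
  out <- normalize_text(text)
  if (!is.list(out)) out <- list(out)
  out
}

#' Keep records matching the vaccine lexicon
#'
#' @inheritParams apply_flags
#' @return the vaccine-related subset, flags set.
#' @export
filter_vaccine <- function(records, lexicon) {
  records <- apply_flags(records, lexicon)
  records[records$is_vaccine, , drop = FALSE]
}

#' Restrict records to a date window
#'
#' Both endpoints are inclusive; timestamps are compared as UTC
#' calendar dates, so a record anywhere on the end date is kept.
#'
#' @param records tweet record data frame.
#' @param start,end `Date`s or `"YYYY-MM-DD"` strings, `start <= end`.
#' @return the records inside the window.
#' @export
filter_window <- function(records, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("start date is after end date")
  d <- as.Date(format(records$timestamp, "%Y-%m-%d", tz = "UTC"))
  records[d >= start & d <= end, , drop = FALSE]
}
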