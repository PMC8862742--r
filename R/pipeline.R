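#' Configure an end-to-end analysis run
#'
#' Bundles and validates everything a full run needs: the corpus path,
#' the lexicon, the date window, LDA parameters, test levels and the
#' root seed. All randomness in a run flows from `seed`.
#'
#' @param corpus path to a JSONL or CSV tweet file.
#' @param out_dir output directory (created if absent).
#' @param lexicon a [lexicon()] object (default lexicon if omitted).
#' @param start,end inclusive date window.
#' @param k number of topics.
#' @param n_iter,burn_in Gibbs iterations and burn-in.
#' @param included_topics topic indices used for representation and
#'   polarization (default all).
#' @param alpha_terms,alpha_topics family-wise levels for the term and
#'   topic tests.
#' @param case_series optional path to a daily case-count CSV with
#'   columns `date` and `new_cases` (enables wave segmentation).
#' @param seed root seed.
#' @return a validated `"run_config"` list.
#' @export
run_config <- function(corpus, out_dir, lexicon = polarlex::lexicon(),
                       start = "2020-02-01", end = "2020-12-11",
                       k = 25, n_iter = 500, burn_in = floor(n_iter / 2),
                       included_topics = NULL,
                       alpha_terms = 0.001, alpha_topics = 0.001,
                       case_series = NULL, seed = 1L) {
  if (!file.exists(corpus)) stop("corpus file not found: ", corpus)
  if (!is.null(case_series) && !file.exists(case_series)) {
    stop("case series file not found: ", case_series)
  }
  stopifnot(inherits(lexicon, "lexicon"))
  structure(list(corpus = corpus, out_dir = out_dir, lexicon = lexicon,
                 start = as.Date(start), end = as.Date(end), k = k,
                 n_iter = n_iter, burn_in = burn_in,
                 included_topics = included_topics,
                 alpha_terms = alpha_terms, alpha_topics = alpha_topics,
                 case_series = case_series, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: lexicon filter (with date window) -> descriptive
#' party statistics -> differential term tests -> LDA topic model ->
#' topic representation, party comparisons and the monthly
#' polarization index; plus wave segmentation and per-wave term tests
#' when a case series is configured. Every artifact is written under
#' `out_dir` and listed (with md5 checksums and row counts) in
#' `manifest.json`, so a rerun with the same config reproduces
#' byte-identical numeric outputs.
#'
#' @param config a [run_config()].
#' @return list of in-memory stage results, invisibly; artifacts on
#'   disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- "filter"
  res <- tryCatch({
    records <- load_tweets(config$corpus)
    records <- filter_window(records, config$start, config$end)
    records <- filter_vaccine(records, config$lexicon)
    records$month <- month_of(records$timestamp)
    flat <- records[, setdiff(names(records), "tokens")]
    write.csv(flat, out("filtered.csv"), row.names = FALSE)

    stage <- "descriptive"
    desc <- descriptive_summary(records)
    write.csv(desc, out("descriptive.csv"), row.names = FALSE)

    stage <- "terms"
    terms_tab <- test_terms(build_term_table(records),
                            alpha = config$alpha_terms)
    write.csv(terms_tab, out("terms.csv"), row.names = FALSE)

    stage <- "topics"
    dtm <- build_dtm(records)
    fit <- fit_lda(dtm, config$k, n_iter = config$n_iter,
                   burn_in = config$burn_in, seed = config$seed)
    write.csv(data.frame(term = fit$vocabulary, t(fit$phi),
                         check.names = FALSE),
              out("phi.csv"), row.names = FALSE)
    write.csv(data.frame(id = rownames(fit$theta), fit$theta,
                         check.names = FALSE),
              out("theta.csv"), row.names = FALSE)
    coh <- coherence_score(fit, dtm)
    jsonlite::write_json(
      list(k = fit$k, alpha = fit$alpha, beta = fit$beta,
           n_iter = fit$n_iter, burn_in = fit$burn_in, seed = config$seed,
           coherence = coh,
           top_words = lapply(seq_len(fit$k), function(t) top_words(fit, t))),
      out("topics.json"), digits = NA, auto_unbox = TRUE)

    stage <- "metrics"
    kept <- records$id %in% fit$doc_ids
    mrec <- records[kept, , drop = FALSE]
    theta <- fit$theta[match(mrec$id, rownames(fit$theta)), , drop = FALSE]
    rep_tab <- topic_representation(theta, mrec,
                                    included_topics = config$included_topics)
    write.csv(rep_tab, out("representation.csv"), row.names = FALSE)
    cmp <- compare_party_topics(theta, mrec,
                                included_topics = config$included_topics,
                                alpha = config$alpha_topics)
    write.csv(cmp, out("topic_tests.csv"), row.names = FALSE)
    pol <- polarization_series(theta, mrec,
                               included_topics = config$included_topics)
    write.csv(pol, out("polarization.csv"), row.names = FALSE)

    waves <- NULL; wave_terms <- NULL
    if (!is.null(config$case_series)) {
      stage <- "waves"
      cs <- read.csv(config$case_series, stringsAsFactors = FALSE)
      cs$date <- as.Date(cs$date)
      waves <- segment_waves(cs)
      wave_terms <- per_wave_analysis(records, waves,
                                      alpha = config$alpha_terms)
      jsonlite::write_json(list(boundaries = waves$boundaries,
                                dates = format(waves$dates)),
                           out("waves.json"), auto_unbox = TRUE)
    }

    list(records = records, descriptive = desc, terms = terms_tab,
         dtm = dtm, model = fit, coherence = coh, representation = rep_tab,
         topic_tests = cmp, polarization = pol, waves = waves,
         wave_terms = wave_terms)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|report\\.md$", files)]
  manifest <- list(
    seed = config$seed, k = config$k, window = c(format(config$start),
                                                 format(config$end)),
    n_records = nrow(res$records),
    artifacts = data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(render_report(res), out("report.md"))
  invisible(res)
}

#' Render a human-readable run report
#'
#' Markdown summary with four sections: corpus description, partisan
#' terms (top 20 each way), per-topic representation with significance
#' marks, and the monthly polarization trend. Sections whose artifact
#' is missing are skipped with a notice.
#'
#' @param res result list from [run_pipeline()] (or a run directory
#'   path; only the in-memory form is rendered fully).
#' @return character vector of markdown lines.
#' @export
render_report <- function(res) {
  lines <- c("# Partisan discourse analysis report", "")
  if (!is.null(res$records)) {
    n <- nrow(res$records)
    lines <- c(lines, "## Corpus", "",
               sprintf("- %d vaccine-related tweets", n),
               sprintf("- Democrats: %.1f%% (n=%d)",
                       party_share(sum(res$records$party == "D"), n),
                       sum(res$records$party == "D")),
               sprintf("- Republicans: %.1f%% (n=%d)",
                       party_share(sum(res$records$party == "R"), n),
                       sum(res$records$party == "R")),
               sprintf("- Retweets: %.1f%% (n=%d)",
                       party_share(sum(res$records$is_retweet), n),
                       sum(res$records$is_retweet)), "")
  } else lines <- c(lines, "*(corpus summary unavailable)*", "")
  if (!is.null(res$terms)) {
    sig <- res$terms[res$terms$significant & !is.na(res$terms$direction), ]
    fmt <- function(df) if (nrow(df) == 0) "(none)" else
      paste(head(df$term[order(df$p)], 20), collapse = ", ")
    lines <- c(lines, "## Partisan terms", "",
               paste0("- Democratic-leaning: ",
                      fmt(sig[sig$direction == "D", ])),
               paste0("- Republican-leaning: ",
                      fmt(sig[sig$direction == "R", ])), "")
  } else lines <- c(lines, "*(term analysis unavailable)*", "")
  if (!is.null(res$topic_tests) && !is.null(res$model)) {
    lines <- c(lines, "## Topics", "",
               "| topic | top words | rep D | rep R | sig |",
               "|---|---|---|---|---|")
    for (i in seq_len(nrow(res$topic_tests))) {
      tt <- res$topic_tests[i, ]
      lines <- c(lines, sprintf(
        "| %d | %s | %.1f | %.1f | %s |", tt$topic,
        paste(top_words(res$model, tt$topic, 5), collapse = " "),
        tt$mean_D, tt$mean_R,
        if (isTRUE(tt$significant)) paste0("*", tt$direction) else ""))
    }
    lines <- c(lines, "")
  } else lines <- c(lines, "*(topic table unavailable)*", "")
  if (!is.null(res$polarization)) {
    lines <- c(lines, "## Polarization by month", "",
               "| month | polarization | n_D | n_R |", "|---|---|---|---|",
               sprintf("| %s | %.1f | %d | %d |", res$polarization$month,
                       res$polarization$value, res$polarization$n_D,
                       res$polarization$n_R), "")
  } else lines <- c(lines, "*(polarization series unavailable)*", "")
  if (!is.null(res$waves)) {
    lines <- c(lines, "## Pandemic waves", "",
               sprintf("- %d waves; boundaries: %s", res$waves$n_waves,
                       paste(format(res$waves$dates), collapse = ", ")), "")
  }
  lines
}
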