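#' Percentage share, rounded as printed
#'
#' `100 * subset / total`, rounded half-up to one decimal — the
#' convention used for printed corpus percentages.
#'
#' @param count_subset nonnegative count.
#' @param count_total positive count, at least `count_subset`.
#' @return percentage with one decimal.
#' @examples
#' party_share(8968, 14519)  # 61.8
#' @export
party_share <- function(count_subset, count_total) {
  if (any(count_total <= 0)) stop("total count must be positive")
  if (any(count_subset > count_total)) stop("subset exceeds total")
  round_half_up(100 * count_subset / count_total, 1)
}

#' Party-by-characteristic contingency table
#'
#' Builds the 2x2 table of party (D, R) against a logical tweet
#' characteristic. Independents and unknown-party records are excluded,
#' matching the two-party framing of the analysis.
#'
#' @param records tweet record data frame with flags set (see
#'   [apply_flags()]).
#' @param characteristic one of `"is_retweet"`, `"mentions_covid"`,
#'   `"mentions_noncovid_disease"`.
#' @return a 2x2 integer matrix, rows `D`/`R`, columns `yes`/`no`.
#' @export
crosstab <- function(records,
                     characteristic = c("is_retweet", "mentions_covid",
                                        "mentions_noncovid_disease")) {
  characteristic <- match.arg(characteristic)
  if (is.null(records[[characteristic]])) {
    stop("records lack the `", characteristic, "` column; run apply_flags()")
  }
  dr <- records[records$party %in% c("D", "R"), , drop = FALSE]
  if (!any(dr$party == "D") || !any(dr$party == "R")) {
    stop("both D and R records are required; one stratum is empty")
  }
  flag <- as.logical(dr[[characteristic]])
  tab <- matrix(c(sum(dr$party == "D" & flag), sum(dr$party == "D" & !flag),
                  sum(dr$party == "R" & flag), sum(dr$party == "R" & !flag)),
                nrow = 2, byrow = TRUE,
                dimnames = list(party = c("D", "R"),
                                setNames(list(c("yes", "no")), characteristic)[[1]]))
  colnames(tab) <- c("yes", "no")
  tab
}

#' Pearson chi-square test for a 2x2 table
#'
#' Chi-square test of independence without continuity correction
#' (df = 1); the p-value is the upper tail of the chi-square
#' distribution. A Yates-corrected variant is available via `correct`.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return list with `statistic`, `p`, `df`.
#' @export
chi2_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0)) stop("negative cell counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: test undefined")
  }
  res <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), p = unname(res$p.value),
       df = unname(res$parameter))
}

#' Descriptive party-by-characteristic summary
#'
#' For each tweet characteristic, reports the per-party percentage and
#' count, plus the chi-square statistic and p-value of the party
#' association.
#'
#' @param records tweet record data frame with flags set.
#' @param characteristics characteristics to summarize.
#' @return a `data.frame` with one row per characteristic:
#'   `characteristic`, `pct_D`, `n_D`, `pct_R`, `n_R`, `chi2`, `p`.
#' @export
descriptive_summary <- function(records,
                                characteristics = c("is_retweet",
                                                    "mentions_covid",
                                                    "mentions_noncovid_disease")) {
  rows <- lapply(characteristics, function(ch) {
    tab <- crosstab(records, ch)
    test <- chi2_2x2(tab)
    data.frame(characteristic = ch,
               pct_D = party_share(tab["D", "yes"], sum(tab["D", ])),
               n_D = tab["D", "yes"],
               pct_R = party_share(tab["R", "yes"], sum(tab["R", ])),
               n_R = tab["R", "yes"],
               chi2 = test$statistic, p = test$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
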