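#' Mean topic representation of a stratum
#'
#' Mean topic probability across the documents of one party-period
#' stratum, times 100. Output sums to 100 (within floating error)
#' because each `theta` row sums to 1.
#'
#' @param theta_rows matrix (or single row) of document-topic
#'   probabilities.
#' @return per-topic percentage vector.
#' @export
mean_topic_representation <- function(theta_rows) {
  if (is.null(dim(theta_rows))) theta_rows <- matrix(theta_rows, nrow = 1)
  if (nrow(theta_rows) == 0) stop("empty stratum")
  100 * colMeans(theta_rows)
}

#' Topic representation by party and period
#'
#' @param theta document-topic matrix aligned with `records` rows.
#' @param records tweet record data frame (needs `party`; `period`
#'   taken from `records$month` unless supplied).
#' @param period optional period label per record.
#' @param included_topics topic indices to report (default all).
#' @return long `data.frame`: `topic`, `party`, `period`, `value`, `n`.
#' @export
topic_representation <- function(theta, records, period = NULL,
                                 included_topics = NULL) {
  if (nrow(theta) != nrow(records)) stop("theta and records differ in rows")
  if (is.null(period)) {
    period <- if (!is.null(records$month)) records$month
              else month_of(records$timestamp)
  }
  if (is.null(included_topics)) included_topics <- seq_len(ncol(theta))
  out <- list()
  for (p in c("D", "R")) {
    for (m in unique(period)) {
      sel <- records$party == p & period == m
      if (!any(sel)) next
      rep <- mean_topic_representation(theta[sel, , drop = FALSE])
      out[[length(out) + 1]] <-
        data.frame(topic = included_topics, party = p, period = m,
                   value = rep[included_topics], n = sum(sel),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare per-topic representation between parties
#'
#' Default: for each topic, a two-sample Wilcoxon rank-sum test of
#' per-tweet topic probabilities, Democratic vs Republican, with
#' Bonferroni family equal to the number of included topics. A paired
#' Wilcoxon signed-rank variant over monthly (D, R) mean-representation
#' pairs is available via `method = "signedrank_monthly"` for analyses
#' that treat months as the pairing unit.
#'
#' @param theta document-topic matrix aligned with `records`.
#' @param records tweet record data frame.
#' @param included_topics topic indices to test (default all).
#' @param alpha family-wise level (default 0.001).
#' @param method `"ranksum"` (per-tweet, default) or
#'   `"signedrank_monthly"`.
#' @return `data.frame`: `topic`, `mean_D`, `mean_R`, `p`,
#'   `significant`, `direction`.
#' @export
compare_party_topics <- function(theta, records, included_topics = NULL,
                                 alpha = 0.001,
                                 method = c("ranksum", "signedrank_monthly")) {
  method <- match.arg(method)
  if (is.null(included_topics)) included_topics <- seq_len(ncol(theta))
  m <- length(included_topics)
  isD <- records$party == "D"; isR <- records$party == "R"
  month <- if (!is.null(records$month)) records$month
           else month_of(records$timestamp)
  rows <- lapply(included_topics, function(t) {
    xD <- theta[isD, t]; xR <- theta[isR, t]
    if (method == "ranksum") {
      if (length(xD) < 2 || length(xR) < 2) {
        warning("topic ", t, " skipped: fewer than 2 observations in a party")
        return(NULL)
      }
      identical_sets <- length(xD) == length(xR) &&
        isTRUE(all.equal(sort(xD), sort(xR)))
      p <- if (identical_sets) 1
           else suppressWarnings(
             wilcox.test(xD, xR, exact = (length(xD) < 50 &&
                                          length(xR) < 50))$p.value)
    } else {
      mo <- sort(unique(month[isD | isR]))
      pairs <- vapply(mo, function(mm) {
        c(D = if (any(isD & month == mm)) mean(theta[isD & month == mm, t])
              else NA_real_,
          R = if (any(isR & month == mm)) mean(theta[isR & month == mm, t])
              else NA_real_)
      }, numeric(2))
      ok <- !is.na(pairs["D", ]) & !is.na(pairs["R", ])
      if (sum(ok) < 2) {
        warning("topic ", t, " skipped: fewer than 2 complete monthly pairs")
        return(NULL)
      }
      d <- pairs["D", ok] - pairs["R", ok]
      p <- if (all(d == 0)) 1
           else wilcox.test(pairs["D", ok], pairs["R", ok],
                            paired = TRUE, exact = FALSE)$p.value
    }
    mD <- mean(xD); mR <- mean(xR)
    data.frame(topic = t, mean_D = 100 * mD, mean_R = 100 * mR, p = p,
               significant = p < alpha / m,
               direction = if (mD > mR) "D" else if (mR > mD) "R" else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}

#' Monthly polarization index
#'
#' For each month with tweets from both parties, the sum over included
#' topics of the absolute difference between Democratic and Republican
#' mean topic representation. Because each party's representation sums
#' to 100 (over all topics), the index ranges 0-200: 0 when the
#' parties' topic use is identical, 200 when completely disjoint.
#' Months missing either party yield `NA` — never a silent zero — with
#' coverage counts reported.
#'
#' @param theta document-topic matrix aligned with `records`.
#' @param records tweet record data frame.
#' @param months ordered month labels (default: observed months).
#' @param included_topics topic indices (default all fitted topics).
#' @return an object of class `"polarization_series"`: `data.frame`
#'   with `month`, `value`, `n_D`, `n_R`.
#' @export
polarization_series <- function(theta, records, months = NULL,
                                included_topics = NULL) {
  month <- if (!is.null(records$month)) records$month
           else month_of(records$timestamp)
  if (is.null(months)) months <- sort(unique(month))
  if (is.null(included_topics)) included_topics <- seq_len(ncol(theta))
  rows <- lapply(months, function(m) {
    selD <- records$party == "D" & month == m
    selR <- records$party == "R" & month == m
    nD <- sum(selD); nR <- sum(selR)
    if (nD == 0 || nR == 0) {
      message("month ", m, ": missing ", if (nD == 0) "D" else "R",
              " tweets; polarization is NA")
      return(data.frame(month = m, value = NA_real_, n_D = nD, n_R = nR,
                        stringsAsFactors = FALSE))
    }
    repD <- mean_topic_representation(theta[selD, , drop = FALSE])
    repR <- mean_topic_representation(theta[selR, , drop = FALSE])
    data.frame(month = m,
               value = sum(abs(repD[included_topics] - repR[included_topics])),
               n_D = nD, n_R = nR, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$month), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("polarization_series", "data.frame")
  out
}

#' @export
plot.polarization_series <- function(x, ...) {
  idx <- seq_len(nrow(x))
  plot.default(idx, x$value, type = "b", xaxt = "n",
               xlab = "month", ylab = "polarization (sum |D - R|, 0-200)", ...)
  axis(1, at = idx, labels = x$month, las = 2, cex.axis = 0.8)
  invisible(x)
}

#' Summarize the direction of a polarization trend
#'
#' Reports month-over-month first differences, their sign pattern, and
#' the longest monotone run — used to compare an estimated trend
#' against a planted one.
#'
#' @param series a `"polarization_series"` (or data frame with `month`
#'   and `value`).
#' @return list with `deltas`, `signs` (+1/-1/0 per step, `NA` over
#'   missing months), `longest_increasing`, `longest_decreasing`.
#' @export
polarization_trend_check <- function(series) {
  v <- series$value
  if (sum(!is.na(v)) < 3) stop("need at least 3 non-missing points")
  d <- diff(v)
  s <- sign(d)
  longest_run <- function(target) {
    best <- run <- 0
    for (x in s) {
      if (!is.na(x) && x == target) { run <- run + 1; best <- max(best, run) }
      else run <- 0
    }
    best + 1   # runs measured in points, not steps
  }
  list(deltas = setNames(d, series$month[-1]),
       signs = setNames(s, series$month[-1]),
       longest_increasing = longest_run(1),
       longest_decreasing = longest_run(-1))
}
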