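#' Generate a synthetic daily case-count series with planted nadirs
#'
#' Builds a nonnegative integer daily series of epidemic waves
#' (raised-cosine peaks separated by the planted troughs) whose 7-day
#' trailing moving average has strict local minima exactly at the
#' trough days when `noise_sd = 0`. Two design choices make that
#' exact: the raw series leads the trough positions by 3 days, so the
#' trailing 7-day window is centered on the trough, and each segment's
#' peak amplitude is scaled with the squared segment length so the
#' curvature at every trough is identical on both sides — the smoothed
#' minimum then cannot drift toward the shallower neighbor.
#'
#' @param n_days length of the series.
#' @param trough_days 1-based day indices of planted wave boundaries;
#'   strictly increasing, at least 7 days from either end and at least
#'   14 days apart (epidemic waves span weeks).
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   raw counts (0 for an exact series).
#' @param seed integer seed (only noise is random).
#' @param base case level at the troughs.
#' @param curvature second difference of the planted curve at each
#'   trough (cases per day^2); larger values give sharper nadirs.
#' @return a `data.frame` with `day` (1-based index), `date` (starting
#'   2020-02-01) and `new_cases`.
#' @export
generate_case_series <- function(n_days, trough_days = integer(),
                                 noise_sd = 0, seed = 1L,
                                 base = 200, curvature = 10) {
  if (n_days < 8) stop("n_days must be at least 8")
  trough_days <- as.integer(trough_days)
  if (any(trough_days < 1 | trough_days > n_days)) {
    stop("trough index outside the series")
  }
  if (is.unsorted(trough_days, strictly = TRUE)) {
    stop("trough days must be strictly increasing")
  }
  if (any(trough_days < 8 | trough_days > n_days - 7)) {
    stop("troughs must be at least 7 days from the series boundaries")
  }
  if (length(trough_days) > 1 && any(diff(trough_days) < 14)) {
    stop("troughs must be at least 14 days apart")
  }
  # Planted curve c(d) on days 1..(n_days + 3); x_t samples c(t + 3) so
  # the trailing 7-day window at t covers c(t - 3)..c(t + 3), centered.
  bounds <- c(1L, trough_days, n_days + 3L)
  cdays <- seq_len(n_days + 3L)
  curve <- numeric(n_days + 3L)
  for (s in seq_len(length(bounds) - 1L)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    len <- max(1L, b - a)
    amp <- curvature * len^2 / pi^2   # equal curvature at both ends
    u <- (a:b - a) / len
    curve[a:b] <- base + amp * (1 - cos(2 * pi * u)) / 2
  }
  set.seed(seed)
  x <- round(curve[cdays > 3L])
  if (noise_sd > 0) x <- x + round(rnorm(n_days, 0, noise_sd))
  x <- pmax(0, round(x))
  data.frame(day = seq_len(n_days),
             date = as.Date("2020-02-01") + seq_len(n_days) - 1L,
             new_cases = as.integer(x))
}

#' Trailing moving average
#'
#' @param x numeric vector.
#' @param window window length; positions before the window fills are `NA`.
#' @return numeric vector of the same length.
#' @export
moving_average <- function(x, window = 7) {
  if (window < 1) stop("window must be at least 1")
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))
}

#' Segment an epidemic case series into waves
#'
#' Computes the trailing `window`-day moving average of daily new
#' cases and places wave boundaries at its interior nadirs (strict
#' local minima; on plateaus the first day is taken). When more nadirs
#' exist than needed, the `n_waves - 1` deepest are kept. A series
#' with no interior nadir yields a single wave with a warning.
#'
#' @param case_series data frame with `new_cases` and either `day` or
#'   `date`.
#' @param window moving-average window (days), default 7.
#' @param n_waves number of waves requested, default 3.
#' @return an object of class `"wave_boundaries"`: a list with
#'   `boundaries` (day indices), `dates` (if dates supplied),
#'   `n_waves`, and the smoothed series.
#' @export
segment_waves <- function(case_series, window = 7, n_waves = 3) {
  x <- case_series$new_cases
  if (length(x) < window) stop("series shorter than the smoothing window")
  ma <- moving_average(x, window)
  valid <- which(!is.na(ma))
  nadirs <- local_minima(ma, valid)
  if (length(nadirs) == 0) {
    warning("no interior nadir in the smoothed series; returning one wave")
    chosen <- integer()
  } else {
    depth_order <- order(ma[nadirs], nadirs)   # deepest first, earliest ties
    chosen <- sort(nadirs[head(depth_order, n_waves - 1L)])
  }
  structure(list(boundaries = chosen,
                 dates = if (!is.null(case_series$date))
                   case_series$date[chosen] else NULL,
                 n_waves = length(chosen) + 1L,
                 smoothed = ma),
            class = "wave_boundaries")
}

# Interior strict local minima of a series (first index of any plateau),
# searched over `valid` (non-NA) positions only.
local_minima <- function(ma, valid) {
  lo <- valid[1]; hi <- valid[length(valid)]
  out <- integer()
  i <- lo + 1L
  while (i < hi) {
    if (ma[i] < ma[i - 1L]) {
      j <- i
      while (j < hi && ma[j + 1L] == ma[j]) j <- j + 1L
      if (j < hi && ma[j + 1L] > ma[j]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' @export
print.wave_boundaries <- function(x, ...) {
  cat("Wave segmentation:", x$n_waves, "wave(s)\n")
  if (length(x$boundaries) > 0) {
    cat("  boundaries at day(s):", paste(x$boundaries, collapse = ", "), "\n")
    if (!is.null(x$dates))
      cat("  dates:", paste(format(x$dates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign records to waves by date
#'
#' @param records tweet record data frame.
#' @param waves a `"wave_boundaries"` object with `dates`, or a vector
#'   of boundary `Date`s.
#' @return integer wave index per record (1-based).
#' @export
assign_waves <- function(records, waves) {
  dates <- if (inherits(waves, "wave_boundaries")) waves$dates else as.Date(waves)
  if (is.null(dates)) stop("wave boundaries carry no dates")
  d <- as.Date(format(records$timestamp, "%Y-%m-%d", tz = "UTC"))
  findInterval(as.numeric(d), as.numeric(dates)) + 1L
}
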