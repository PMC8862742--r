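#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the
#' convention used for printed percentages in most applied reports
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Sample from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha concentration vector (length K, all positive).
#' @return an `n` x `K` matrix whose rows sum to 1.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  # Guard against all-zero rows when every alpha is tiny
  zero <- rowSums(g) == 0
  if (any(zero)) {
    idx <- sample.int(k, sum(zero), replace = TRUE)
    g[cbind(which(zero), idx)] <- 1
  }
  g / rowSums(g)
}

#' Cosine similarity between two vectors
#' @keywords internal
cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

#' Match estimated topics to reference topics
#'
#' Finds the one-to-one assignment of estimated topics to reference
#' topics that maximizes the mean cosine similarity between matched
#' topic-word vectors. For K <= 8 the optimum is found by exhaustive
#' permutation search; for larger K a greedy best-pair heuristic is
#' used (adequate when topics are well separated).
#'
#' Columns are aligned by term name when both matrices have column
#' names; terms present in only one matrix contribute zero mass on the
#' other side.
#'
#' @param phi_est estimated K x V topic-word matrix (rows sum to 1).
#' @param phi_ref reference K x V' topic-word matrix.
#' @return list with `assignment` (for each estimated topic, the index
#'   of its matched reference topic), `cosines` (per matched pair) and
#'   `mean_cosine`.
#' @export
match_topics <- function(phi_est, phi_ref) {
  if (nrow(phi_est) != nrow(phi_ref)) {
    stop("phi_est and phi_ref must have the same number of topics")
  }
  k <- nrow(phi_est)
  if (!is.null(colnames(phi_est)) && !is.null(colnames(phi_ref))) {
    vocab <- union(colnames(phi_est), colnames(phi_ref))
    a <- matrix(0, k, length(vocab), dimnames = list(NULL, vocab))
    b <- a
    a[, colnames(phi_est)] <- phi_est
    b[, colnames(phi_ref)] <- phi_ref
    phi_est <- a; phi_ref <- b
  } else if (ncol(phi_est) != ncol(phi_ref)) {
    stop("topic-word matrices must share a vocabulary (set column names)")
  }
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) sim[i, j] <- cosine_sim(phi_est[i, ], phi_ref[j, ])
  }
  if (k <= 8) {
    perms <- permutations_of(k)
    best <- NULL; best_val <- -Inf
    for (p in perms) {
      v <- sum(sim[cbind(seq_len(k), p)])
      if (v > best_val) { best_val <- v; best <- p }
    }
    assignment <- best
  } else {
    assignment <- integer(k)
    s <- sim
    for (step in seq_len(k)) {
      ij <- arrayInd(which.max(s), dim(s))
      assignment[ij[1]] <- ij[2]
      s[ij[1], ] <- -Inf
      s[, ij[2]] <- -Inf
    }
  }
  cosines <- sim[cbind(seq_len(k), assignment)]
  list(assignment = assignment, cosines = cosines,
       mean_cosine = mean(cosines))
}

# All permutations of 1..n as a list of integer vectors
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[idx]] <- append(p, n, after = pos - 1L)
      idx <- idx + 1L
    }
  }
  out
}

# Sequence of "YYYY-MM" month labels, inclusive
#' Calendar month sequence
#'
#' @param from,to month labels in `"YYYY-MM"` form.
#' @return character vector of consecutive month labels.
#' @export
month_seq <- function(from = "2020-02", to = "2020-12") {
  f <- as.Date(paste0(from, "-01")); t <- as.Date(paste0(to, "-01"))
  if (f > t) stop("`from` is after `to`")
  format(seq(f, t, by = "month"), "%Y-%m")
}

# Month label of a timestamp vector (UTC)
month_of <- function(timestamp) format(timestamp, "%Y-%m", tz = "UTC")
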