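# Rank statistics with exact small-sample null distributions.
#
# The headline comparisons are all rank-based (paired Wilcoxon signed-rank,
# Mann-Whitney U, Spearman correlation).  Ties get mid-ranks throughout.
# For small samples the null distribution is enumerated exactly -- over
# sign flips, group labelings or permutations respectively -- which stays
# correct under ties, where the classical tables (and the approximations
# stats::wilcox.test falls back to) do not apply.  Two-sided p-values are
# 2 * min(lower tail, upper tail), capped at 1.

two_sided <- function(p_lo, p_hi) min(1, 2 * min(p_lo, p_hi))

#' Paired Wilcoxon signed-rank test
#'
#' Tests for a location shift between paired observations.  Zero
#' differences are dropped before ranking; absolute differences get
#' mid-ranks; the statistic is the sum W of ranks of positive
#' differences.  For `n <= exact_limit` non-zero pairs the null is
#' enumerated exactly over all 2^n sign assignments (via the subset-sum
#' generating function over the doubled mid-ranks, so ties are handled
#' exactly); otherwise a normal approximation with tie correction and a
#' 0.5 continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_limit Use exact enumeration when the number of non-zero
#'   differences is at most this (default 25).
#' @return List with `statistic` (W), `n` (non-zero pairs), `p_value`
#'   (two-sided) and `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, n = 0L, p_value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # counts over 2W (integer because mid-ranks are multiples of 1/2)
    r2 <- as.integer(round(2 * r))
    counts <- c(1, numeric(sum(r2)))
    for (ri in r2)
      counts <- counts + c(numeric(ri), counts[seq_len(length(counts) - ri)])
    w2 <- as.integer(round(2 * W))
    total <- 2^n
    p_lo <- sum(counts[seq_len(w2 + 1L)]) / total
    p_hi <- sum(counts[(w2 + 1L):length(counts)]) / total
    list(statistic = W, n = n, p_value = two_sided(p_lo, p_hi),
         method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = W, n = n, p_value = max(p, .Machine$double.xmin),
         method = "normal")
  }
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Compares two independent samples by ranks (mid-ranks for ties).  The
#' statistic is `U = W_x - n1(n1+1)/2`, with `W_x` the rank sum of `x` in
#' the pooled ranking.  When both group sizes are at most `exact_limit`
#' the null is enumerated exactly over all `choose(n1+n2, n1)` group
#' labelings of the observed pooled ranks (exact under ties); otherwise a
#' normal approximation with tie correction is used.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param exact_limit Enumerate exactly when `max(n1, n2)` is at most
#'   this (default 10).
#' @return List with `statistic` (U for `x`), `n1`, `n2`, `p_value`
#'   (two-sided) and `method`.
#' @examples
#' mann_whitney_u(c(3, 4), c(1, 2))
#' @export
mann_whitney_u <- function(x, y, exact_limit = 10) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(c(x, y))
  Wx <- sum(r[seq_len(n1)])
  U <- Wx - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_limit) {
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    eps <- 1e-9
    p_lo <- mean(sums <= Wx + eps)
    p_hi <- mean(sums >= Wx - eps)
    list(statistic = U, n1 = n1, n2 = n2,
         p_value = two_sided(p_lo, p_hi), method = "exact")
  } else {
    N <- n1 + n2
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = U, n1 = n1, n2 = n2,
         p_value = max(p, .Machine$double.xmin), method = "normal")
  }
}

# all permutations of 1..n as an integer matrix (n! rows); n <= 10
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    shifted <- sub
    shifted[sub >= k] <- shifted[sub >= k] + 1L
    out[rows, -1L] <- shifted
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks.  For
#' `n <= exact_limit` the two-sided p-value is `P(|rho_perm| >= |rho|)`
#' over all `n!` permutations of one variable (exact under ties);
#' otherwise it uses the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @param exact_limit Enumerate all permutations when `n` is at most this
#'   (default 10; 10! = 3.6M permutations is the practical ceiling).
#' @return List with `rho`, `n`, `p_value` and `method`.
#' @export
spearman_rho_test <- function(x, y, exact_limit = 10) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant ranks; Spearman correlation undefined", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (n <= exact_limit) {
    perms <- all_permutations(n)
    # rho is affine in the rank cross-sum (the rank sds are fixed under
    # permutation, ties included), so compare cross-sums; the null mean
    # of the cross-sum is the symmetry center
    s_obs <- sum(rx * ry)
    s_perm <- as.vector(matrix(rx[perms], nrow = nrow(perms)) %*% ry)
    m <- mean(s_perm)
    p <- mean(abs(s_perm - m) >= abs(s_obs - m) - 1e-9)
    list(rho = rho, n = n, p_value = p, method = "exact")
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    list(rho = rho, n = n, p_value = max(p, .Machine$double.xmin),
         method = "t-approximation")
  }
}
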