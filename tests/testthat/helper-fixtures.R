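# Shared fixtures and independent brute-force oracles.

toy_sheet <- function(n_ko = 1, n_ctrl = 1) {
  data.frame(
    sample_id = c(sprintf("ko_%d", seq_len(n_ko)),
                  sprintf("ctrl_%d", seq_len(n_ctrl))),
    condition = rep(c("knockout", "control"), c(n_ko, n_ctrl)),
    replicate = c(seq_len(n_ko), seq_len(n_ctrl)),
    stringsAsFactors = FALSE)
}

toy_matrix <- function(values, n_genes, n_ko = 1, n_ctrl = 1,
                       gene_ids = sprintf("g%d", seq_len(n_genes))) {
  sheet <- toy_sheet(n_ko, n_ctrl)
  m <- matrix(values, nrow = n_genes,
              dimnames = list(gene_ids, sheet$sample_id))
  expression_matrix(m, sheet)
}

# --- rank-test oracles (enumeration routes independent of the package) ---

# signed-rank: enumerate every sign assignment explicitly
oracle_signed_rank_p <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  eps <- 1e-9
  min(1, 2 * min(mean(W_all <= W_obs + eps), mean(W_all >= W_obs - eps)))
}

# Mann-Whitney: U from pairwise comparisons (not rank sums), permutation
# null over group labelings of the pooled values
oracle_u_stat <- function(x, y)
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

oracle_mann_whitney_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  combos <- utils::combn(length(pool), n1)
  U_obs <- oracle_u_stat(x, y)
  U_all <- apply(combos, 2L, function(idx)
    oracle_u_stat(pool[idx], pool[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(U_all <= U_obs + eps), mean(U_all >= U_obs - eps)))
}

# mid-ranks and Spearman rho from first principles
oracle_midranks <- function(v)
  vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, 0)

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# lexicographic next-permutation enumeration (independent of the
# package's recursive generator)
oracle_permutations <- function(n) {
  p <- seq_len(n)
  out <- list(p)
  repeat {
    i <- n - 1L
    while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (p[j] <= p[i]) j <- j - 1L
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1L):n] <- rev(p[(i + 1L):n])
    out[[length(out) + 1L]] <- p
  }
  do.call(rbind, out)
}

oracle_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 8)
  rho_obs <- abs(oracle_spearman_rho(x, y))
  perms <- oracle_permutations(n)
  rho_all <- apply(perms, 1L, function(idx)
    abs(oracle_spearman_rho(x[idx], y)))
  mean(rho_all >= rho_obs - 1e-9)
}

# --- Ward oracle: merge costs recomputed from scratch via the ESS
# (centroid) identity instead of the Lance-Williams recursion ---

oracle_ward_merges <- function(d) {
  D2 <- unclass(d)^2
  n <- nrow(D2)
  members <- as.list(seq_len(n))
  code <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  pair_value <- function(A, B) {
    nA <- length(A); nB <- length(B)
    centroid2 <- sum(D2[A, B]) / (nA * nB) -
      sum(D2[A, A]) / (2 * nA^2) - sum(D2[B, B]) / (2 * nB^2)
    2 * (nA * nB / (nA + nB)) * centroid2   # Lance-Williams Ward value
  }
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_v <- Inf
    for (a in seq_along(members)[-length(members)])
      for (b in (a + 1L):length(members)) {
        v <- pair_value(members[[a]], members[[b]])
        if (v < best_v - 1e-12) { best_v <- v; best <- c(a, b) }
      }
    merge[step, ] <- sort(c(code[best[1]], code[best[2]]))
    height[step] <- sqrt(best_v)
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
    code[best[1]] <- step
    code <- code[-best[2]]
  }
  list(merge = merge, height = height)
}

# hypergeometric upper tail by direct pmf summation
oracle_hyper_tail <- function(k, K, N, n)
  sum(stats::dhyper(k:min(K, n), K, N - K, n))

# tail probabilities P(X >= k) for k = 1..min(K, n)
oracle_hyper_tail_vec <- function(N, K, n)
  vapply(seq_len(min(K, n)), oracle_hyper_tail, 0, K = K, N = N, n = n)
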