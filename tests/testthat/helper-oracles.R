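# Independent brute-force / closed-form oracles used across the suite.
# Each is deliberately written from the definition, not from the package's
# implementation path.

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# C(m+n, m) rank assignments (untied inputs only).
oracle_wilcoxon_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  stopifnot(!anyDuplicated(c(x, y)))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  all_w <- apply(utils::combn(m + n, m), 2,
                 function(idx) sum(idx) - m * (m + 1) / 2)
  lower <- mean(all_w <= w_obs)
  upper <- mean(all_w >= w_obs)
  min(1, 2 * min(lower, upper))
}

# Normal approximation with continuity correction and tie correction,
# from the z-statistic formula.
oracle_wilcoxon_normal <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- m * n / 12 *
    ((m + n + 1) - sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
  z <- w - m * n / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
}

# Benjamini-Hochberg by direct application of the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hypergeometric upper tail by exhaustive enumeration of all n-subsets of
# a background of N genes with K marked.
oracle_hyper_enum <- function(k, K, n, N) {
  marked <- seq_len(K)
  subsets <- utils::combn(N, n)
  overlaps <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(overlaps >= k)
}

# Enrichment score by an explicit position-by-position running-sum walk.
# Same signed-extremum tie rule as the implementation (ties to positive).
oracle_enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  L <- nrow(ranked)
  hit <- ranked$gene %in% gene_set
  w <- abs(ranked$score)^weight_exponent
  W <- sum(w[hit])
  inc <- if (W > 0) ifelse(hit, w / W, 0) else ifelse(hit, 1 / sum(hit), 0)
  dec <- ifelse(hit, 0, 1 / (L - sum(hit)))
  dev <- cumsum(inc - dec)
  hi <- max(dev, 0); lo <- min(dev, 0)
  if (hi >= -lo) hi else lo
}

# Welch t-test p-value from the closed-form statistic and
# Welch-Satterthwaite degrees of freedom.
oracle_welch_p <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}
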