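# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Two-sided Fisher exact p by hypergeometric enumeration: sum the point
# probabilities of all tables with the same margins that are no more likely
# than the observed one (with the conventional 1e-7 relative tolerance on the
# tie comparison).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + c        # selected
  n_col <- b + d    # unselected
  K <- a + b        # in-set
  lo <- max(0, K - n_col)
  hi <- min(K, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n_col, K)
  p_obs <- stats::dhyper(a, m, n_col, K)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact binomial p by full enumeration (point-probability method).
oracle_binom_two_sided <- function(k, n, p0 = 0.5) {
  probs <- stats::dbinom(0:n, n, p0)
  p_obs <- stats::dbinom(k, n, p0)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up by the hand rule: q_i = min over j with p_(j) >= p_(i) of
# p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Weighted KS running-sum ES, written independently (loop form).
oracle_gsea_es <- function(scores_sorted, hit_idx, weight = 1) {
  N <- length(scores_sorted)
  K <- length(hit_idx)
  w <- abs(scores_sorted[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, K)
  run <- 0
  best <- 0
  wsum <- sum(w)
  for (i in seq_len(N)) {
    if (i %in% hit_idx) run <- run + w[match(i, hit_idx)] / wsum
    else run <- run - 1 / (N - K)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Tiny instrument-set factory for MR tests.
toy_instruments <- function(bx, by, sy, rho = NULL) {
  k <- length(bx)
  ld <- if (is.null(rho)) diag(k) else { m <- matrix(rho, k, k); diag(m) <- 1; m }
  instrument_set(paste0("v", seq_len(k)), bx, rep(0.01, k), by, sy, ld)
}
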