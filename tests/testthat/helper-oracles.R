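# Independent oracles used across the suite.

# Exact Dirichlet-multinomial probability of one count vector by exhaustive
# enumeration of Polya-urn draw sequences: every ordering of the multiset is
# walked, multiplying the urn probabilities (a_c + drawn_c) / (A + t - 1).
urn_probability <- function(counts, alpha) {
  total <- sum(alpha)
  recurse <- function(remaining, drawn, t) {
    if (all(remaining == 0)) {
      return(1)
    }
    p <- 0
    for (c in which(remaining > 0)) {
      step <- (alpha[c] + drawn[c]) / (total + t - 1)
      remaining[c] <- remaining[c] - 1
      drawn[c] <- drawn[c] + 1
      p <- p + step * recurse(remaining, drawn, t + 1)
      remaining[c] <- remaining[c] + 1
      drawn[c] <- drawn[c] - 1
    }
    p
  }
  recurse(counts, rep(0, length(counts)), 1)
}

# Brute-force Benjamini-Hochberg step-up from its definition.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (k in seq_len(m)) {
    q_sorted[k] <- min(1, min(m * p[ord][k:m] / (k:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Small helper: beta-binomial pmf by direct (non-log) beta-function ratio,
# usable as an oracle at small N.
bb_pmf_direct <- function(x, n, a, b) {
  choose(n, x) * beta(x + a, n - x + b) / beta(a, b)
}
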