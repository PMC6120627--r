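# Independent oracles used across test files. These deliberately avoid the
# code paths they check: table probabilities come from binomial-coefficient
# ratios, not dhyper; run-count moments from brute-force enumeration.

# Two-sided Fisher p for a 2x2 table by exhaustive enumeration over the
# hypergeometric support, with probabilities from lchoose().
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  x <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  probs <- exp(logp)
  p_obs <- probs[x == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact mean and variance of the run count for n1+n2 <= ~14 labels by
# enumerating every arrangement.
runs_enum_moments <- function(n1, n2) {
  n <- n1 + n2
  combos <- utils::combn(n, n1)
  runs <- apply(combos, 2, function(ix) {
    x <- rep(0L, n); x[ix] <- 1L
    1L + sum(x[-1] != x[-n])
  })
  list(mean = mean(runs), var = stats::var(runs) * (length(runs) - 1) / length(runs))
}

options(hexmeth.verbose = FALSE)
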