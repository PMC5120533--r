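# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's dhyper/dbinom code paths: pmfs are
# built from choose() arithmetic and summed by full enumeration.

oracle_binom_p <- function(k, n, p0 = 0.5) {
  i <- 0:n
  pmf <- choose(n, i) * p0^i * (1 - p0)^(n - i)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  pmf <- choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)])
}

# BH step-up by direct application of the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  q
}
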