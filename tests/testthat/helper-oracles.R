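# Independent arithmetic oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Upper-tail hypergeometric by direct combinatorial sums (no log space).
brute_hyper_upper <- function(k, s, M, N) {
  i <- k:min(s, M)
  if (k > min(s, M)) return(0)
  sum(choose(M, i) * choose(N - M, s - i)) / choose(N, s)
}

# Pooled-variance two-sample two-tailed t-test by hand.
pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tt), na + nb - 2)
}

# BH step-up by its definition: sort, q_(i) = min_{j>=i} p_(j) m / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, ps[i] * m / i)
    q[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# A tiny hand-rolled nanopolish-polya style table writer.
write_fake_polya <- function(lines, path) {
  writeLines(lines, path)
  path
}
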