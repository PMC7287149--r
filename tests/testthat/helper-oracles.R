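# Independent statistical oracles, deliberately naive.

# binomial upper/lower tail by direct probability summation
binom_tail_oracle <- function(K, M, omega, alternative) {
  pk <- vapply(0:M, function(k)
    choose(M, k) * omega^k * (1 - omega)^(M - k), numeric(1))
  if (alternative == "greater") sum(pk[(K + 1):(M + 1)]) else sum(pk[1:(K + 1)])
}

# two-sided Fisher p by full hypergeometric enumeration: sum the
# probabilities of all tables (fixed margins) no more probable than the
# observed one (with the conventional 1e-7 relative slack on "no more
# probable")
fisher_oracle <- function(k1, k2, M) {
  total <- k1 + k2
  lo <- max(0, total - M); hi <- min(total, M)
  prob <- function(a) choose(M, a) * choose(M, total - a) /
    choose(2 * M, total)
  pa <- vapply(lo:hi, prob, numeric(1))
  sum(pa[pa <= prob(k1) * (1 + 1e-7)])
}
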