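# rank-formula reference implementations, written independently of the
# package internals, for oracle comparisons
bf_kruskal <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / as.vector(table(groups))) - 3 * (N + 1)
  tie <- table(values)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

bf_dunn_z <- function(values, groups, i, j) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  tie <- table(values)
  s2 <- N * (N + 1) / 12 - sum(tie^3 - tie) / (12 * (N - 1))
  Rbar <- tapply(r, groups, mean)
  nj <- as.vector(table(groups))
  (Rbar[i] - Rbar[j]) / sqrt(s2 * (1 / nj[i] + 1 / nj[j]))
}

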