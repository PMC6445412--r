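# Independent brute-force oracles, kept deliberately naive: direct
# transcriptions of the defining formulas, sharing no code with the package.

# Kruskal-Wallis H with tie correction, from first principles.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  num <- 0
  for (i in seq_along(groups)) {
    ri <- r[idx == i]
    num <- num + length(ri) * (mean(ri) - (N + 1) / 2)^2
  }
  h <- 12 / (N * (N + 1)) * num
  tie <- 0
  for (t in table(x)) tie <- tie + t^3 - t
  h / (1 - tie / (N^3 - N))
}

# Mann-Whitney U for the first sample, by pairwise comparison counting.
oracle_mwu_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bi in b) {
    if (ai > bi) u <- u + 1 else if (ai == bi) u <- u + 0.5
  }
  u
}

# Exact two-sided MWU p-value by full enumeration of group labelings.
oracle_mwu_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- oracle_mwu_u(a, b)
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(ix) {
    oracle_mwu_u(pooled[ix], pooled[-ix])
  })
  centre <- na * length(b) / 2
  mean(abs(us - centre) >= abs(obs - centre) - 1e-12)
}

# Literal step-up definition of Benjamini-Hochberg.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) {
    if (p[o[i]] <= i / m * q) k <- i
  }
  reject <- rep(FALSE, m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  list(reject = reject, critical_p = if (k > 0) k / m * q else 0)
}

# Literal step-down definition of Holm on a vector of raw p-values.
oracle_holm_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  reject <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (p[o[i]] <= alpha / (m - i + 1)) reject[o[i]] <- TRUE else break
  }
  reject
}
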