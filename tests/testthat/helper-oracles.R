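# Independent brute-force oracles. These deliberately re-derive each
# statistic with plain scalar loops, separate from the package's vectorised
# code paths.

# Weir & Cockerham (1984) two-population FST, ratio of sums over sites.
# geno_obj / geno_ref: samples x sites matrices coded 0/1/2/NA.
oracle_wc_fst <- function(geno_obj, geno_ref) {
  num <- 0; den <- 0
  r <- 2
  for (j in seq_len(ncol(geno_obj))) {
    pops <- list(geno_obj[, j], geno_ref[, j])
    n <- numeric(2); p <- numeric(2); h <- numeric(2)
    for (i in 1:2) {
      g <- pops[[i]][!is.na(pops[[i]])]
      n[i] <- length(g)
      if (n[i] == 0) next
      p[i] <- sum(g) / (2 * n[i])
      h[i] <- sum(g == 1) / n[i]
    }
    if (any(n == 0)) next
    nbar <- mean(n)
    if (nbar <= 1) next
    pbar <- sum(n * p) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NaN else num / den
}

# Nucleotide diversity as the mean pairwise allele difference per site,
# divided by the window span.
oracle_pi <- function(geno, span) {
  total <- 0
  for (j in seq_len(ncol(geno))) {
    g <- geno[, j][!is.na(geno[, j])]
    alleles <- integer()
    for (x in g) alleles <- c(alleles, c(x >= 1, x >= 2))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0; pairs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      diffs <- diffs + (alleles[a] != alleles[b])
      pairs <- pairs + 1
    }
    total <- total + diffs / pairs
  }
  total / span
}

# Exact hypergeometric upper tail P[X >= k] by direct combinatorial sum.
oracle_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  tot <- 0
  for (i in k:min(K, n)) {
    tot <- tot + exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n))
  }
  tot
}

# Random small genotype fixture: two pops x n_samp x n_site with missingness.
random_two_pop <- function(n_site = 20, n_samp = 8, miss = 0.05) {
  mk <- function() {
    m <- matrix(sample(0:2, n_samp * n_site, replace = TRUE), n_samp, n_site)
    m[matrix(stats::runif(length(m)) < miss, nrow(m), ncol(m))] <- NA
    m
  }
  list(obj = mk(), ref = mk())
}
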