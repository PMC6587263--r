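# Independent brute-force oracles used to validate the package estimators.
# These are deliberately written from first principles (pairwise loops,
# textbook formulas) and never share code with the implementation.

# mean pairwise difference per site over all haplotype pairs, / n_callable
oracle_pi <- function(hap, n_callable) {
  per_site <- 0
  for (s in seq_len(ncol(hap))) {
    a <- hap[, s]; a <- a[!is.na(a)]
    if (length(a) < 2) next
    cnt <- 0; mm <- 0
    for (i in seq_len(length(a) - 1)) for (j in (i + 1):length(a)) {
      mm <- mm + (a[i] != a[j]); cnt <- cnt + 1
    }
    per_site <- per_site + mm / cnt
  }
  per_site / n_callable
}

oracle_dxy <- function(h1, h2, n_callable) {
  tot <- 0
  for (s in seq_len(ncol(h1))) {
    a <- h1[, s]; b <- h2[, s]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) next
    cnt <- 0; mm <- 0
    for (x in a) for (y in b) { mm <- mm + (x != y); cnt <- cnt + 1 }
    tot <- tot + mm / cnt
  }
  tot / n_callable
}

# Weir & Cockerham (1984) theta-hat via the general multi-allele
# formulation (eqs. 2-4), summed over both alleles of a biallelic site.
oracle_wc_fst <- function(g1, g2) {
  num <- 0; den <- 0
  for (s in seq_len(ncol(g1))) {
    x1 <- g1[, s]; x2 <- g2[, s]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    if (n1 < nrow(g1) / 2 || n2 < nrow(g2) / 2) next
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    for (allele in c(0, 2)) {
      p1 <- mean(x1 == allele) + 0.5 * mean(x1 == 1)
      p2 <- mean(x2 == allele) + 0.5 * mean(x2 == 1)
      pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * mean(x1 == 1) + n2 * mean(x2 == 1)) / (n1 + n2)
      a <- nbar / nc * (s2 - 1 / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
        (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a / 2        # each allele contributes half
      den <- den + (a + b + cc) / 2
    }
  }
  if (den > 0) num / den else NA_real_
}

# Mantel test with explicit row/column permutation, written independently
oracle_mantel <- function(A, B, n_perm, seed) {
  set.seed(seed)
  lt <- lower.tri(A)
  r_obs <- cor(A[lt], B[lt])
  cnt <- 0
  for (b in seq_len(n_perm)) {
    p <- sample(nrow(A))
    if (cor(A[p, p][lt], B[lt]) >= r_obs) cnt <- cnt + 1
  }
  list(r = r_obs, p = (cnt + 1) / (n_perm + 1))
}

# expected downsampled SFS by hypergeometric projection of the full
# allele-count spectrum
oracle_projected_sfs_expectation <- function(counts_n, counts_i, target) {
  len <- target + 1L
  out <- numeric(len)
  for (s in seq_along(counts_n)) {
    n <- counts_n[s]; i <- counts_i[s]
    if (n < target) next
    for (d in 0:target)
      out[d + 1] <- out[d + 1] + dhyper(d, i, n - i, target)
  }
  out
}

# Tajima's D from the published constants, written out by hand
oracle_tajima_d <- function(pi_total, S, n) {
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# single-population constant-size model used across tests
single_pop_model <- function(ne = 10000, n_diploid = 10) {
  demographic_model(
    populations = data.frame(name = "A", n_diploid = n_diploid),
    epochs = list(A = data.frame(start_gen = 0, ne = ne)))
}

two_pop_isolation <- function(ne = 10000, split_gen = 20000,
                              n_diploid = 10) {
  demographic_model(
    populations = data.frame(name = c("X", "Y"),
                             n_diploid = rep(n_diploid, 2)),
    epochs = list(X = data.frame(start_gen = 0, ne = ne),
                  Y = data.frame(start_gen = 0, ne = ne)),
    splits = data.frame(time_gen = split_gen, derived = "Y",
                        ancestral = "X"))
}

# random symmetric zero-diagonal matrix (distance-like)
sym <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

random_hap_matrix <- function(n, S, p = 0.3, miss = 0) {
  m <- matrix(rbinom(n * S, 1, p), n, S)
  if (miss > 0) m[runif(n * S) < miss] <- NA
  m
}
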