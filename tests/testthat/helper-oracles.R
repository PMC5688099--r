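# Independent oracles used to cross-check the package's estimators.

# Weir & Cockerham (1984) theta for two populations, computed from diploid
# 0/1/2 genotypes. Independent of the Hudson estimator in R/popgen.R.
wc_fst <- function(genotypes, groups) {
  gl <- sort(unique(groups))
  stopifnot(length(gl) == 2)
  r <- 2
  sapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    n_i <- p_i <- h_i <- numeric(r)
    for (k in 1:r) {
      gk <- g[groups == gl[k]]
      gk <- gk[!is.na(gk)]
      n_i[k] <- length(gk)
      p_i[k] <- mean(gk) / 2
      h_i[k] <- mean(gk == 1)
    }
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) 0 else a / (a + b + cc)
  })
}

# Exhaustive fixed-margin enumeration of the lower-tail exclusivity
# probability: sum over all 2x2 tables with margins (ka, kb) out of n of
# the probability of at most `obs` co-occurrences.
enum_exclusivity_p <- function(n, ka, kb, obs) {
  ks <- max(0, ka + kb - n):min(ka, kb)
  mass <- choose(ka, ks) * choose(n - ka, kb - ks) / choose(n, kb)
  sum(mass[ks <= obs])
}

# Exhaustive 2^n sign-assignment enumeration of the two-sided signed-rank
# p-value for untied absolute differences.
enum_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.vector(signs %*% r)
  p_low <- mean(V_all <= V_obs)
  p_high <- mean(V_all >= V_obs)
  min(1, 2 * min(p_low, p_high))
}

# Adjusted Rand index between two labelings.
ari <- function(x, y) mclust::adjustedRandIndex(x, y)

# Balding-Nichols island-model genotypes: two populations of size n_per,
# m SNPs, divergence F around uniform ancestral frequencies.
sim_island_genotypes <- function(n_per, m, F, seed) {
  set.seed(seed)
  geno <- matrix(0L, 2 * n_per, m)
  for (j in seq_len(m)) {
    anc <- runif(1, 0.1, 0.9)
    p <- if (F > 0) {
      rbeta(2, anc * (1 - F) / F, (1 - anc) * (1 - F) / F)
    } else rep(anc, 2)
    geno[, j] <- c(rbinom(n_per, 2, p[1]), rbinom(n_per, 2, p[2]))
  }
  list(genotypes = geno,
       groups = rep(c("pop1", "pop2"), each = n_per))
}
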