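# Independent brute-force oracles used to validate the analytical
# implementations. These deliberately take the slow enumeration route.

# Pairwise-difference nucleotide diversity of one site by explicit
# enumeration over all haplotype pairs. `g` is a vector of diploid dosages.
oracle_site_pi <- function(g) {
  g <- g[!is.na(g)]
  hap <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
  n <- length(hap)
  if (n < 2) return(0)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diffs <- diffs + (hap[i] != hap[j])
  }
  diffs / choose(n, 2)
}

# Tajima's D of a complete genotype matrix (sites x samples), computed from
# scratch: enumerated pi, counted S, textbook constants.
oracle_tajima_d <- function(g) {
  stopifnot(!anyNA(g))
  n <- 2 * ncol(g)
  seg <- apply(g, 1, function(row) {
    s <- sum(row)
    s > 0 && s < 2 * length(row)
  })
  S <- sum(seg)
  if (n < 4 || S < 3) return(NA_real_)
  pi_tot <- sum(apply(g[seg, , drop = FALSE], 1, oracle_site_pi))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Two-sided Fisher exact p of a 2x2 table by hypergeometric enumeration,
# using the conventional "probabilities not larger than the observed" rule.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c          # first-column margin
  n <- b + d
  k <- a + b          # first-row margin
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (tie-free inputs).
oracle_mw_p <- function(x, y) {
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  nx <- length(x)
  r_obs <- sum(rank(vals)[seq_len(nx)])
  combos <- combn(length(vals), nx)
  rks <- rank(vals)
  w <- apply(combos, 2, function(idx) sum(rks[idx]))
  p_le <- mean(w <= r_obs)
  p_ge <- mean(w >= r_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Random small genotype matrix with given dimensions.
random_genotypes <- function(n_sites, n_samples, maf_range = c(0.1, 0.9)) {
  p <- runif(n_sites, maf_range[1], maf_range[2])
  g <- vapply(seq_len(n_samples), function(j) rbinom(n_sites, 2, p),
              numeric(n_sites))
  genotype_matrix(matrix(g, nrow = n_sites), rep("pop", n_samples),
                  positions = sort(sample.int(20000, n_sites)))
}

# Random tree with positive branch lengths; returns the tree and its
# additive path-length distance matrix.
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, d = cophenetic(tr))
}
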