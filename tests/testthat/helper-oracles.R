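# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles and share no code with the
# implementation under test.

# EHH by exhaustive enumeration of all haplotype pairs over the core->target
# span: fraction of carrier pairs identical over the whole span.
oracle_ehh <- function(hap_matrix, core, target, core_allele) {
  carriers <- which(hap_matrix[, core] == core_allele)
  if (length(carriers) < 2) return(NA_real_)
  span <- min(core, target):max(core, target)
  n_match <- 0; n_pair <- 0
  for (i in seq_along(carriers)) for (j in seq_len(i - 1)) {
    n_pair <- n_pair + 1
    if (all(hap_matrix[carriers[i], span] == hap_matrix[carriers[j], span]))
      n_match <- n_match + 1
  }
  n_match / n_pair
}

# Tajima's D from the haplotype matrix by the direct pairwise double loop.
oracle_tajimas_d <- function(hap_matrix) {
  n <- nrow(hap_matrix)
  seg <- apply(hap_matrix, 2, function(col) length(unique(col)) > 1)
  s <- sum(seg)
  if (s == 0) return(NA_real_)
  diffs <- 0; n_pair <- 0
  for (i in seq_len(n)) for (j in seq_len(i - 1)) {
    diffs <- diffs + sum(hap_matrix[i, ] != hap_matrix[j, ])
    n_pair <- n_pair + 1
  }
  pi_hat <- diffs / n_pair
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_hat - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

# Exact Hardy-Weinberg p-value by enumeration over all genotype
# configurations compatible with the allele counts, using exact multinomial
# probabilities (no factorial-cancellation shortcuts).
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq.int(min(nA, 2 * n - nA) %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    exp(lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) -
          lgamma(n - aa - h + 1) + h * log(2) +
          lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Small random phased haplotype fixture with a matching map.
random_hapset <- function(n_hap, n_snp, seed, p = NULL, spacing_bp = 1e5) {
  set.seed(seed)
  if (is.null(p)) p <- runif(n_snp, 0.1, 0.9)
  h <- matrix(rbinom(n_hap * n_snp, 1, rep(p, each = n_hap)), n_hap, n_snp)
  map <- marker_map(paste0("s", seq_len(n_snp)), "X",
                    pos_bp = cumsum(rep(spacing_bp, n_snp)),
                    ancestral = "allele_a")
  list(haps = haplotype_set(h, population = "test", snps = map$snp_id,
                            orientation = "ancestral_known", diploid = FALSE),
       map = map)
}
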