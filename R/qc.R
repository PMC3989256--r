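#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test given the allele counts: enumerates all heterozygote
#' counts compatible with the observed allele counts and sums the probabilities
#' of configurations no more probable than the observed one (two-sided by
#' cumulative probability).
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts (sum >= 1).
#' @return A p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotyped individual")
  nA <- 2L * n_AA + n_Aa
  na <- 2L * n_aa + n_Aa
  # heterozygote counts share the parity of the minor allele count
  n_min <- min(nA, na)
  h <- seq.int(n_min %% 2L, n_min, by = 2L)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_Aa, h)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Filter individuals on genotype call rate
#'
#' Individuals whose fraction of non-missing calls falls below
#' `min_call_rate` are discarded; order of the survivors is preserved.
#'
#' @param gt A [genotype_table()].
#' @param min_call_rate Minimum per-individual call rate in (0, 1].
#' @return A filtered [genotype_table()]. Warns (does not error) if no
#'   individual survives.
#' @export
filter_individuals <- function(gt, min_call_rate = 0.90) {
  stopifnot(inherits(gt, "genotype_table"),
            min_call_rate > 0, min_call_rate <= 1)
  rate <- rowMeans(!is.na(gt$calls))
  keep <- rate >= min_call_rate
  if (!any(keep)) warning("all individuals removed by call-rate filter")
  genotype_table(gt$calls[keep, , drop = FALSE],
                 individuals = gt$individuals[keep], snps = gt$snps)
}

#' Filter SNPs on call rate, Hardy-Weinberg equilibrium and MAF
#'
#' Filters are applied in fixed order: call rate, then HWE exact test, then
#' (only if `apply_maf`) minor allele frequency. The MAF filter is meant for
#' within-population statistics (iHS, Tajima's D) and is skipped for
#' between-population analyses.
#'
#' @param gt A [genotype_table()] for one population under analysis.
#' @param map Optional [marker_map()] filtered in parallel.
#' @param min_call_rate Minimum per-SNP call rate.
#' @param hwe_alpha SNPs with HWE exact p-value strictly below this are removed.
#' @param maf_min Minimum minor allele frequency (observed alleles).
#' @param apply_maf Whether to apply the MAF filter.
#' @return A list with `genotypes`, `map` (or `NULL`) and `report`, a
#'   data.frame of per-filter removal counts.
#' @export
filter_snps <- function(gt, map = NULL, min_call_rate = 0.90,
                        hwe_alpha = 1e-6, maf_min = 0.05, apply_maf = FALSE) {
  stopifnot(inherits(gt, "genotype_table"),
            min_call_rate > 0, min_call_rate <= 1,
            hwe_alpha >= 0, hwe_alpha <= 1, maf_min >= 0, maf_min <= 0.5)
  calls <- gt$calls
  keep <- rep(TRUE, ncol(calls))

  rate <- colMeans(!is.na(calls))
  fail_rate <- rate < min_call_rate
  keep <- keep & !fail_rate

  fail_hwe <- rep(FALSE, ncol(calls))
  for (j in which(keep)) {
    g <- calls[, j]
    n_aa <- sum(g == 0L, na.rm = TRUE)
    n_Aa <- sum(g == 1L, na.rm = TRUE)
    n_AA <- sum(g == 2L, na.rm = TRUE)
    if (n_aa + n_Aa + n_AA >= 1)
      fail_hwe[j] <- hwe_exact_p(n_AA, n_Aa, n_aa) < hwe_alpha
  }
  keep <- keep & !fail_hwe

  fail_maf <- rep(FALSE, ncol(calls))
  if (apply_maf) {
    for (j in which(keep)) {
      g <- calls[, j]
      n_obs <- 2 * sum(!is.na(g))
      if (n_obs == 0) next
      p <- sum(g, na.rm = TRUE) / n_obs
      fail_maf[j] <- min(p, 1 - p) < maf_min
    }
    keep <- keep & !fail_maf
  }

  report <- data.frame(
    filter = c("call_rate", "hwe", "maf"),
    n_removed = c(sum(fail_rate), sum(fail_hwe), sum(fail_maf)),
    applied = c(TRUE, TRUE, apply_maf))
  out_map <- NULL
  if (!is.null(map)) {
    out_map <- map[keep, , drop = FALSE]
    rownames(out_map) <- NULL
    class(out_map) <- c("marker_map", "data.frame")
  }
  list(genotypes = genotype_table(calls[, keep, drop = FALSE],
                                  individuals = gt$individuals,
                                  snps = gt$snps[keep]),
       map = out_map, report = report)
}
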