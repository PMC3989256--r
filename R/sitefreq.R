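#' Construct per-population allele counts
#'
#' @param x Matrix of allele-A counts, populations in rows, SNPs in columns.
#' @param n Matrix (same shape) of total observed allele counts.
#' @param populations,snps Optional labels.
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(x, n, populations = rownames(x), snps = colnames(x)) {
  x <- as.matrix(x); n <- as.matrix(n)
  stopifnot(all(dim(x) == dim(n)), all(x >= 0), all(x <= n))
  if (is.null(populations)) populations <- paste0("pop", seq_len(nrow(x)))
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(x)))
  structure(list(x = x, n = n, populations = populations, snps = snps),
            class = "allele_counts")
}

#' Allele counts from a genotype table or haplotype set
#'
#' @param obj A [genotype_table()] (missing calls reduce per-SNP `n`) or a
#'   [haplotype_set()].
#' @return For one object, a 1-population [allele_counts()]; use
#'   [combine_counts()] to stack populations.
#' @export
count_alleles <- function(obj) {
  if (inherits(obj, "haplotype_set")) {
    x <- colSums(obj$haplotypes)
    n <- rep(nrow(obj$haplotypes), ncol(obj$haplotypes))
    allele_counts(matrix(x, 1), matrix(n, 1), populations = obj$population,
                  snps = obj$snps)
  } else if (inherits(obj, "genotype_table")) {
    x <- colSums(obj$calls, na.rm = TRUE)
    n <- 2 * colSums(!is.na(obj$calls))
    allele_counts(matrix(x, 1), matrix(n, 1), snps = obj$snps)
  } else stop("unsupported object")
}

#' Stack single-population allele counts over shared SNPs
#'
#' @param ... [allele_counts()] objects with identical SNP sets.
#' @return A multi-population [allele_counts()].
#' @export
combine_counts <- function(...) {
  lst <- list(...)
  snps <- lst[[1]]$snps
  for (ac in lst) stopifnot(identical(ac$snps, snps))
  allele_counts(do.call(rbind, lapply(lst, function(a) a$x)),
                do.call(rbind, lapply(lst, function(a) a$n)),
                populations = unlist(lapply(lst, function(a) a$populations)),
                snps = snps)
}

#' Posterior draws of an allele frequency under a uniform prior
#'
#' With a non-informative (uniform) prior, the posterior of the allele-A
#' frequency given `x` copies among `n` observed alleles is
#' `Beta(x + 1, n - x + 1)`.
#'
#' @param x Allele-A count, `0 <= x <= n`.
#' @param n Total observed alleles, `n >= 1`.
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_draws` frequencies in `[0, 1]`.
#' @export
allele_freq_posterior <- function(x, n, n_draws = 1000, seed = NULL) {
  if (n < 1) stop("n must be at least 1")
  stopifnot(x >= 0, x <= n, n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rbeta(n_draws, x + 1, n - x + 1)
}

#' Per-locus Fst from population allele frequencies
#'
#' Wright-style ratio of the between-population variance of the allele
#' frequency to its maximum possible value:
#' `Fst = mean((p_r - pbar)^2) / (pbar * (1 - pbar))` with the unweighted
#' mean `pbar`. Ranges from 0 (identical populations) to 1 (populations fixed
#' for alternate alleles). When `pbar` is 0 or 1 there is no variation and
#' Fst is defined as 0.
#'
#' @param p Numeric vector of allele frequencies, one per population (R >= 2),
#'   or a matrix with populations in rows (vectorized over columns).
#' @return Fst value(s) in `[0, 1]`.
#' @export
fst_draw <- function(p) {
  if (is.matrix(p)) {
    stopifnot(nrow(p) >= 2, all(p >= 0 & p <= 1))
    pbar <- colMeans(p)
    v <- colMeans((p - matrix(pbar, nrow(p), ncol(p), byrow = TRUE))^2)
    den <- pbar * (1 - pbar)
    out <- ifelse(den > 0, v / den, 0)
    pmin(pmax(out, 0), 1)
  } else {
    fst_draw(matrix(p, ncol = 1))[1]
  }
}

#' Two-step Bayesian Fst track
#'
#' Step one draws per-population allele frequencies from their Beta posteriors
#' (uniform prior); step two treats those posterior samples as data and maps
#' each joint draw to a per-locus Fst via [fst_draw()]. The track carries the
#' posterior mean per SNP.
#'
#' @param counts A multi-population [allele_counts()].
#' @param map Optional [marker_map()] aligned to the counts.
#' @param n_draws Posterior draws per SNP (default 1000).
#' @param seed Integer seed; the track is reproducible given the seed.
#' @param keep_draws If `TRUE`, attach the per-SNP draw matrix.
#' @return A `score_track` data.frame with `raw_score` = posterior mean Fst
#'   (the `std_score` column repeats it; Fst is not z-standardized), and, if
#'   requested, an attribute `draws` (n_draws x n_snp matrix).
#' @export
fst_posterior_track <- function(counts, map = NULL, n_draws = 1000,
                                seed = NULL, keep_draws = FALSE) {
  stopifnot(inherits(counts, "allele_counts"), nrow(counts$x) >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_snp <- ncol(counts$x)
  draws <- fst_posterior_draws(counts$x, counts$n, n_draws)
  post_mean <- colMeans(draws)
  if (is.null(map))
    map <- marker_map(counts$snps, "chr", seq_len(n_snp))
  tr <- score_track(map, post_mean, post_mean, method = "fst",
                    population = paste(counts$populations, collapse = "_"))
  if (keep_draws) attr(tr, "draws") <- draws
  tr
}

# n_draws x n_snp matrix of per-locus Fst posterior draws; one vectorized
# rbeta call over populations x draws x SNPs
fst_posterior_draws <- function(x, n, n_draws) {
  n_pop <- nrow(x); n_snp <- ncol(x)
  a <- rep(as.vector(x) + 1, n_draws)
  b <- rep(as.vector(n - x) + 1, n_draws)
  p <- array(stats::rbeta(n_pop * n_snp * n_draws, a, b),
             dim = c(n_pop, n_snp * n_draws))
  matrix(fst_draw(p), nrow = n_draws, byrow = TRUE)
}

tajima_constants <- function(n) {
  stopifnot(n >= 4)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from per-site allele counts
#'
#' Contrasts the mean pairwise difference pi with the Watterson estimate
#' `S / a1`: `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with the standard
#' constants depending on the haplotype sample size `n` only. Pi is computed
#' from allele counts as `sum_sites 2*x*(n-x) / (n*(n-1))`, identical to the
#' haplotype pairwise-difference definition. D is near zero for neutral
#' variation, negative under an excess of rare variants (recent sweep),
#' positive under an excess of intermediate frequencies (balancing selection).
#'
#' @param x Vector of per-site derived (or minor; D is label-invariant) allele
#'   counts within the window; sites with `x == 0` or `x == n` are dropped.
#' @param n Haplotype sample size (>= 4), constant across sites.
#' @return Tajima's D, or `NA` if no site segregates.
#' @export
tajimas_d <- function(x, n) {
  stopifnot(n >= 4, all(x >= 0), all(x <= n))
  x <- x[x > 0 & x < n]
  s <- length(x)
  if (s == 0) return(NA_real_)
  k <- tajima_constants(n)
  pi_hat <- sum(2 * x * (n - x) / (n * (n - 1)))
  (pi_hat - s / k$a1) / sqrt(k$e1 * s + k$e2 * s * (s - 1))
}

#' Tile a chromosome into fixed, non-overlapping windows
#'
#' Windows are 0-based half-open `[k*w, (k+1)*w)` from position 0.
#'
#' @param chrom_length_bp Chromosome length in bp.
#' @param window_bp Window size in bp (default 800 kb).
#' @return data.frame with `start`, `end` (0-based half-open).
#' @export
window_tiles <- function(chrom_length_bp, window_bp = 800000) {
  stopifnot(window_bp > 0, chrom_length_bp > 0)
  n_win <- ceiling(chrom_length_bp / window_bp)
  data.frame(start = (seq_len(n_win) - 1) * window_bp,
             end = pmin(seq_len(n_win) * window_bp, chrom_length_bp))
}

#' Windowed scan of a per-SNP quantity
#'
#' Assigns SNPs (1-based bp converted to the half-open window convention) to
#' consecutive fixed windows and summarizes each window. For `statistic =
#' "tajimas_d"` the values are per-site derived-allele counts and each
#' window's D is computed from its site-frequency spectrum; for `"max"` /
#' `"mean"` the values are per-SNP scores (e.g. Fst posterior means) and the
#' window carries their max / mean.
#'
#' @param pos_bp 1-based SNP positions.
#' @param values Per-SNP values (counts for Tajima's D, scores otherwise).
#' @param chrom_length_bp Chromosome length; defaults to max position.
#' @param window_bp Window size in bp.
#' @param statistic `"tajimas_d"`, `"max"` or `"mean"`.
#' @param n Haplotype sample size (required for Tajima's D).
#' @return A `window_track` data.frame: `start`, `end`, `n_snps`, `statistic`,
#'   `flag` (`"empty"` or `"no_segregating"` where undefined).
#' @export
window_scan <- function(pos_bp, values, chrom_length_bp = max(pos_bp),
                        window_bp = 800000,
                        statistic = c("tajimas_d", "max", "mean"), n = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(length(pos_bp) == length(values))
  tiles <- window_tiles(chrom_length_bp, window_bp)
  # a SNP at bp k*w falls in the (k+1)-th window [k*w, (k+1)*w)
  idx <- findInterval(pos_bp, tiles$start)
  stat <- rep(NA_real_, nrow(tiles))
  nsnp <- integer(nrow(tiles))
  flag <- rep("", nrow(tiles))
  for (w in seq_len(nrow(tiles))) {
    v <- values[idx == w]
    nsnp[w] <- length(v)
    if (length(v) == 0) { flag[w] <- "empty"; next }
    if (statistic != "tajimas_d" && all(is.na(v))) { flag[w] <- "missing"; next }
    stat[w] <- switch(statistic,
                      tajimas_d = tajimas_d(v, n),
                      max = max(v, na.rm = TRUE),
                      mean = mean(v, na.rm = TRUE))
    if (is.na(stat[w]))
      flag[w] <- if (statistic == "tajimas_d") "no_segregating" else "missing"
  }
  out <- data.frame(start = tiles$start, end = tiles$end, n_snps = nsnp,
                    statistic = stat, flag = flag)
  class(out) <- c("window_track", "data.frame")
  out
}
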