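#' Extended haplotype homozygosity between a core SNP and a target SNP
#'
#' EHH is the probability that two haplotypes drawn at random among the
#' carriers of the core allele are identical over the whole interval from the
#' core SNP to the target SNP:
#' `EHH = sum_h C(e_h, 2) / C(c, 2)`, where the `e_h` are the counts of the
#' distinct extended haplotypes among the `c` core-allele carriers.
#'
#' @param haps A [haplotype_set()].
#' @param core_index Column index of the core SNP.
#' @param target_index Column index of the target SNP (may equal the core).
#' @param core_allele `0`, `1`, or `"all"` to use every haplotype (the
#'   cross-population convention used by XPEHH).
#' @return EHH in `[0, 1]`, or `NA` if fewer than two carriers exist.
#' @export
ehh_at <- function(haps, core_index, target_index, core_allele = "all") {
  h <- haps$haplotypes
  carriers <- if (identical(core_allele, "all")) seq_len(nrow(h))
              else which(h[, core_index] == core_allele)
  c_n <- length(carriers)
  if (c_n < 2) return(NA_real_)
  span <- seq(min(core_index, target_index), max(core_index, target_index))
  keys <- apply(h[carriers, span, drop = FALSE], 1, paste, collapse = "")
  e <- table(keys)
  sum(choose(e, 2)) / choose(c_n, 2)
}

#' One-sided EHH decay curve from a core SNP
#'
#' Walks SNP by SNP outward from the core, refining haplotype classes, until
#' EHH drops below `truncation` (the first sub-threshold point is kept as the
#' boundary point), the chromosome end, or `max_extend_cm` is reached.
#'
#' @inheritParams ehh_at
#' @param map A [marker_map()] aligned to `haps` (supplies cM positions).
#' @param side `"left"` or `"right"`.
#' @param truncation EHH level below which the walk stops (default 0.05).
#' @param max_extend_cm Maximum extension in cM from the core (default `Inf`).
#' @return A list of class `ehh_curve`: `core_snp`, `side`, `points` (a
#'   data.frame with `dist_cm` >= 0 and `ehh`), `core_allele`, and
#'   `stop_reason` in `{"truncated", "chrom_end", "max_extend"}`.
#' @export
ehh_curve <- function(haps, map, core_index, core_allele = "all",
                      side = c("right", "left"), truncation = 0.05,
                      max_extend_cm = Inf) {
  side <- match.arg(side)
  h <- haps$haplotypes
  carriers <- if (identical(core_allele, "all")) seq_len(nrow(h))
              else which(h[, core_index] == core_allele)
  c_n <- length(carriers)
  if (c_n < 2)
    return(structure(list(core_snp = haps$snps[core_index], side = side,
                          points = data.frame(dist_cm = 0, ehh = NA_real_),
                          core_allele = core_allele,
                          stop_reason = "too_few_carriers"),
                     class = "ehh_curve"))
  step <- if (side == "right") 1L else -1L
  n_snp <- ncol(h)
  pairs_tot <- choose(c_n, 2)
  # group ids refine as the walk extends; homozygosity from class sizes
  grp <- rep(1L, c_n)
  dist <- 0
  ehh <- 1
  j <- core_index
  stop_reason <- "chrom_end"
  repeat {
    jn <- j + step
    if (jn < 1L || jn > n_snp) { stop_reason <- "chrom_end"; break }
    d <- abs(map$pos_cm[jn] - map$pos_cm[core_index])
    if (d > max_extend_cm) { stop_reason <- "max_extend"; break }
    key <- grp * 2L + h[carriers, jn]
    grp <- match(key, unique(key))
    e <- sum(choose(tabulate(grp), 2)) / pairs_tot
    dist <- c(dist, d)
    ehh <- c(ehh, e)
    j <- jn
    if (e < truncation) { stop_reason <- "truncated"; break }
  }
  structure(list(core_snp = haps$snps[core_index], side = side,
                 points = data.frame(dist_cm = dist, ehh = ehh),
                 core_allele = core_allele, stop_reason = stop_reason),
            class = "ehh_curve")
}

#' Integrated EHH (iHH) from a pair of one-sided curves
#'
#' Trapezoidal integral of EHH over genetic distance, summed over the two
#' sides of the core. Zero-width cM gaps contribute zero area.
#'
#' @param curve_left,curve_right [ehh_curve()] objects sharing a core SNP.
#' @return iHH in cM units (>= 0).
#' @export
integrate_ihh <- function(curve_left, curve_right) {
  if (!identical(curve_left$core_snp, curve_right$core_snp))
    stop("curves must share the same core SNP")
  side_area <- function(cv) {
    p <- cv$points
    if (nrow(p) < 2 || anyNA(p$ehh)) return(0)
    sum(diff(p$dist_cm) * (utils::head(p$ehh, -1) + utils::tail(p$ehh, -1)) / 2)
  }
  side_area(curve_left) + side_area(curve_right)
}

ihh_for_allele <- function(haps, map, core_index, core_allele,
                           truncation = 0.05, max_extend_cm = Inf) {
  cl <- ehh_curve(haps, map, core_index, core_allele, side = "left",
                  truncation = truncation, max_extend_cm = max_extend_cm)
  cr <- ehh_curve(haps, map, core_index, core_allele, side = "right",
                  truncation = truncation, max_extend_cm = max_extend_cm)
  list(ihh = integrate_ihh(cl, cr),
       edge = (cl$stop_reason == "chrom_end" &&
                 utils::tail(cl$points$ehh, 1) >= truncation) ||
              (cr$stop_reason == "chrom_end" &&
                 utils::tail(cr$points$ehh, 1) >= truncation))
}

#' Raw cross-population EHH score
#'
#' `ln(iHH_obs / iHH_ref)`. A negative score points to selection in the
#' reference population, a positive one to the observed population.
#'
#' @param ihh_obs,ihh_ref Integrated EHH in the observed and reference
#'   populations at the same core SNP.
#' @return The log ratio, or `NA` if either integral is zero.
#' @export
xpehh_raw <- function(ihh_obs, ihh_ref) {
  out <- ifelse(ihh_obs > 0 & ihh_ref > 0, log(ihh_obs / ihh_ref), NA_real_)
  out
}

#' Raw integrated haplotype score
#'
#' `ln(iHH_ancestral / iHH_derived)`: negative when the derived allele sits on
#' unusually long shared haplotypes (an ongoing sweep).
#'
#' @param ihh_ancestral,ihh_derived Integrated EHH for carriers of the
#'   ancestral and derived core allele.
#' @return The log ratio, or `NA` if either integral is zero.
#' @export
ihs_raw <- function(ihh_ancestral, ihh_derived) {
  ifelse(ihh_ancestral > 0 & ihh_derived > 0,
         log(ihh_ancestral / ihh_derived), NA_real_)
}

#' Standardize scan scores to zero mean and unit variance
#'
#' `mode = "global"` is classic z-scoring (used for XPEHH); `mode =
#' "freq_bins"` standardizes within derived-allele-frequency bins (used for
#' iHS, so that the statistic is comparable across frequency classes). Bins
#' with fewer than `min_bin` scores are merged with their nearest neighbour.
#'
#' @param scores Numeric vector of raw scores (`NA` allowed, passed through).
#' @param freq Derived allele frequencies, required for `mode = "freq_bins"`.
#' @param mode `"global"` or `"freq_bins"`.
#' @param bin_width Frequency bin width (default 0.02).
#' @param min_bin Minimum scores per bin before merging (default 20).
#' @return Standardized scores; within each bin the non-`NA` values have mean
#'   0 and sd 1 exactly.
#' @export
standardize_scores <- function(scores, freq = NULL,
                               mode = c("global", "freq_bins"),
                               bin_width = 0.02, min_bin = 20) {
  mode <- match.arg(mode)
  ok <- !is.na(scores)
  out <- rep(NA_real_, length(scores))
  if (mode == "global") {
    if (sum(ok) < 2) stop("need at least two scores to standardize")
    s <- stats::sd(scores[ok])
    if (s == 0) stop("zero variance in global bin")
    out[ok] <- (scores[ok] - mean(scores[ok])) / s
    return(out)
  }
  if (is.null(freq)) stop("freq_bins mode requires derived allele frequencies")
  stopifnot(length(freq) == length(scores))
  bin <- pmin(floor(freq / bin_width), floor(1 / bin_width) - 1)
  bin[!ok] <- NA
  # merge sparse bins with their nearest occupied neighbour
  repeat {
    tab <- table(bin[ok])
    small <- names(tab)[tab < min_bin]
    if (length(small) == 0 || length(tab) == 1) break
    b <- as.numeric(small[1])
    others <- as.numeric(setdiff(names(tab), small[1]))
    nearest <- others[which.min(abs(others - b))]
    bin[!is.na(bin) & bin == b] <- nearest
  }
  for (b in unique(bin[ok])) {
    i <- ok & !is.na(bin) & bin == b
    if (sum(i) < 2) stop("bin ", b, " has fewer than 2 scores")
    s <- stats::sd(scores[i])
    if (s == 0) stop("zero variance in frequency bin ", b)
    out[i] <- (scores[i] - mean(scores[i])) / s
  }
  out
}

#' Genome scan of the integrated haplotype score (iHS)
#'
#' For each SNP with known ancestral orientation and minor allele frequency at
#' least `min_maf`, computes iHH separately for carriers of the ancestral and
#' derived core allele, takes `ln(iHH_A / iHH_D)`, and standardizes within
#' derived-allele-frequency bins.
#'
#' @param haps A [haplotype_set()] coded 0 = ancestral where orientation is
#'   known, or accompanied by `ancestral_fallback`.
#' @param map A [marker_map()] aligned to `haps`.
#' @param min_maf Within-population MAF filter (default 0.05).
#' @param truncation,max_extend_cm EHH curve controls, see [ehh_curve()].
#' @param bin_width,min_bin Standardization controls, see
#'   [standardize_scores()].
#' @param ancestral_fallback If `TRUE`, SNPs of unknown orientation are
#'   polarized by taking the major allele as ancestral (with a warning);
#'   otherwise they are skipped.
#' @return A `score_track` data.frame: `snp_id`, `chrom`, `pos_bp`,
#'   `derived_freq`, `raw_score`, `std_score`, `n_anc`, `n_der`, `flag`.
#' @export
ihs_scan <- function(haps, map, min_maf = 0.05, truncation = 0.05,
                     max_extend_cm = Inf, bin_width = 0.02, min_bin = 20,
                     ancestral_fallback = FALSE) {
  h <- haps$haplotypes
  n_snp <- ncol(h)
  derived <- rep(1L, n_snp)   # allele code counted as derived
  known <- haps$orientation == "ancestral_known"
  if (any(!known)) {
    if (ancestral_fallback) {
      warning(sum(!known), " SNPs polarized by major-allele-as-ancestral fallback")
      maj <- colMeans(h[, !known, drop = FALSE]) > 0.5
      derived[!known][maj] <- 0L
      known[!known] <- TRUE
    }
  }
  raw <- rep(NA_real_, n_snp)
  dfreq <- colMeans(h == matrix(derived, nrow(h), n_snp, byrow = TRUE))
  n_anc <- round((1 - dfreq) * nrow(h))
  n_der <- nrow(h) - n_anc
  flag <- rep("", n_snp)
  flag[!known] <- "no_ancestral"
  usable <- known & pmin(dfreq, 1 - dfreq) >= min_maf
  flag[known & !usable] <- "maf"
  for (j in which(usable)) {
    anc <- ihh_for_allele(haps, map, j, 1L - derived[j], truncation, max_extend_cm)
    der <- ihh_for_allele(haps, map, j, derived[j], truncation, max_extend_cm)
    raw[j] <- ihs_raw(anc$ihh, der$ihh)
    if (anc$edge || der$edge) flag[j] <- "edge_truncated"
  }
  std <- rep(NA_real_, n_snp)
  if (sum(!is.na(raw)) >= 2)
    std <- standardize_scores(raw, freq = dfreq, mode = "freq_bins",
                              bin_width = bin_width, min_bin = min_bin)
  score_track(map, raw, std, method = "ihs", population = haps$population,
              extra = data.frame(derived_freq = dfreq, n_anc = n_anc,
                                 n_der = n_der, flag = flag))
}

#' Genome scan of the cross-population EHH score (XPEHH)
#'
#' At each shared SNP, EHH is computed over all haplotypes of each population
#' (not split by core allele), integrated over genetic distance, and the score
#' is `ln(iHH_obs / iHH_ref)`; both the raw and the globally standardized
#' track are returned.
#'
#' @param haps_obs,haps_ref [haplotype_set()]s of the observed and reference
#'   populations over the same SNPs.
#' @param map A [marker_map()] aligned to both.
#' @param truncation,max_extend_cm EHH curve controls, see [ehh_curve()].
#' @return A `score_track` data.frame with `raw_score` and `std_score`.
#' @export
xpehh_scan <- function(haps_obs, haps_ref, map, truncation = 0.05,
                       max_extend_cm = Inf) {
  stopifnot(ncol(haps_obs$haplotypes) == ncol(haps_ref$haplotypes))
  n_snp <- ncol(haps_obs$haplotypes)
  raw <- rep(NA_real_, n_snp)
  flag <- rep("", n_snp)
  for (j in seq_len(n_snp)) {
    a <- ihh_for_allele(haps_obs, map, j, "all", truncation, max_extend_cm)
    b <- ihh_for_allele(haps_ref, map, j, "all", truncation, max_extend_cm)
    raw[j] <- xpehh_raw(a$ihh, b$ihh)
    if (is.na(raw[j])) flag[j] <- "zero_ihh"
    else if (a$edge || b$edge) flag[j] <- "edge_truncated"
  }
  std <- rep(NA_real_, n_snp)
  if (sum(!is.na(raw)) >= 2) std <- standardize_scores(raw, mode = "global")
  score_track(map, raw, std, method = "xpehh",
              population = paste0(haps_obs$population, "_vs_",
                                  haps_ref$population),
              extra = data.frame(flag = flag))
}

score_track <- function(map, raw, std, method, population, extra = NULL) {
  out <- data.frame(snp_id = map$snp_id, chrom = map$chromosome,
                    pos_bp = map$pos_bp, raw_score = raw, std_score = std,
                    method = method, population = population,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) out <- cbind(out, extra)
  class(out) <- c("score_track", "data.frame")
  out
}
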