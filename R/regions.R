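#' Empirical top-fraction cutoff from autosomal scores
#'
#' Significance of the multi-marker statistics (XPEHH, iHS, XPCLR) is judged
#' against the empirical distribution of the same statistic on the autosomes:
#' the top 5% of autosomal signals defines the cutoff applied to the X
#' chromosome. Quantiles use linear interpolation of the empirical CDF
#' (`stats::quantile` type 7).
#'
#' @param autosome_scores Numeric vector of genome-wide autosomal scores
#'   (`NA` dropped); at least `min_scores` required.
#' @param fraction Flagged fraction (default 0.05).
#' @param min_scores Minimum number of scores for a stable empirical quantile
#'   (default 100; chip-scale inputs far exceed it).
#' @param two_sided If `TRUE`, lower/upper cutoffs at `fraction/2` and
#'   `1 - fraction/2`; otherwise a single upper cutoff at `1 - fraction`.
#' @return An object of class `sel_threshold` with `lower`, `upper`,
#'   `provenance = "autosome_top_fraction"`.
#' @export
autosomal_cutoff <- function(autosome_scores, fraction = 0.05,
                             two_sided = FALSE, min_scores = 100) {
  scores <- autosome_scores[!is.na(autosome_scores)]
  if (length(scores) < min_scores)
    stop("need at least ", min_scores, " autosomal scores")
  stopifnot(fraction > 0, fraction <= 1)
  if (two_sided) {
    q <- stats::quantile(scores, c(fraction / 2, 1 - fraction / 2),
                         type = 7, names = FALSE)
    thr <- list(lower = q[1], upper = q[2])
  } else {
    thr <- list(lower = NULL,
                upper = stats::quantile(scores, 1 - fraction, type = 7,
                                        names = FALSE))
  }
  structure(c(thr, list(provenance = "autosome_top_fraction",
                        fraction = fraction, two_sided = two_sided)),
            class = "sel_threshold")
}

#' @export
print.sel_threshold <- function(x, ...) {
  cat(sprintf("<sel_threshold> %s: lower=%s upper=%s\n", x$provenance,
              if (is.null(x$lower)) "-" else format(x$lower, digits = 4),
              if (is.null(x$upper)) "-" else format(x$upper, digits = 4)))
  invisible(x)
}

#' Permutation null threshold for frequency-based statistics
#'
#' Builds an empirical null for per-SNP Fst or windowed Tajima's D by
#' shuffling each population's per-SNP allele-frequency vector independently
#' across the fixed SNP positions, recomputing the statistic each time, and
#' pooling all permuted values. This breaks both the SNP-position structure
#' and the cross-population coupling, giving a no-differentiation null.
#' Permutation is only offered for statistics that use allele frequencies
#' alone: shuffling frequencies destroys LD, so a permutation null is not
#' meaningful for the haplotype and composite-likelihood scans.
#'
#' @param counts A multi-population [allele_counts()] (Fst) or a
#'   single-population one (Tajima's D).
#' @param statistic `"fst"` (per-SNP plug-in Fst of the shuffled frequencies)
#'   or `"tajimas_d"` (per-window D of the shuffled site counts).
#' @param pos_bp SNP positions (required for `"tajimas_d"` windowing).
#' @param window_bp,chrom_length_bp Windowing controls for Tajima's D.
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param two_sided Lower tail too? Default `TRUE` for Tajima's D (sweeps are
#'   the lower tail, balancing selection the upper), `FALSE` for Fst.
#' @param n_draws Posterior draws per permuted SNP for the Fst statistic.
#'   Keep it equal to the draw count of the observed track (default 1000 for
#'   both): the null must carry the same Monte-Carlo noise as the statistic
#'   it calibrates, or the threshold is biased wherever posterior means
#'   cluster (e.g. at near-fixed SNPs).
#' @param seed Integer seed; the threshold is reproducible given the seed.
#' @return A `sel_threshold` with `provenance = "permutation"` and the pooled
#'   null size `n_null`.
#' @export
permutation_threshold <- function(counts, statistic = c("fst", "tajimas_d"),
                                  pos_bp = NULL, window_bp = 800000,
                                  chrom_length_bp = NULL, n_perm = 5000,
                                  alpha = 0.05,
                                  two_sided = (statistic == "tajimas_d"),
                                  n_draws = 1000, seed = NULL) {
  statistic <- match.arg(statistic)
  force(two_sided)
  stopifnot(inherits(counts, "allele_counts"), n_perm >= 100)
  if (!is.null(seed)) set.seed(seed)
  n_pop <- nrow(counts$x)
  n_snp <- ncol(counts$x)
  null_vals <- vector("list", n_perm)
  if (statistic == "fst") {
    stopifnot(n_pop >= 2)
    if (n_pop == 2) {
      # two-population fast path: draw each population's posterior samples
      # once, tabulate the posterior-mean Fst of every cross-pairing of SNP
      # columns, then each permutation only re-pairs the columns
      D <- lapply(1:2, function(r)
        matrix(stats::rbeta(n_draws * n_snp,
                            rep(counts$x[r, ] + 1, each = n_draws),
                            rep(counts$n[r, ] - counts$x[r, ] + 1,
                                each = n_draws)),
               nrow = n_draws))
      pairF <- matrix(NA_real_, n_snp, n_snp)
      for (a in seq_len(n_snp)) {
        p1 <- D[[1]][, a]
        num <- (p1 - D[[2]])^2
        den <- (p1 + D[[2]]) * (2 - p1 - D[[2]])
        pairF[a, ] <- colMeans(ifelse(den > 0, num / den, 0))
      }
      for (b in seq_len(n_perm)) {
        ord1 <- sample.int(n_snp); ord2 <- sample.int(n_snp)
        null_vals[[b]] <- pairF[cbind(ord1, ord2)]
      }
    } else {
      for (b in seq_len(n_perm)) {
        ord <- vapply(seq_len(n_pop), function(r) sample.int(n_snp),
                      integer(n_snp))
        x_perm <- t(vapply(seq_len(n_pop),
                           function(r) counts$x[r, ord[, r]],
                           numeric(n_snp)))
        n_perm_mat <- t(vapply(seq_len(n_pop),
                               function(r) counts$n[r, ord[, r]],
                               numeric(n_snp)))
        null_vals[[b]] <- colMeans(fst_posterior_draws(x_perm, n_perm_mat,
                                                       n_draws))
      }
    }
  } else {
    stopifnot(!is.null(pos_bp), length(pos_bp) == n_snp)
    if (is.null(chrom_length_bp)) chrom_length_bp <- max(pos_bp)
    n <- counts$n[1, 1]
    for (b in seq_len(n_perm)) {
      x_perm <- counts$x[1, sample.int(n_snp)]
      wt <- window_scan(pos_bp, x_perm, chrom_length_bp, window_bp,
                        statistic = "tajimas_d", n = n)
      null_vals[[b]] <- wt$statistic[!is.na(wt$statistic)]
    }
  }
  pool <- unlist(null_vals)
  if (two_sided) {
    thr <- list(lower = stats::quantile(pool, alpha, type = 7, names = FALSE),
                upper = stats::quantile(pool, 1 - alpha, type = 7,
                                        names = FALSE))
  } else {
    thr <- list(lower = NULL,
                upper = stats::quantile(pool, 1 - alpha, type = 7,
                                        names = FALSE))
  }
  structure(c(thr, list(provenance = "permutation", alpha = alpha,
                        n_permutations = n_perm, n_null = length(pool),
                        two_sided = two_sided, seed = seed)),
            class = "sel_threshold")
}

#' Flag outlier SNPs beyond a threshold
#'
#' Scores strictly above the upper cutoff and (when present) strictly below
#' the lower cutoff are flagged; exact ties are not flagged. For signed
#' cross-population scores (XPEHH) the flag direction partitions footprints:
#' positive outliers indicate selection in the observed population, negative
#' ones in the reference population.
#'
#' @param track A `score_track` (uses `std_score` where non-`NA`, else
#'   `raw_score`) or a numeric vector.
#' @param threshold A `sel_threshold`.
#' @param use `"std_score"`, `"raw_score"` or `"auto"` (default).
#' @return A data.frame of flagged SNPs with `index`, `score` and `direction`
#'   (`"upper"` or `"lower"`); for score tracks also `snp_id`, `chrom`,
#'   `pos_bp`.
#' @export
flag_outliers <- function(track, threshold, use = "auto") {
  stopifnot(inherits(threshold, "sel_threshold"))
  if (is.numeric(track)) {
    score <- track
    meta <- NULL
  } else {
    col <- if (use == "auto") {
      if (any(!is.na(track$std_score))) "std_score" else "raw_score"
    } else use
    score <- track[[col]]
    meta <- track[, intersect(c("snp_id", "chrom", "pos_bp"), names(track)),
                  drop = FALSE]
  }
  up <- if (!is.null(threshold$upper)) score > threshold$upper else FALSE
  lo <- if (!is.null(threshold$lower)) score < threshold$lower else FALSE
  up[is.na(up)] <- FALSE
  lo[is.na(lo)] <- FALSE
  idx <- which(up | lo)
  out <- data.frame(index = idx, score = score[idx],
                    direction = ifelse(up[idx], "upper", "lower"),
                    stringsAsFactors = FALSE)
  if (!is.null(meta)) out <- cbind(meta[idx, , drop = FALSE], out)
  rownames(out) <- NULL
  out
}

#' Build selection regions around flagged footprints
#'
#' Each flagged SNP is extended `extend_bp` towards both its upstream and
#' downstream direction (clipped at the chromosome bounds) and overlapping or
#' book-ended intervals are merged. Intervals are 0-based half-open.
#'
#' @param flagged A data.frame from [flag_outliers()] with `pos_bp` and
#'   `score` columns (1-based positions), or a numeric vector of positions.
#' @param extend_bp Extension on each side (default 400 kb).
#' @param chrom_length_bp Upper clip bound (default `Inf`).
#' @param chrom,method,population Provenance labels carried on the regions.
#' @return A data.frame of class `selection_regions`: `chrom`, `start`, `end`
#'   (0-based half-open), `method`, `population`, `peak_score`, `peak_pos_bp`,
#'   `n_snps`; pairwise disjoint and sorted.
#' @export
build_regions <- function(flagged, extend_bp = 400000,
                          chrom_length_bp = Inf, chrom = "X",
                          method = "", population = "") {
  if (is.numeric(flagged))
    flagged <- data.frame(pos_bp = flagged, score = NA_real_)
  if (nrow(flagged) == 0) return(empty_regions())
  flagged <- flagged[order(flagged$pos_bp), , drop = FALSE]
  start <- pmax(flagged$pos_bp - extend_bp, 0)
  end <- pmin(flagged$pos_bp + extend_bp, chrom_length_bp)
  ir <- IRanges::IRanges(start = start + 1, end = end)   # 1-based closed
  merged <- IRanges::reduce(ir)
  hit <- IRanges::findOverlaps(IRanges::IRanges(flagged$pos_bp,
                                                flagged$pos_bp), merged)
  out <- data.frame(chrom = chrom,
                    start = IRanges::start(merged) - 1,
                    end = IRanges::end(merged),
                    method = method, population = population,
                    peak_score = NA_real_, peak_pos_bp = NA_real_,
                    n_snps = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    i <- S4Vectors::queryHits(hit)[S4Vectors::subjectHits(hit) == k]
    out$n_snps[k] <- length(i)
    if (length(i) && any(!is.na(flagged$score[i]))) {
      j <- i[which.max(abs(flagged$score[i]))]
      out$peak_score[k] <- flagged$score[j]
      out$peak_pos_bp[k] <- flagged$pos_bp[j]
    }
  }
  class(out) <- c("selection_regions", "data.frame")
  out
}

empty_regions <- function() {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    method = character(), population = character(),
                    peak_score = numeric(), peak_pos_bp = numeric(),
                    n_snps = integer(), stringsAsFactors = FALSE)
  class(out) <- c("selection_regions", "data.frame")
  out
}

#' Flag fixed windows whose contents exceed a threshold
#'
#' For the window-based statistics (Fst, Tajima's D) a window is a selection
#' region iff it contains at least one value beyond the threshold; regions
#' keep the fixed window length and adjacent flagged windows are not merged.
#'
#' @param wtrack A `window_track` (from [window_scan()]); `statistic` holds
#'   the per-window value tested (for Fst, use a track of per-SNP posterior
#'   means and `per_snp_scores`/`per_snp_pos` instead).
#' @param threshold A `sel_threshold`.
#' @param per_snp_scores,per_snp_pos Optional per-SNP values and positions;
#'   when given, a window is flagged iff any contained SNP exceeds the
#'   threshold (the per-SNP rule used for Fst).
#' @param chrom,method,population Provenance labels.
#' @return A `selection_regions` data.frame of fixed-length windows.
#' @export
flag_windows <- function(wtrack, threshold, per_snp_scores = NULL,
                         per_snp_pos = NULL, chrom = "X", method = "",
                         population = "") {
  stopifnot(inherits(threshold, "sel_threshold"))
  beyond <- function(v) {
    up <- if (!is.null(threshold$upper)) v > threshold$upper else FALSE
    lo <- if (!is.null(threshold$lower)) v < threshold$lower else FALSE
    (up | lo) & !is.na(v)
  }
  if (!is.null(per_snp_scores)) {
    stopifnot(length(per_snp_scores) == length(per_snp_pos))
    flag_snp <- beyond(per_snp_scores)
    keep <- vapply(seq_len(nrow(wtrack)), function(w) {
      inw <- per_snp_pos > wtrack$start[w] & per_snp_pos <= wtrack$end[w]
      any(flag_snp & inw)
    }, logical(1))
    peak <- vapply(seq_len(nrow(wtrack)), function(w) {
      inw <- per_snp_pos > wtrack$start[w] & per_snp_pos <= wtrack$end[w]
      if (!any(inw)) NA_real_ else max(abs(per_snp_scores[inw]), na.rm = TRUE)
    }, numeric(1))
    nsnp <- wtrack$n_snps
  } else {
    keep <- beyond(wtrack$statistic)
    peak <- wtrack$statistic
    nsnp <- wtrack$n_snps
  }
  if (!any(keep)) return(empty_regions())
  out <- data.frame(chrom = chrom, start = wtrack$start[keep],
                    end = wtrack$end[keep], method = method,
                    population = population, peak_score = peak[keep],
                    peak_pos_bp = NA_real_, n_snps = nsnp[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("selection_regions", "data.frame")
  out
}

#' Empirical quantile of a score within a reference distribution
#'
#' The q-value reported alongside a footprint: the empirical CDF rank
#' `(# reference values <= score) / N`, i.e. which quantile of the reference
#' statistic the value cuts off.
#'
#' @param score Numeric score(s).
#' @param reference_scores Non-empty reference distribution (`NA` dropped).
#' @return q in `[0, 1]`, vectorized over `score`.
#' @export
quantile_value <- function(score, reference_scores) {
  ref <- reference_scores[!is.na(reference_scores)]
  if (length(ref) == 0) stop("reference distribution is empty")
  vapply(score, function(s) mean(ref <= s), numeric(1))
}

#' Pairwise overlap of selection regions across methods (Mb)
#'
#' @param regions_by_method Named list of `selection_regions` data.frames,
#'   all on the same chromosome and population.
#' @return Symmetric matrix in Mb: diagonal = total merged length per method;
#'   off-diagonal = total intersection length of the two merged sets.
#' @export
overlap_matrix <- function(regions_by_method) {
  methods <- names(regions_by_method)
  stopifnot(!is.null(methods))
  as_ir <- function(r) {
    if (nrow(r) == 0) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(start = r$start + 1, end = r$end))
  }
  irs <- lapply(regions_by_method, as_ir)
  m <- matrix(0, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_along(methods)) for (j in seq_along(methods)) {
    m[i, j] <- if (i == j) sum(IRanges::width(irs[[i]])) / 1e6
               else sum(IRanges::width(IRanges::intersect(irs[[i]],
                                                          irs[[j]]))) / 1e6
  }
  m
}

#' Write selection regions as BED
#'
#' BED is 0-based half-open, matching the in-memory convention; the name field
#' is `method:population` and the score field the peak score.
#'
#' @param regions A `selection_regions` data.frame.
#' @param path Output file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE),
                    name = paste0(regions$method, ":", regions$population),
                    score = ifelse(is.na(regions$peak_score), 0,
                                   round(regions$peak_score, 4)))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
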