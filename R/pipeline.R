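#' Scan one chromosome for selection footprints
#'
#' The orchestrating fit function: runs any subset of the five statistics over
#' all populations / population pairs, derives significance thresholds
#' (empirical autosomal top-fraction cutoffs for the multi-marker statistics
#' XPEHH, iHS and XPCLR; permutation nulls for the frequency-only statistics
#' Fst and Tajima's D), flags footprints, builds selection regions (+-
#' `extend_bp` extension and merging for SNP-based methods, fixed windows for
#' the window-based ones), and computes per-population cross-method overlap.
#'
#' Pair handling mirrors the asymmetry of the statistics: XPEHH runs once per
#' pair (its sign assigns each footprint to the observed or the reference
#' population), XPCLR runs twice per pair (each population in turn as the
#' observed one), and an Fst region indicates selection in both populations
#' of its pair.
#'
#' @param haps Named list of [haplotype_set()]s over the same SNPs (one per
#'   population). Within-population methods need >= 1, between-population
#'   methods >= 2 populations.
#' @param map A [marker_map()] aligned to the haplotype sets.
#' @param methods Subset of `c("xpehh", "xpclr", "fst", "ihs", "tajd")`.
#' @param chrom_length_bp Chromosome length (default: last SNP position).
#' @param window_bp Window size for Fst / Tajima's D regions (800 kb).
#' @param extend_bp Footprint extension for SNP-based regions (400 kb).
#' @param fraction Autosomal top fraction for XPEHH/iHS/XPCLR cutoffs (0.05).
#' @param alpha Permutation significance level for Fst/Tajima's D (0.05).
#' @param n_perm Number of permutations (default 5000).
#' @param autosome_scores Named list of autosomal score vectors per method
#'   (`xpehh`/`ihs` standardized scores, `xpclr` CLR values). Missing entries
#'   are generated by simulating `n_autosomes` extra neutral chromosomes with
#'   `sim_config` and scanning them the same way.
#' @param sim_config A [sweep_sim_config()] used to generate autosomal
#'   calibration chromosomes when needed.
#' @param n_autosomes Number of neutral calibration chromosomes (default 3).
#' @param xpclr_control An [xpclr_model()] (omega is re-estimated per pair).
#' @param min_maf Within-population MAF filter applied for iHS.
#' @param seed Integer seed controlling permutations and simulated autosomes.
#' @return An object of class `selscan`; see [summary.selscan()],
#'   [regions()], [overlap_mb()].
#' @export
selscan <- function(haps, map, methods = c("xpehh", "xpclr", "fst", "ihs",
                                           "tajd"),
                    chrom_length_bp = NULL, window_bp = 800000,
                    extend_bp = 400000, fraction = 0.05, alpha = 0.05,
                    n_perm = 5000, autosome_scores = list(),
                    sim_config = NULL, n_autosomes = 3,
                    xpclr_control = xpclr_model(), min_maf = 0.05,
                    seed = 1L) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(length(haps) >= 1)
  if (is.null(names(haps)) || any(!nzchar(names(haps))))
    names(haps) <- vapply(haps, function(h) h$population, character(1))
  between <- intersect(methods, c("xpehh", "xpclr", "fst"))
  if (length(between) > 0 && length(haps) < 2)
    stop("between-population methods (", paste(between, collapse = ", "),
         ") require at least two populations")
  if (is.null(chrom_length_bp)) chrom_length_bp <- max(map$pos_bp)
  pops <- names(haps)
  pairs <- if (length(pops) >= 2) utils::combn(pops, 2, simplify = FALSE)
           else list()

  tracks <- list(); wtracks <- list(); thresholds <- list()
  regions <- list(); footprints <- list()

  need_auto <- intersect(methods, c("xpehh", "ihs", "xpclr"))
  need_auto <- setdiff(need_auto, names(autosome_scores))
  if (length(need_auto) > 0) {
    if (is.null(sim_config))
      stop("no autosomal calibration scores for ",
           paste(need_auto, collapse = ", "),
           "; supply autosome_scores or sim_config")
    autosome_scores <- c(autosome_scores,
                         simulate_autosome_scores(need_auto, haps, sim_config,
                                                  n_autosomes,
                                                  xpclr_control, min_maf,
                                                  seed = seed + 7L))
  }

  if ("xpehh" %in% methods) {
    thresholds$xpehh <- autosomal_cutoff(autosome_scores$xpehh, fraction,
                                         two_sided = TRUE)
    fp <- stats::setNames(vector("list", length(pops)), pops)
    for (pr in pairs) {
      tr <- xpehh_scan(haps[[pr[1]]], haps[[pr[2]]], map)
      tracks[[paste0("xpehh.", pr[1], "_vs_", pr[2])]] <- tr
      fl <- flag_outliers(tr, thresholds$xpehh)
      # positive score: selection in observed population; negative: reference
      fp[[pr[1]]] <- rbind(fp[[pr[1]]], fl[fl$direction == "upper",
                                           c("pos_bp", "score")])
      fp[[pr[2]]] <- rbind(fp[[pr[2]]], fl[fl$direction == "lower",
                                           c("pos_bp", "score")])
    }
    for (p in pops)
      regions[[paste0("xpehh.", p)]] <-
        build_regions(if (is.null(fp[[p]])) empty_flags() else fp[[p]],
                      extend_bp, chrom_length_bp, chrom = map$chromosome[1],
                      method = "xpehh", population = p)
    footprints$xpehh <- fp
  }

  if ("xpclr" %in% methods) {
    thresholds$xpclr <- autosomal_cutoff(autosome_scores$xpclr, fraction,
                                         two_sided = FALSE, min_scores = 50)
    fp <- stats::setNames(vector("list", length(pops)), pops)
    for (pr in pairs) for (d in 1:2) {
      obs <- pr[d]; ref <- pr[3 - d]
      tr <- xpclr_scan(haps[[obs]], haps[[ref]], map, xpclr_control)
      tracks[[paste0("xpclr.", obs, "_obs_", ref, "_ref")]] <- tr
      fl <- flag_outliers(tr$clr, thresholds$xpclr)
      if (nrow(fl) > 0)
        fp[[obs]] <- rbind(fp[[obs]],
                           data.frame(pos_bp = tr$grid_pos_bp[fl$index],
                                      score = fl$score))
    }
    for (p in pops)
      regions[[paste0("xpclr.", p)]] <-
        build_regions(if (is.null(fp[[p]])) empty_flags() else fp[[p]],
                      extend_bp, chrom_length_bp, chrom = map$chromosome[1],
                      method = "xpclr", population = p)
    footprints$xpclr <- fp
  }

  if ("fst" %in% methods) {
    reg_by_pop <- stats::setNames(vector("list", length(pops)), pops)
    for (pr in pairs) {
      cts <- combine_counts(count_alleles(haps[[pr[1]]]),
                            count_alleles(haps[[pr[2]]]))
      thr <- permutation_threshold(cts, "fst", n_perm = n_perm,
                                   alpha = alpha, seed = seed + 11L)
      thresholds[[paste0("fst.", pr[1], "_", pr[2])]] <- thr
      tr <- fst_posterior_track(cts, map, seed = seed + 13L)
      tracks[[paste0("fst.", pr[1], "_", pr[2])]] <- tr
      wt <- window_scan(map$pos_bp, tr$raw_score, chrom_length_bp, window_bp,
                        statistic = "max")
      wtracks[[paste0("fst.", pr[1], "_", pr[2])]] <- wt
      rg <- flag_windows(wt, thr, per_snp_scores = tr$raw_score,
                         per_snp_pos = map$pos_bp,
                         chrom = map$chromosome[1], method = "fst",
                         population = paste(pr, collapse = "_"))
      # an Fst region marks selection in both populations of the pair
      for (p in pr) reg_by_pop[[p]] <- rbind(reg_by_pop[[p]], rg)
    }
    for (p in pops) {
      rg <- reg_by_pop[[p]]
      if (is.null(rg)) rg <- empty_regions()
      rg <- rg[!duplicated(rg$start), , drop = FALSE]
      rg <- rg[order(rg$start), , drop = FALSE]
      if (nrow(rg) > 0) rg$population <- p
      class(rg) <- c("selection_regions", "data.frame")
      regions[[paste0("fst.", p)]] <- rg
    }
  }

  if ("ihs" %in% methods) {
    thresholds$ihs <- autosomal_cutoff(autosome_scores$ihs, fraction,
                                       two_sided = TRUE)
    for (p in pops) {
      tr <- ihs_scan(haps[[p]], map, min_maf = min_maf,
                     ancestral_fallback = TRUE)
      tracks[[paste0("ihs.", p)]] <- tr
      fl <- flag_outliers(tr, thresholds$ihs)
      regions[[paste0("ihs.", p)]] <-
        build_regions(fl[, c("pos_bp", "score"), drop = FALSE], extend_bp,
                      chrom_length_bp, chrom = map$chromosome[1],
                      method = "ihs", population = p)
    }
  }

  if ("tajd" %in% methods) {
    for (p in pops) {
      cts <- count_alleles(haps[[p]])
      n_hap <- nrow(haps[[p]]$haplotypes)
      thr <- permutation_threshold(cts, "tajimas_d", pos_bp = map$pos_bp,
                                   window_bp = window_bp,
                                   chrom_length_bp = chrom_length_bp,
                                   n_perm = n_perm, alpha = alpha,
                                   seed = seed + 17L)
      thresholds[[paste0("tajd.", p)]] <- thr
      wt <- window_scan(map$pos_bp, as.numeric(cts$x[1, ]), chrom_length_bp,
                        window_bp, statistic = "tajimas_d", n = n_hap)
      wtracks[[paste0("tajd.", p)]] <- wt
      regions[[paste0("tajd.", p)]] <-
        flag_windows(wt, thr, chrom = map$chromosome[1], method = "tajd",
                     population = p)
    }
  }

  overlap <- list()
  for (p in pops) {
    keys <- grep(paste0("\\.", p, "$"), names(regions), value = TRUE)
    if (length(keys) >= 2) {
      rl <- regions[keys]
      names(rl) <- sub("\\..*$", "", keys)
      overlap[[p]] <- overlap_matrix(rl)
    }
  }

  out <- structure(list(tracks = tracks, window_tracks = wtracks,
                        thresholds = thresholds, regions = regions,
                        footprints = footprints, overlap = overlap,
                        populations = pops, methods = methods, map = map,
                        config = list(chrom_length_bp = chrom_length_bp,
                                      window_bp = window_bp,
                                      extend_bp = extend_bp,
                                      fraction = fraction, alpha = alpha,
                                      n_perm = n_perm, min_maf = min_maf,
                                      seed = seed)),
                   class = "selscan")
  out
}

empty_flags <- function() data.frame(pos_bp = numeric(), score = numeric())

simulate_autosome_scores <- function(need, haps, sim_config, n_autosomes,
                                     xpclr_control, min_maf, seed) {
  out <- list()
  for (m in need) out[[m]] <- numeric()
  cfg <- sim_config
  cfg$sweep$enabled <- FALSE
  for (a in seq_len(n_autosomes)) {
    cfg$seed <- as.integer((seed + a * 1009L) %% .Machine$integer.max)
    sim <- simulate_sweep_data(cfg)
    if ("xpehh" %in% need && length(sim$haps) >= 2) {
      tr <- xpehh_scan(sim$haps[[1]], sim$haps[[2]], sim$map)
      out$xpehh <- c(out$xpehh, tr$std_score[!is.na(tr$std_score)])
    }
    if ("ihs" %in% need) {
      tr <- ihs_scan(sim$haps[[1]], sim$map, min_maf = min_maf,
                     ancestral_fallback = TRUE)
      out$ihs <- c(out$ihs, tr$std_score[!is.na(tr$std_score)])
    }
    if ("xpclr" %in% need && length(sim$haps) >= 2) {
      tr <- xpclr_scan(sim$haps[[1]], sim$haps[[2]], sim$map, xpclr_control)
      out$xpclr <- c(out$xpclr, tr$clr[!is.na(tr$clr)])
    }
  }
  out[need]
}

#' Summarize selection regions per method and population
#'
#' The region-report table: number of regions, average length in Mb, and
#' average number of chip SNPs per region, for every method x population
#' combination.
#'
#' @param regions Named list of `selection_regions` (names `method.pop`), or
#'   a `selscan` object.
#' @param map Optional [marker_map()]; when given, SNPs per region are counted
#'   from it (otherwise the stored `n_snps`, which for SNP-based methods
#'   counts flagged footprints only).
#' @return data.frame with `method`, `population`, `n_regions`,
#'   `mean_length_mb`, `mean_snps_per_region`, `total_length_mb`.
#' @export
summarize_regions <- function(regions, map = NULL) {
  if (inherits(regions, "selscan")) {
    if (is.null(map)) map <- regions$map
    regions <- regions$regions
  }
  rows <- lapply(names(regions), function(key) {
    rg <- regions[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    n <- nrow(rg)
    nsnp <- if (n == 0) NA_real_ else if (!is.null(map)) {
      mean(vapply(seq_len(n), function(k)
        sum(map$pos_bp > rg$start[k] & map$pos_bp <= rg$end[k]), numeric(1)))
    } else mean(rg$n_snps)
    data.frame(method = parts[1],
               population = paste(parts[-1], collapse = "."),
               n_regions = n,
               mean_length_mb = if (n == 0) 0 else
                 mean(rg$end - rg$start) / 1e6,
               mean_snps_per_region = nsnp,
               total_length_mb = sum(rg$end - rg$start) / 1e6,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract selection regions from a fitted scan
#'
#' @param object A `selscan` object.
#' @param method,population Optional filters.
#' @return One combined `selection_regions` data.frame.
#' @export
regions <- function(object, method = NULL, population = NULL) {
  stopifnot(inherits(object, "selscan"))
  keys <- names(object$regions)
  if (!is.null(method))
    keys <- keys[sub("\\..*$", "", keys) %in% method]
  if (!is.null(population))
    keys <- keys[sub("^[^.]*\\.", "", keys) %in% population]
  out <- do.call(rbind, object$regions[keys])
  if (is.null(out)) out <- empty_regions()
  rownames(out) <- NULL
  class(out) <- c("selection_regions", "data.frame")
  out
}

#' Cross-method overlap lengths (Mb) for one population
#'
#' @param object A `selscan` object.
#' @param population Population label (default: first).
#' @return Symmetric Mb matrix, see [overlap_matrix()].
#' @export
overlap_mb <- function(object, population = NULL) {
  stopifnot(inherits(object, "selscan"))
  if (is.null(population)) population <- object$populations[1]
  object$overlap[[population]]
}

#' @export
print.selscan <- function(x, ...) {
  cat("Selection footprint scan\n")
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  cat("  methods:    ", paste(x$methods, collapse = ", "), "\n")
  n_reg <- vapply(x$regions, nrow, integer(1))
  cat("  regions:    ", sum(n_reg), "across", length(n_reg),
      "method x population tracks\n")
  invisible(x)
}

#' Summary method for a selection scan
#'
#' @param object A `selscan` object.
#' @param ... Unused.
#' @return The region-report table of [summarize_regions()], printed with the
#'   threshold values.
#' @export
summary.selscan <- function(object, ...) {
  out <- list(regions = summarize_regions(object),
              thresholds = object$thresholds,
              overlap = object$overlap)
  class(out) <- "summary.selscan"
  out
}

#' @export
print.summary.selscan <- function(x, ...) {
  cat("Selection regions by method and population\n")
  print(x$regions, row.names = FALSE, digits = 4)
  cat("\nThresholds\n")
  for (nm in names(x$thresholds)) {
    t <- x$thresholds[[nm]]
    cat(sprintf("  %-18s lower=%s upper=%s (%s)\n", nm,
                if (is.null(t$lower)) "-" else format(t$lower, digits = 4),
                if (is.null(t$upper)) "-" else format(t$upper, digits = 4),
                t$provenance))
  }
  if (length(x$overlap) > 0) {
    cat("\nCross-method overlap (Mb)\n")
    for (p in names(x$overlap)) {
      cat(" ", p, "\n")
      print(round(x$overlap[[p]], 2))
    }
  }
  invisible(x)
}

#' Plot the score tracks of a selection scan
#'
#' One panel per stored track: per-SNP (or per-grid-point) scores along the
#' chromosome with the matching threshold drawn as dashed lines.
#'
#' @param x A `selscan` object.
#' @param tracks Names of tracks to plot (default: all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.selscan <- function(x, tracks = names(x$tracks), ...) {
  tracks <- intersect(tracks, names(x$tracks))
  if (length(tracks) == 0) stop("no tracks to plot")
  old <- graphics::par(mfrow = c(length(tracks), 1),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (nm in tracks) {
    tr <- x$tracks[[nm]]
    method <- sub("\\..*$", "", nm)
    if (inherits(tr, "xpclr_track")) {
      xs <- tr$grid_pos_bp / 1e6; ys <- tr$clr
    } else {
      xs <- tr$pos_bp / 1e6
      ys <- if (any(!is.na(tr$std_score))) tr$std_score else tr$raw_score
    }
    graphics::plot(xs, ys, pch = 16, cex = 0.5, xlab = "position (Mb)",
                   ylab = method, main = nm, ...)
    thr <- x$thresholds[[nm]]
    if (is.null(thr)) thr <- x$thresholds[[method]]
    if (!is.null(thr)) {
      if (!is.null(thr$upper)) graphics::abline(h = thr$upper, lty = 2)
      if (!is.null(thr$lower)) graphics::abline(h = thr$lower, lty = 2)
    }
  }
  invisible(x)
}
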