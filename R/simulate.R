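#' Configuration of the two-population sweep simulator
#'
#' Defaults emulate the structure of a 60K-chip X-chromosome dataset: about
#' 110 kb mean SNP spacing (180 SNPs on 20 Mb), ~34 diploid females sampled
#' per population (68 haplotypes), populations diverged by 300 generations of
#' drift, and chip-like ascertainment discarding ancestrally rare alleles.
#'
#' @param n_haplotypes_per_pop Breeding population size in haplotypes (200).
#' @param sample_size_per_pop Haplotypes sampled per population for analysis
#'   (68, i.e. 34 diploid females).
#' @param chrom_length_bp Chromosome length (20 Mb).
#' @param target_n_snps Number of chip SNPs drawn before ascertainment (180,
#'   ~110 kb spacing).
#' @param recomb_cm_per_mb Constant genetic-map rate (1 cM/Mb).
#' @param generations_split Generations of independent drift after the split
#'   (300).
#' @param n_populations Number of daughter populations (2 or 3).
#' @param sweep List: `enabled`, `position_bp`, `s` (fitness advantage per
#'   derived copy), `population` (index of the swept population), `min_freq`
#'   (conditioning floor for the final sweep-allele frequency, 0.8),
#'   `max_restarts`.
#' @param maf_ascertain Minimum minor allele frequency for a SNP to be kept
#'   on the "chip" (0.05; set to 0 for sequence-like, unascertained data).
#' @param ascertainment When `"panel"` (default) the chip is ascertained the
#'   way commercial arrays are: SNPs must reach `maf_ascertain` in the pooled
#'   present-day samples, after the populations have diverged, which keeps
#'   most delivered markers segregating within breeds (as observed in real
#'   chip data). `"ancestral"` instead ascertains on the ancestral pool;
#'   under strong drift most such markers fix within populations before
#'   sampling.
#' @param mutation_rate Expected allele flips per haplotype per generation
#'   spread over the SNP grid (0 by default; drift-only split phase).
#' @param ld_mix_per_cm Ancestral-pool LD control: carrier-permutation
#'   transpositions per haplotype per cM (larger = faster LD decay). The
#'   default 0.15 is calibrated so that the r-squared profile of the evolved
#'   populations matches chip data from livestock breeds (adjacent-SNP
#'   r-squared near 0.4 at ~110 kb spacing, ~0.2 at 1 Mb).
#' @param seed Integer seed; all stages are deterministic given it.
#' @return An object of class `sweep_sim_config`.
#' @export
sweep_sim_config <- function(n_haplotypes_per_pop = 200,
                             sample_size_per_pop = 68,
                             chrom_length_bp = 20e6,
                             target_n_snps = 180,
                             recomb_cm_per_mb = 1.0,
                             generations_split = 300,
                             n_populations = 2,
                             sweep = list(enabled = FALSE,
                                          position_bp = 10e6, s = 0.05,
                                          population = 1, min_freq = 0.8,
                                          max_restarts = 200),
                             maf_ascertain = 0.05,
                             ascertainment = c("panel", "ancestral"),
                             mutation_rate = 0,
                             ld_mix_per_cm = 0.15,
                             seed = 1L) {
  ascertainment <- match.arg(ascertainment)
  defaults <- list(enabled = FALSE, position_bp = chrom_length_bp / 2,
                   s = 0.05, population = 1, min_freq = 0.8,
                   max_restarts = 200)
  sweep <- utils::modifyList(defaults, sweep)
  stopifnot(n_haplotypes_per_pop > 0, sample_size_per_pop > 0,
            sample_size_per_pop <= n_haplotypes_per_pop,
            chrom_length_bp > 0, target_n_snps > 1, recomb_cm_per_mb >= 0,
            generations_split >= 0, n_populations >= 1,
            sweep$s >= 0, sweep$position_bp >= 1,
            sweep$position_bp <= chrom_length_bp,
            maf_ascertain >= 0, maf_ascertain < 0.5, mutation_rate >= 0)
  structure(list(n_haplotypes_per_pop = as.integer(n_haplotypes_per_pop),
                 sample_size_per_pop = as.integer(sample_size_per_pop),
                 chrom_length_bp = chrom_length_bp,
                 target_n_snps = as.integer(target_n_snps),
                 recomb_cm_per_mb = recomb_cm_per_mb,
                 generations_split = as.integer(generations_split),
                 n_populations = as.integer(n_populations),
                 sweep = sweep, maf_ascertain = maf_ascertain,
                 ascertainment = ascertainment,
                 mutation_rate = mutation_rate,
                 ld_mix_per_cm = ld_mix_per_cm, seed = as.integer(seed)),
            class = "sweep_sim_config")
}

#' Simulate the ancestral haplotype pool and chip marker map
#'
#' SNP positions are uniform on the chromosome; derived-allele pool counts
#' follow a neutral-like spectrum (probability proportional to 1/i for i
#' derived copies among the pool). Carriers of the derived allele are assigned
#' through a slowly mixing haplotype permutation: adjacent SNPs give their
#' derived alleles to nearly the same haplotypes, so linkage disequilibrium is
#' high nearby and decays with genetic distance. Chip-like ascertainment then
#' drops SNPs with pool MAF below `maf_ascertain`.
#'
#' @param config A [sweep_sim_config()].
#' @return List with `haps` (the ancestral [haplotype_set()], all SNPs
#'   oriented ancestral/derived) and `map` (a [marker_map()]). Under
#'   `"ancestral"` ascertainment exactly `target_n_snps` chip markers are
#'   delivered; under `"panel"` ascertainment a three-fold oversample of
#'   candidate sites is returned and the chip is cut down to the target
#'   after the split (see [simulate_sweep_data()]).
#' @export
simulate_ancestral <- function(config) {
  set.seed(config$seed)
  M <- config$n_haplotypes_per_pop
  panel <- config$ascertainment == "panel" && config$maf_ascertain > 0
  L <- if (panel) 3L * config$target_n_snps else config$target_n_snps
  pos <- sort(sample.int(config$chrom_length_bp, L))
  # neutral-like site-frequency spectrum on the pool; under ancestral
  # ascertainment it is truncated to sites with pool MAF >= maf_ascertain,
  # so the delivered marker count matches the chip target
  i_grid <- seq_len(M - 1)
  if (!panel)
    i_grid <- i_grid[pmin(i_grid, M - i_grid) / M >= config$maf_ascertain]
  counts <- sample(i_grid, L, replace = TRUE, prob = 1 / i_grid)
  # carrier assignment through a slowly mixing permutation
  perm <- sample.int(M)
  H <- matrix(0L, M, L)
  d_cm <- diff(pos) / 1e6 * config$recomb_cm_per_mb
  for (j in seq_len(L)) {
    if (j > 1) {
      n_swap <- stats::rpois(1, M * d_cm[j - 1] * config$ld_mix_per_cm)
      if (n_swap > 0) for (t in seq_len(min(n_swap, 10 * M))) {
        ij <- sample.int(M, 2)
        perm[ij] <- perm[rev(ij)]
      }
    }
    H[perm[seq_len(counts[j])], j] <- 1L
  }
  map <- marker_map(sprintf("snp%05d", seq_along(pos)), "X", pos,
                    cm_per_mb = config$recomb_cm_per_mb,
                    ancestral = "allele_a")
  list(haps = haplotype_set(H, population = "ancestral", snps = map$snp_id,
                            orientation = "ancestral_known", diploid = FALSE),
       map = map)
}

# One or more generations of Wright-Fisher resampling with recombination and
# optional per-copy selection at one site. H is the haplotype matrix; r_frac
# the per-interval recombination fraction. Returns the evolved matrix.
wf_evolve <- function(H, r_frac, generations, s = 0, sweep_col = NA,
                      mutation_rate = 0, stop_if_lost = FALSE) {
  N <- nrow(H); L <- ncol(H)
  for (g in seq_len(generations)) {
    w <- if (s > 0 && !is.na(sweep_col)) (1 + s)^H[, sweep_col] else NULL
    p1 <- sample.int(N, N, replace = TRUE, prob = w)
    p2 <- sample.int(N, N, replace = TRUE, prob = w)
    start <- stats::rbinom(N, 1, 0.5)
    if (L >= 2) {
      switches <- matrix(stats::runif(N * (L - 1)) <
                           matrix(r_frac, N, L - 1, byrow = TRUE), N, L - 1)
      # row-wise cumulative switch counts via one flattened cumsum
      z <- cumsum(rbind(start, t(switches)))
      zm <- matrix(z, nrow = L)
      off <- c(0, zm[L, -N])
      par <- t((zm - rep(off, each = L)) %% 2)
    } else {
      par <- matrix(start, N, 1)
    }
    H <- H[p1, , drop = FALSE] * (1L - par) + H[p2, , drop = FALSE] * par
    storage.mode(H) <- "integer"
    if (mutation_rate > 0) {
      n_mut <- stats::rpois(1, mutation_rate * N)
      if (n_mut > 0) {
        ij <- cbind(sample.int(N, n_mut, replace = TRUE),
                    sample.int(L, n_mut, replace = TRUE))
        H[ij] <- 1L - H[ij]
      }
    }
    if (stop_if_lost && !is.na(sweep_col) && sum(H[, sweep_col]) == 0L)
      return(structure(H, lost = TRUE))
  }
  H
}

recomb_fractions <- function(map) {
  d_cm <- diff(map$pos_cm)
  # Haldane map function; ~ d/100 Morgans for chip-scale distances
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' Evolve daughter populations independently from the ancestral pool
#'
#' Each daughter population starts as the full ancestral pool and undergoes
#' `generations_split` generations of Wright-Fisher resampling with
#' recombination (and optional mutation); drift accumulates divergence
#' between them.
#'
#' @param ancestral Output of [simulate_ancestral()].
#' @param config A [sweep_sim_config()].
#' @return List of [haplotype_set()]s, one per population (full pool size;
#'   subsample with [sample_haplotypes()]).
#' @export
evolve_split <- function(ancestral, config) {
  set.seed(config$seed + 1L)
  r_frac <- recomb_fractions(ancestral$map)
  lapply(seq_len(config$n_populations), function(k) {
    H <- wf_evolve(ancestral$haps$haplotypes, r_frac,
                   config$generations_split,
                   mutation_rate = config$mutation_rate)
    haplotype_set(H, population = paste0("pop", k),
                  snps = ancestral$map$snp_id,
                  orientation = "ancestral_known", diploid = FALSE)
  })
}

#' Evolve one population under a hard sweep
#'
#' Re-runs the forward phase for one population with the derived allele at
#' the sweep site receiving a multiplicative fitness advantage `(1 + s)` per
#' copy, conditioned on that allele reaching frequency `min_freq` by the end
#' (the run restarts otherwise, up to `max_restarts` times). The sweep site is
#' the chip SNP nearest `sweep$position_bp` that segregates in the starting
#' pool; if the nearest SNP is fixed ancestral, the next nearest segregating
#' SNP is taken.
#'
#' @param population A [haplotype_set()] giving the starting pool (normally
#'   the ancestral pool).
#' @param map The [marker_map()] aligned to it.
#' @param config A [sweep_sim_config()] with `sweep$enabled = TRUE`.
#' @return A [haplotype_set()] with attribute `sweep_site` (SNP index) and
#'   `sweep_freq` (final derived frequency at the site).
#' @export
impose_sweep <- function(population, map, config) {
  stopifnot(isTRUE(config$sweep$enabled))
  set.seed(config$seed + 2L)
  H0 <- population$haplotypes
  segregating <- colSums(H0) > 0 & colSums(H0) < nrow(H0)
  if (!any(segregating)) stop("no segregating site available for the sweep")
  ord <- order(abs(map$pos_bp - config$sweep$position_bp))
  sweep_col <- ord[segregating[ord]][1]
  r_frac <- recomb_fractions(map)
  for (try in seq_len(config$sweep$max_restarts)) {
    H <- wf_evolve(H0, r_frac, config$generations_split,
                   s = config$sweep$s, sweep_col = sweep_col,
                   mutation_rate = config$mutation_rate,
                   stop_if_lost = config$sweep$s > 0)
    if (isTRUE(attr(H, "lost"))) next
    freq <- mean(H[, sweep_col])
    if (config$sweep$s == 0 || freq >= config$sweep$min_freq) {
      out <- haplotype_set(H, population = population$population,
                           snps = map$snp_id,
                           orientation = "ancestral_known", diploid = FALSE)
      attr(out, "sweep_site") <- sweep_col
      attr(out, "sweep_freq") <- freq
      return(out)
    }
  }
  stop("sweep did not reach frequency ", config$sweep$min_freq, " in ",
       config$sweep$max_restarts, " restarts")
}

#' Subsample haplotypes from a population
#'
#' @param haps A [haplotype_set()].
#' @param n Number of haplotypes to draw without replacement.
#' @param seed Optional seed.
#' @return A [haplotype_set()] of `n` haplotypes.
#' @export
sample_haplotypes <- function(haps, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n <= nrow(haps$haplotypes))
  idx <- sample.int(nrow(haps$haplotypes), n)
  out <- haplotype_set(haps$haplotypes[idx, , drop = FALSE],
                       population = haps$population, snps = haps$snps,
                       orientation = haps$orientation, diploid = FALSE)
  for (a in c("sweep_site", "sweep_freq")) attr(out, a) <- attr(haps, a)
  out
}

#' Simulate a complete two- (or three-) population chip dataset
#'
#' Runs the full generator: ancestral pool, independent drift of the daughter
#' populations, optional hard sweep in one of them, and subsampling to the
#' analysis sample size.
#'
#' @param config A [sweep_sim_config()].
#' @return List with `haps` (list of sampled [haplotype_set()]s), `map`, and
#'   `truth` (seed, sweep site index/position/frequency if a sweep was run).
#' @export
simulate_sweep_data <- function(config = sweep_sim_config()) {
  anc <- simulate_ancestral(config)
  pops <- evolve_split(anc, config)
  truth <- list(seed = config$seed, sweep = config$sweep)
  if (isTRUE(config$sweep$enabled)) {
    k <- config$sweep$population
    pops[[k]] <- impose_sweep(anc$haps, anc$map, config)
    pops[[k]]$population <- paste0("pop", k)
    truth$sweep_site <- attr(pops[[k]], "sweep_site")
    truth$sweep_pos_bp <- anc$map$pos_bp[truth$sweep_site]
    truth$sweep_final_freq <- attr(pops[[k]], "sweep_freq")
  }
  set.seed(config$seed + 3L)
  haps <- lapply(pops, sample_haplotypes, n = config$sample_size_per_pop)
  map <- anc$map
  if (config$ascertainment == "panel" && config$maf_ascertain > 0) {
    # chip design: keep candidate SNPs common in the pooled present-day
    # panel, then thin evenly to the chip's marker count
    pooled <- colMeans(do.call(rbind, lapply(haps, function(h) h$haplotypes)))
    keep <- which(pmin(pooled, 1 - pooled) >= config$maf_ascertain)
    if (length(keep) > config$target_n_snps)
      keep <- keep[round(seq(1, length(keep),
                             length.out = config$target_n_snps))]
    sweep_id <- if (!is.null(truth$sweep_site)) map$snp_id[truth$sweep_site]
    map <- map[keep, , drop = FALSE]
    rownames(map) <- NULL
    class(map) <- c("marker_map", "data.frame")
    haps <- lapply(haps, subset_to_map, map = map)
    if (!is.null(truth$sweep_site))
      truth$sweep_site <- match(sweep_id, map$snp_id)  # NA if dropped
  }
  list(haps = haps, map = map, truth = truth)
}

#' Write a simulated dataset as phased VCF + map + truth JSON
#'
#' One minimal phased VCF (GT only, `0|1` coding, consecutive haplotype pairs
#' as individuals) per population, a PLINK-style extended map file, and a
#' truth JSON carrying the seed and sweep parameters so the run can be
#' reproduced byte-identically.
#'
#' @param hapsets List of [haplotype_set()]s (even haplotype counts).
#' @param map The shared [marker_map()].
#' @param outdir Output directory (created if absent).
#' @param truth List written as `truth.json`.
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(hapsets, map, outdir, truth = list()) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character()
  for (hs in hapsets) {
    path <- file.path(outdir, paste0(hs$population, ".vcf"))
    write_phased_vcf(hs, map, path)
    files <- c(files, path)
  }
  map_path <- file.path(outdir, "markers.map")
  utils::write.table(
    data.frame(map$chromosome, map$snp_id, map$pos_cm,
               format(map$pos_bp, scientific = FALSE, trim = TRUE),
               map$allele_a, map$allele_b, map$ancestral),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, map_path, truth_path))
}

write_phased_vcf <- function(haps, map, path) {
  h <- haps$haplotypes
  if (nrow(h) %% 2L != 0L) stop("need an even haplotype count to write VCF")
  n_ind <- nrow(h) / 2
  ids <- paste0(haps$population, "_", seq_len(n_ind))
  gt <- matrix(paste0(h[seq(1, nrow(h), 2), ], "|", h[seq(2, nrow(h), 2), ]),
               nrow = n_ind)
  header <- c("##fileformat=VCFv4.2",
              paste0("##contig=<ID=", map$chromosome[1], ">"),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(map)), function(j) {
    paste(c(map$chromosome[j],
            format(map$pos_bp[j], scientific = FALSE, trim = TRUE),
            map$snp_id[j], map$allele_a[j], map$allele_b[j], ".", "PASS",
            ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
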