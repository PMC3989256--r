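#' Construct a genotype table
#'
#' A genotype table holds diploid genotype calls for one population as counts
#' of the B (alternate) allele: 0, 1, 2 or `NA` for missing.
#'
#' @param calls Integer matrix, individuals in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param individuals Character vector of sample ids (row labels).
#' @param snps Character vector of marker ids (column labels).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, individuals = rownames(calls),
                           snps = colnames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(calls)))
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(calls)))
  stopifnot(nrow(calls) == length(individuals), ncol(calls) == length(snps))
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(individuals, snps)
  structure(list(individuals = individuals, snps = snps, calls = calls),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d SNPs (%.1f%% missing)\n",
              length(x$individuals), length(x$snps),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Construct a phased haplotype set
#'
#' Binary haplotype matrix for one population; no missing values (phased /
#' complete input contract). Alleles are coded 0/1; where the ancestral state
#' is known, 0 is ancestral and 1 derived.
#'
#' @param haplotypes Matrix in `{0,1}`, haplotypes in rows, SNPs in columns.
#' @param population Population label.
#' @param snps Marker ids (column labels).
#' @param orientation Per-SNP flag, `"ancestral_known"` or `"unknown"`.
#' @param diploid Logical; if `TRUE` (default) the haplotype count must be even.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(haplotypes, population = "pop",
                          snps = colnames(haplotypes),
                          orientation = "unknown", diploid = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L)))
    stop("haplotypes must be binary with no missing values")
  if (diploid && nrow(haplotypes) %% 2L != 0L)
    stop("diploid phased data must have an even number of haplotypes")
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(haplotypes)))
  orientation <- rep_len(orientation, ncol(haplotypes))
  if (!all(orientation %in% c("ancestral_known", "unknown")))
    stop("orientation must be 'ancestral_known' or 'unknown'")
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- snps
  structure(list(population = population, haplotypes = haplotypes,
                 snps = snps, orientation = orientation),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> population '%s': %d haplotypes x %d SNPs\n",
              x$population, nrow(x$haplotypes), ncol(x$haplotypes)))
  invisible(x)
}

#' Construct a marker map
#'
#' Per-SNP coordinates and alleles. Physical positions (`pos_bp`) are 1-based
#' and must be strictly increasing within a chromosome; genetic positions
#' (`pos_cm`) must be non-decreasing. If `pos_cm` is missing it is filled from
#' `pos_bp` with a constant rate (default 1 cM/Mb).
#'
#' @param snp_id,chromosome,pos_bp Required per-SNP columns.
#' @param pos_cm Genetic position in cM, or `NULL` to derive from `pos_bp`.
#' @param allele_a,allele_b Allele labels (A = reference/first, B = alternate).
#' @param ancestral One of `"allele_a"`, `"allele_b"`, `"unknown"` per SNP.
#' @param cm_per_mb Rate used when `pos_cm` is `NULL`.
#' @return A `data.frame` of class `marker_map`.
#' @export
marker_map <- function(snp_id, chromosome, pos_bp, pos_cm = NULL,
                       allele_a = "A", allele_b = "B", ancestral = "unknown",
                       cm_per_mb = 1.0) {
  n <- length(snp_id)
  chromosome <- rep_len(as.character(chromosome), n)
  pos_bp <- as.numeric(pos_bp)
  if (is.null(pos_cm)) pos_cm <- pos_bp / 1e6 * cm_per_mb
  map <- data.frame(snp_id = as.character(snp_id), chromosome = chromosome,
                    pos_bp = pos_bp, pos_cm = as.numeric(pos_cm),
                    allele_a = rep_len(as.character(allele_a), n),
                    allele_b = rep_len(as.character(allele_b), n),
                    ancestral = rep_len(as.character(ancestral), n),
                    stringsAsFactors = FALSE)
  if (!all(map$ancestral %in% c("allele_a", "allele_b", "unknown")))
    stop("ancestral must be 'allele_a', 'allele_b' or 'unknown'")
  for (chr in unique(map$chromosome)) {
    i <- map$chromosome == chr
    if (any(diff(map$pos_bp[i]) <= 0))
      stop("pos_bp must be strictly increasing within chromosome ", chr)
    if (any(diff(map$pos_cm[i]) < 0))
      stop("pos_cm must be non-decreasing within chromosome ", chr)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Read genotypes and a marker map from disk
#'
#' Supports phased VCF (via vcfR) and a whitespace-delimited haplotype text
#' format with one haplotype per row. Phased VCF input additionally yields a
#' [haplotype_set()]; an unphased VCF yields genotypes only, and requesting
#' haplotypes from it is an error.
#'
#' @param path Path to the genotype file.
#' @param format `"vcf"` or `"haps_text"`.
#' @param map For `haps_text`, a [marker_map()] or path to a map file read by
#'   [read_marker_map()]; ignored for VCF (the map comes from the VCF itself,
#'   with cM positions from `cm_per_mb`).
#' @param population Population label attached to the haplotype set.
#' @param require_phased For VCF: error if any genotype is unphased or missing
#'   when `TRUE`; otherwise haplotypes are returned only when possible.
#' @param cm_per_mb Constant genetic-map rate used when no cM map is supplied.
#' @return A list with elements `genotypes` ([genotype_table()]), `map`
#'   ([marker_map()]) and `haplotypes` ([haplotype_set()] or `NULL`).
#' @export
read_genotypes <- function(path, format = c("vcf", "haps_text"), map = NULL,
                           population = "pop", require_phased = FALSE,
                           cm_per_mb = 1.0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    read_genotypes_vcf(path, population, require_phased, cm_per_mb)
  } else {
    if (is.character(map)) map <- read_marker_map(map, cm_per_mb = cm_per_mb)
    if (is.null(map)) stop("haps_text input requires a marker map")
    read_genotypes_haps(path, map, population)
  }
}

read_genotypes_vcf <- function(path, population, require_phased, cm_per_mb) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  snp_id <- fix[, "ID"]
  snp_id[is.na(snp_id) | snp_id == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(snp_id) | snp_id == "."]
  map <- marker_map(snp_id, fix[, "CHROM"], as.numeric(fix[, "POS"]),
                    allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                    cm_per_mb = cm_per_mb)
  samples <- colnames(gt)
  n_snp <- nrow(gt)
  phased <- grepl("^[01]\\|[01]$", gt)
  missing <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  bad <- !phased & !missing & !grepl("^[01][/|][01]$", gt)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("cannot parse GT '%s' at record %d, sample %s",
                 gt[bad][1], idx[1], samples[idx[2]]))
  }
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  calls <- a1 + a2
  calls[missing] <- NA_integer_
  calls <- t(matrix(calls, nrow = n_snp, dimnames = list(map$snp_id, samples)))
  gtab <- genotype_table(calls, individuals = samples, snps = map$snp_id)
  haps <- NULL
  if (all(phased | FALSE) && !any(missing)) {
    hmat <- matrix(0L, nrow = 2L * length(samples), ncol = n_snp)
    hmat[seq(1, nrow(hmat), by = 2), ] <- t(matrix(a1, nrow = n_snp))
    hmat[seq(2, nrow(hmat), by = 2), ] <- t(matrix(a2, nrow = n_snp))
    haps <- haplotype_set(hmat, population = population, snps = map$snp_id)
  } else if (require_phased) {
    stop("VCF contains unphased or missing genotypes; phased complete input required")
  }
  list(genotypes = gtab, map = map, haplotypes = haps)
}

read_genotypes_haps <- function(path, map, population) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "\\s+")
  n_snp <- nrow(map)
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) != n_snp)
      stop(sprintf("line %d has %d fields, expected %d (marker map length)",
                   i, length(rows[[i]]), n_snp))
    if (!all(rows[[i]] %in% c("0", "1")))
      stop(sprintf("line %d contains a non-binary symbol '%s'",
                   i, setdiff(rows[[i]], c("0", "1"))[1]))
  }
  hmat <- matrix(as.integer(unlist(rows)), nrow = length(rows),
                 ncol = n_snp, byrow = TRUE)
  haps <- haplotype_set(hmat, population = population, snps = map$snp_id,
                        orientation = ifelse(map$ancestral == "unknown",
                                             "unknown", "ancestral_known"),
                        diploid = FALSE)
  gtab <- haplotypes_to_genotypes(haps)
  list(genotypes = gtab, map = map, haplotypes = haps)
}

#' Collapse a phased haplotype set to diploid genotype calls
#'
#' Consecutive haplotype pairs (1,2), (3,4), ... are taken as individuals.
#'
#' @param haps A [haplotype_set()]; the haplotype count must be even.
#' @return A [genotype_table()].
#' @export
haplotypes_to_genotypes <- function(haps) {
  h <- haps$haplotypes
  if (nrow(h) %% 2L != 0L) stop("odd haplotype count cannot form diploids")
  calls <- h[seq(1, nrow(h), by = 2), , drop = FALSE] +
    h[seq(2, nrow(h), by = 2), , drop = FALSE]
  genotype_table(calls,
                 individuals = paste0(haps$population, "_", seq_len(nrow(calls))),
                 snps = haps$snps)
}

#' Read a marker map file
#'
#' Whitespace/tab-delimited, 4 to 7 columns in PLINK `.map` order extended by
#' optional allele and ancestral columns:
#' `chrom, snp_id, pos_cm, pos_bp[, allele_a, allele_b, ancestral]`.
#' A `pos_cm` column of all zeros is treated as absent and filled at
#' `cm_per_mb`.
#'
#' @param path File path.
#' @param cm_per_mb Rate used when cM positions are absent or all zero.
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path, cm_per_mb = 1.0) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("marker map needs >= 4 columns (chrom id cM bp)")
  pos_cm <- as.numeric(tab[[3]])
  if (all(pos_cm == 0)) pos_cm <- NULL
  marker_map(snp_id = tab[[2]], chromosome = tab[[1]],
             pos_bp = as.numeric(tab[[4]]), pos_cm = pos_cm,
             allele_a = if (ncol(tab) >= 5) tab[[5]] else "A",
             allele_b = if (ncol(tab) >= 6) tab[[6]] else "B",
             ancestral = if (ncol(tab) >= 7) tab[[7]] else "unknown",
             cm_per_mb = cm_per_mb)
}

#' Intersect marker maps by SNP id
#'
#' Builds the common-SNP map used for population-pair statistics (XPEHH, Fst,
#' XPCLR): the intersection of all maps by `snp_id`, in position order of the
#' first map.
#'
#' @param maps A list of two or more [marker_map()] objects.
#' @return A [marker_map()] restricted to the shared SNPs.
#' @export
common_snps <- function(maps) {
  if (length(maps) < 2) stop("need at least two marker maps")
  ids <- Reduce(intersect, lapply(maps, function(m) m$snp_id))
  if (length(ids) == 0) stop("marker maps share no SNPs")
  out <- maps[[1]][maps[[1]]$snp_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Subset a haplotype set (and optionally a genotype table) to a marker map
#'
#' @param x A [haplotype_set()] or [genotype_table()].
#' @param map Target [marker_map()]; all its SNPs must be present in `x`.
#' @return `x` restricted to `map$snp_id`, in map order.
#' @export
subset_to_map <- function(x, map) {
  idx <- match(map$snp_id, x$snps)
  if (anyNA(idx)) stop("marker map contains SNPs absent from the data")
  if (inherits(x, "haplotype_set")) {
    haplotype_set(x$haplotypes[, idx, drop = FALSE], population = x$population,
                  snps = x$snps[idx], orientation = x$orientation[idx],
                  diploid = FALSE)
  } else if (inherits(x, "genotype_table")) {
    genotype_table(x$calls[, idx, drop = FALSE], individuals = x$individuals,
                   snps = x$snps[idx])
  } else stop("unsupported object")
}
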