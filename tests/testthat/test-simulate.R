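# Smaller-than-default configurations keep the simulator tests fast; the
# full default configuration is exercised by the acceptance suite.
small_cfg <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_haplotypes_per_pop = 60, sample_size_per_pop = 30,
         chrom_length_bp = 1e7, target_n_snps = 90,
         generations_split = 60, seed = seed),
    list(...))
  do.call(sweep_sim_config, args)
}

test_that("the ancestral pool is seed-deterministic with chip-like spacing", {
  cfg <- small_cfg(seed = 61)
  a1 <- simulate_ancestral(cfg)
  a2 <- simulate_ancestral(cfg)
  expect_identical(a1$haps$haplotypes, a2$haps$haplotypes)
  expect_identical(a1$map$pos_bp, a2$map$pos_bp)
  expect_true(all(a1$haps$haplotypes %in% 0:1))
  # ancestral-mode ascertainment delivers the target count and spacing
  cfg_a <- small_cfg(seed = 62, ascertainment = "ancestral")
  a3 <- simulate_ancestral(cfg_a)
  expect_equal(ncol(a3$haps$haplotypes), 90)
  expect_equal(mean(diff(a3$map$pos_bp)), 1e7 / 90, tolerance = 0.2)
  maf <- pmin(colMeans(a3$haps$haplotypes), 1 - colMeans(a3$haps$haplotypes))
  expect_true(all(maf >= 0.05))
})

test_that("linkage disequilibrium decays with distance in the ancestral pool", {
  r2_near <- c(); r2_far <- c()
  for (s in 1:8) {
    a <- simulate_ancestral(small_cfg(seed = 100 + s))
    H <- a$haps$haplotypes
    r2 <- suppressWarnings(stats::cor(H))^2
    d <- abs(outer(a$map$pos_bp, a$map$pos_bp, "-"))
    ut <- upper.tri(r2)
    r2_near <- c(r2_near, r2[ut & d < 3e5])
    r2_far <- c(r2_far, r2[ut & d > 5e6])
  }
  expect_gt(mean(r2_near, na.rm = TRUE), mean(r2_far, na.rm = TRUE))
  expect_gt(mean(r2_near, na.rm = TRUE), 0.1)
})

test_that("divergence grows with split time and is absent without drift", {
  fst_of <- function(gens, seed) {
    cfg <- small_cfg(seed = seed, generations_split = gens)
    sim <- simulate_sweep_data(cfg)
    p <- rbind(colMeans(sim$haps[[1]]$haplotypes),
               colMeans(sim$haps[[2]]$haplotypes))
    mean(fst_draw(p))
  }
  f0 <- vapply(1:5, function(s) fst_of(0, 200 + s), numeric(1))
  f60 <- vapply(1:5, function(s) fst_of(60, 300 + s), numeric(1))
  f240 <- vapply(1:5, function(s) fst_of(240, 400 + s), numeric(1))
  expect_lt(mean(f0), 0.02)         # same-pool resamples are undifferentiated
  expect_gt(mean(f60), mean(f0))
  expect_gt(mean(f240), mean(f60))  # drift accumulates
})

test_that("frequencies stay valid through the split phase", {
  sim <- simulate_sweep_data(small_cfg(seed = 71))
  for (h in sim$haps) {
    p <- colMeans(h$haplotypes)
    expect_true(all(p >= 0 & p <= 1))
    expect_true(all(h$haplotypes %in% 0:1))
  }
})

test_that("an imposed sweep reaches the conditioning frequency and raises local homozygosity", {
  hits <- 0
  for (s in 1:6) {
    cfg <- small_cfg(seed = 500 + s,
                     sweep = list(enabled = TRUE, s = 0.08, position_bp = 5e6))
    anc <- simulate_ancestral(cfg)
    sw <- impose_sweep(anc$haps, anc$map, cfg)
    site <- attr(sw, "sweep_site")
    expect_gte(attr(sw, "sweep_freq"), 0.8)
    ihh_site <- sweepscan:::ihh_for_allele(sw, anc$map, site, "all")$ihh
    probe <- unique(round(seq(3, ncol(sw$haplotypes) - 2, length.out = 12)))
    ihh_bg <- mean(vapply(probe, function(j)
      sweepscan:::ihh_for_allele(sw, anc$map, j, "all")$ihh, numeric(1)))
    if (ihh_site > ihh_bg) hits <- hits + 1
  }
  # haplotype homozygosity around the swept site beats the background mean
  # in most replicates
  expect_gte(hits, 4)
})

test_that("a zero selection coefficient leaves evolution neutral", {
  cfg <- small_cfg(seed = 81,
                   sweep = list(enabled = TRUE, s = 0, position_bp = 5e6))
  anc <- simulate_ancestral(cfg)
  sw <- impose_sweep(anc$haps, anc$map, cfg)
  # no conditioning applies at s = 0; the trajectory is plain drift
  expect_true(attr(sw, "sweep_freq") >= 0 && attr(sw, "sweep_freq") <= 1)
  p_anc <- colMeans(anc$haps$haplotypes)
  p_sw <- colMeans(sw$haplotypes)
  site <- attr(sw, "sweep_site")
  d <- abs(seq_along(p_anc) - site)
  # frequency change at the "sweep" site is drift-sized, not selection-sized
  expect_lt(abs(p_sw[site] - p_anc[site]),
            4 * sqrt(p_anc[site] * (1 - p_anc[site]) *
                       cfg$generations_split / cfg$n_haplotypes_per_pop) + 0.1)
})

test_that("fixtures round-trip through the VCF reader byte-identically", {
  cfg <- small_cfg(seed = 91, sample_size_per_pop = 30)
  sim <- simulate_sweep_data(cfg)
  outdir <- withr::local_tempdir()
  files <- write_fixture(sim$haps, sim$map, outdir, truth = sim$truth)
  vcf <- file.path(outdir, "pop1.vcf")
  expect_true(file.exists(vcf))
  back <- read_genotypes(vcf, "vcf", population = "pop1")
  expect_identical(unname(back$haplotypes$haplotypes),
                   unname(sim$haps[[1]]$haplotypes))
  expect_equal(back$map$pos_bp, sim$map$pos_bp)
  truth <- jsonlite::read_json(file.path(outdir, "truth.json"))
  expect_equal(truth$seed, cfg$seed)
  # rerunning the generator from the recorded seed reproduces the files
  sim2 <- simulate_sweep_data(cfg)
  outdir2 <- withr::local_tempdir()
  write_fixture(sim2$haps, sim2$map, outdir2, truth = sim2$truth)
  expect_identical(readLines(vcf), readLines(file.path(outdir2, "pop1.vcf")))
  # three-population configs give three VCFs and one shared map
  cfg3 <- small_cfg(seed = 92, n_populations = 3)
  sim3 <- simulate_sweep_data(cfg3)
  outdir3 <- withr::local_tempdir()
  write_fixture(sim3$haps, sim3$map, outdir3)
  expect_length(list.files(outdir3, pattern = "\\.vcf$"), 3)
  expect_length(list.files(outdir3, pattern = "\\.map$"), 1)
})

test_that("the full generator is deterministic end to end under a seed", {
  cfg <- small_cfg(seed = 95, sweep = list(enabled = TRUE, s = 0.08))
  s1 <- simulate_sweep_data(cfg)
  s2 <- simulate_sweep_data(cfg)
  expect_identical(s1$haps[[1]]$haplotypes, s2$haps[[1]]$haplotypes)
  expect_identical(s1$haps[[2]]$haplotypes, s2$haps[[2]]$haplotypes)
  expect_identical(s1$truth$sweep_pos_bp, s2$truth$sweep_pos_bp)
})
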