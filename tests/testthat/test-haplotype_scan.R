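test_that("ehh_at equals brute-force pair counting on stated examples", {
  # 4 carriers, extended haplotypes {00, 00, 01, 10}: one identical pair of 6
  h <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 1), c(1, 1, 0))
  hs <- haplotype_set(h, diploid = FALSE)
  expect_equal(ehh_at(hs, 1, 3, 1), 1 / 6)
  # all identical -> 1; all distinct -> 0
  hs_same <- haplotype_set(matrix(1L, 4, 3), diploid = FALSE)
  expect_equal(ehh_at(hs_same, 1, 3, 1), 1.0)
  h_dist <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  expect_equal(ehh_at(haplotype_set(h_dist, diploid = FALSE), 1, 3, 1), 0.0)
  # fewer than two carriers is undefined
  expect_true(is.na(ehh_at(hs, 1, 3, 0)))
})

test_that("ehh_at matches the enumeration oracle on random small instances", {
  set.seed(11)
  for (rep in 1:40) {
    n_hap <- sample(4:12, 1); n_snp <- sample(3:10, 1)
    h <- matrix(rbinom(n_hap * n_snp, 1, runif(1, 0.2, 0.8)), n_hap, n_snp)
    hs <- haplotype_set(h, diploid = FALSE)
    core <- sample(n_snp, 1); target <- sample(n_snp, 1)
    allele <- sample(0:1, 1)
    expect_equal(ehh_at(hs, core, target, allele),
                 oracle_ehh(h, core, target, allele))
  }
})

test_that("EHH curves start at 1, never increase, and honour stopping rules", {
  set.seed(5)
  fx <- random_hapset(16, 30, seed = 21)
  for (core in c(1, 10, 30)) for (al in list(0L, 1L, "all")) {
    cv <- ehh_curve(fx$haps, fx$map, core, al, side = "right",
                    truncation = 0.05)
    if (anyNA(cv$points$ehh)) next
    expect_equal(cv$points$ehh[1], 1.0)
    expect_true(all(diff(cv$points$ehh) <= 1e-12))
    expect_true(all(cv$points$ehh >= 0 & cv$points$ehh <= 1))
    if (cv$stop_reason == "truncated")
      expect_lt(utils::tail(cv$points$ehh, 1), 0.05)
  }
  # core at the chromosome end: left side has only the core point
  cv <- ehh_curve(fx$haps, fx$map, 1, "all", side = "left")
  expect_equal(nrow(cv$points), 1)
  expect_equal(cv$stop_reason, "chrom_end")
  # max_extend_cm stops the walk
  cv <- ehh_curve(fx$haps, fx$map, 15, "all", side = "right",
                  truncation = 0, max_extend_cm = 0.25)
  expect_equal(cv$stop_reason, "max_extend")
  expect_lte(max(cv$points$dist_cm), 0.25)
  # a fully homozygous population stays at EHH = 1 throughout
  hom <- haplotype_set(matrix(1L, 8, 30), snps = fx$map$snp_id,
                       diploid = FALSE)
  cv <- ehh_curve(hom, fx$map, 15, "all", side = "right")
  expect_true(all(cv$points$ehh == 1))
})

test_that("integrate_ihh is the trapezoid rule over both sides", {
  mk <- function(dist, ehh, side)
    structure(list(core_snp = "c", side = side,
                   points = data.frame(dist_cm = dist, ehh = ehh),
                   core_allele = "all", stop_reason = "truncated"),
              class = "ehh_curve")
  left <- mk(c(0, 0.1, 0.2), c(1, 0.5, 0), "left")
  right <- mk(0, 1, "right")
  expect_equal(integrate_ihh(left, right), 0.100)
  # both sides single-point -> 0
  expect_equal(integrate_ihh(mk(0, 1, "left"), mk(0, 1, "right")), 0)
  # doubling the cM gaps doubles the integral
  left2 <- mk(c(0, 0.2, 0.4), c(1, 0.5, 0), "left")
  expect_equal(integrate_ihh(left2, right), 2 * integrate_ihh(left, right))
})

test_that("xpehh_raw and ihs_raw follow the log-ratio and sign conventions", {
  expect_equal(xpehh_raw(0.2, 0.2), 0)
  expect_equal(xpehh_raw(0.2 * exp(1), 0.2), 1)
  expect_lt(xpehh_raw(0.1, 0.2), 0)   # selection in the reference population
  expect_true(is.na(xpehh_raw(0, 0.2)))
  expect_equal(ihs_raw(0.3, 0.3), 0)
  expect_lt(ihs_raw(0.1, 0.4), 0)     # long derived haplotype -> negative
  # antisymmetry under label swap / population swap
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 0.01, 5); b <- runif(1, 0.01, 5)
    expect_equal(xpehh_raw(a, b), -xpehh_raw(b, a))
    expect_equal(ihs_raw(a, b), -ihs_raw(b, a))
  }
})

test_that("standardization yields exact zero mean and unit sd within bins", {
  set.seed(9)
  x <- rnorm(500, mean = 2, sd = 3)
  z <- standardize_scores(x, mode = "global")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(z, as.numeric(scale(x)))
  f <- runif(500)
  zb <- standardize_scores(x, freq = f, mode = "freq_bins", bin_width = 0.1,
                           min_bin = 30)
  bins <- floor(f / 0.1)
  for (b in unique(bins)) {
    i <- bins == b
    if (sum(i) >= 30) {
      expect_equal(mean(zb[i]), 0, tolerance = 0.3)  # bins may have merged
    }
  }
  expect_equal(mean(zb), 0, tolerance = 0.05)
  # sparse bins merge instead of erroring; constant scores error
  expect_silent(standardize_scores(rnorm(50), freq = runif(50),
                                   mode = "freq_bins", min_bin = 20))
  expect_error(standardize_scores(rep(1, 30), mode = "global"),
               "zero variance")
})

test_that("scan tracks carry standardized scores with the expected moments", {
  fx <- random_hapset(40, 60, seed = 31)
  fx2 <- random_hapset(40, 60, seed = 32)
  tr <- xpehh_scan(fx$haps, fx2$haps, fx$map)
  ok <- !is.na(tr$std_score)
  expect_gt(sum(ok), 50)
  expect_equal(mean(tr$std_score[ok]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(tr$std_score[ok]), 1, tolerance = 1e-10)
  ti <- ihs_scan(fx$haps, fx$map)
  ok <- !is.na(ti$std_score)
  expect_gt(sum(ok), 20)
  expect_equal(mean(ti$std_score[ok]), 0, tolerance = 0.2)
})

test_that("iHS skips unknown-orientation SNPs unless the fallback is on", {
  fx <- random_hapset(20, 12, seed = 41)
  fx$haps$orientation[5] <- "unknown"
  tr <- ihs_scan(fx$haps, fx$map)
  expect_true(is.na(tr$raw_score[5]))
  expect_equal(tr$flag[5], "no_ancestral")
  expect_warning(tr2 <- ihs_scan(fx$haps, fx$map, ancestral_fallback = TRUE),
                 "fallback")
  expect_false(anyNA(tr2$raw_score[5]) &&
                 min(colMeans(fx$haps$haplotypes)[5],
                     1 - colMeans(fx$haps$haplotypes)[5]) >= 0.05)
})
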