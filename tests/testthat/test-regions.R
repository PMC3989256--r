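test_that("autosomal cutoff uses linear-interpolation quantiles", {
  thr <- autosomal_cutoff(1:100, fraction = 0.05, two_sided = FALSE)
  expect_equal(thr$upper, 95.05)
  expect_null(thr$lower)
  # two-sided cutoffs of a symmetric sample sit symmetric about the median
  x <- c(-(50:1), 1:50)
  thr2 <- autosomal_cutoff(x, fraction = 0.05, two_sided = TRUE)
  expect_equal(thr2$lower, -thr2$upper)
  # fraction 1 puts the one-sided threshold at the minimum
  thr3 <- autosomal_cutoff(1:200, fraction = 1)
  expect_equal(thr3$upper, 1)
  expect_error(autosomal_cutoff(1:50), "at least 100")
})

test_that("outlier flagging is strict and partitions XPEHH by sign", {
  thr <- autosomal_cutoff(1:100, 0.05, two_sided = TRUE)
  sc <- c(thr$upper, thr$upper + 1, thr$lower, thr$lower - 1, 50)
  fl <- flag_outliers(sc, thr)
  expect_equal(fl$index, c(2, 4))   # exact ties are not flagged
  expect_equal(fl$direction, c("upper", "lower"))
  # no exceedance -> empty set
  expect_equal(nrow(flag_outliers(rep(50, 10), thr)), 0)
  # signed partition on a track: + observed, - reference
  map <- marker_map(c("a", "b"), "X", c(1e6, 2e6))
  tr <- sweepscan:::score_track(map, c(2.5, -2.5), c(2.5, -2.5), "xpehh", "p")
  thr2 <- structure(list(lower = -2, upper = 2, provenance = "test"),
                    class = "sel_threshold")
  fl2 <- flag_outliers(tr, thr2)
  expect_equal(fl2$direction, c("upper", "lower"))
})

test_that("regions extend 400 kb, merge by overlap, and are idempotent", {
  r1 <- build_regions(data.frame(pos_bp = 1e7, score = 3), 400000)
  expect_equal(r1$start, 9600000)
  expect_equal(r1$end, 10400000)
  expect_equal(r1$end - r1$start, 800000)
  # two outliers 300 kb apart merge into one 1.1 Mb region
  r2 <- build_regions(data.frame(pos_bp = c(1e7, 1e7 + 3e5),
                                 score = c(2, -4)), 400000)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$end - r2$start, 1100000)
  expect_equal(r2$peak_score, -4)   # peak by |score|, sign kept
  # 900 kb apart stay separate
  r3 <- build_regions(c(1e7, 1e7 + 9e5), 400000)
  expect_equal(nrow(r3), 2)
  expect_true(all(r3$start[-1] >= r3$end[-nrow(r3)]))
  # book-ended intervals merge (800 kb apart exactly)
  r4 <- build_regions(c(1e7, 1e7 + 8e5), 400000)
  expect_equal(nrow(r4), 1)
  # idempotence on its own output: re-extending flagged peaks reproduces cover
  r5 <- build_regions(r2$peak_pos_bp, 400000)
  expect_true(all(r5$start >= r2$start & r5$end <= r2$end))
  # clipping at chromosome bounds
  r6 <- build_regions(2e5, 400000, chrom_length_bp = 1e6)
  expect_equal(c(r6$start, r6$end), c(0, 600000))
})

test_that("window flagging gives fixed-length unmerged regions", {
  wt <- window_scan(c(1e5, 5e5, 9e5, 17e5), c(0.1, 0.9, 0.95, 0.2),
                    chrom_length_bp = 2.4e6, window_bp = 8e5,
                    statistic = "max")
  thr <- structure(list(lower = NULL, upper = 0.8, provenance = "test"),
                   class = "sel_threshold")
  rg <- flag_windows(wt, thr, method = "fst")
  expect_equal(nrow(rg), 2)                       # adjacent windows unmerged
  expect_true(all(rg$end - rg$start == 8e5))      # fixed 800-kb length
  # per-SNP rule: window flagged iff it contains an exceeding SNP
  rg2 <- flag_windows(wt, thr, per_snp_scores = c(0.1, 0.9, 0.95, 0.2),
                      per_snp_pos = c(1e5, 5e5, 9e5, 17e5))
  expect_equal(rg2$start, c(0, 8e5))
  expect_equal(nrow(flag_windows(wt, structure(list(lower = NULL, upper = 2,
                                                    provenance = "t"),
                                               class = "sel_threshold"))), 0)
})

test_that("quantile values are empirical CDF ranks", {
  expect_equal(quantile_value(971, 1:1000), 0.971)
  expect_equal(quantile_value(1000, 1:1000), 1.0)
  ref <- 1:101
  expect_equal(quantile_value(51, ref), 51 / 101)  # middle of odd-sized ref
  expect_error(quantile_value(1, numeric(0)), "empty")
})

test_that("overlap matrix is symmetric with bounded off-diagonals", {
  mk <- function(start, end) {
    r <- data.frame(chrom = "X", start = start, end = end, method = "m",
                    population = "p", peak_score = NA, peak_pos_bp = NA,
                    n_snps = 0L)
    class(r) <- c("selection_regions", "data.frame"); r
  }
  a <- mk(0, 10e6); b <- mk(5e6, 12e6)
  m <- overlap_matrix(list(A = a, B = b))
  expect_equal(m["A", "B"], 5.0)
  expect_equal(m["A", "A"], 10.0)
  expect_equal(m["B", "B"], 7.0)
  expect_equal(m, t(m))
  # identical sets: off-diagonal equals diagonal; disjoint: zero
  m2 <- overlap_matrix(list(A = a, B = a))
  expect_equal(m2["A", "B"], m2["A", "A"])
  m3 <- overlap_matrix(list(A = mk(0, 1e6), B = mk(2e6, 3e6)))
  expect_equal(m3["A", "B"], 0)
  # off-diagonal never exceeds either diagonal
  set.seed(43)
  for (i in 1:5) {
    s1 <- sort(sample.int(2e7, 4)); s2 <- sort(sample.int(2e7, 4))
    m4 <- overlap_matrix(list(A = mk(s1[c(1, 3)], s1[c(2, 4)]),
                              B = mk(s2[c(1, 3)], s2[c(2, 4)])))
    expect_lte(m4["A", "B"], min(m4["A", "A"], m4["B", "B"]) + 1e-9)
  }
})

test_that("permutation thresholds are seed-deterministic and preserve the frequency multiset", {
  set.seed(47)
  x <- rbind(rbinom(60, 40, 0.5), rbinom(60, 40, 0.5))
  cts <- allele_counts(x, matrix(40, 2, 60))
  t1 <- permutation_threshold(cts, "fst", n_perm = 200, n_draws = 50, seed = 9)
  t2 <- permutation_threshold(cts, "fst", n_perm = 200, n_draws = 50, seed = 9)
  expect_identical(t1$upper, t2$upper)
  expect_equal(t1$provenance, "permutation")
  expect_equal(t1$n_null, 200 * 60)
  t3 <- permutation_threshold(cts, "fst", n_perm = 200, n_draws = 50, seed = 10)
  expect_false(identical(t1$upper, t3$upper))
  # Tajima's D permutation: two-sided by default, deterministic
  c1 <- allele_counts(matrix(rbinom(60, 30, 0.3), 1), matrix(30, 1, 60))
  td <- permutation_threshold(c1, "tajimas_d", pos_bp = (1:60) * 1e5,
                              n_perm = 150, seed = 3)
  expect_lt(td$lower, td$upper)
})

test_that("total flagged-region length shrinks as the cutoff rises", {
  set.seed(53)
  pos <- sort(sample.int(2e7, 300))
  score <- rnorm(300)
  lens <- vapply(c(0.5, 1, 1.5, 2), function(cut) {
    thr <- structure(list(lower = NULL, upper = cut, provenance = "t"),
                     class = "sel_threshold")
    fl <- flag_outliers(score, thr)
    rg <- build_regions(pos[fl$index], chrom_length_bp = 2e7)
    sum(rg$end - rg$start)
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})
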