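test_that("omega estimation recovers simulated binomial drift and scales with time", {
  set.seed(29)
  n_snp <- 2000
  drift_once <- function(p, omega) {
    # one round of binomial drift calibrated to the target variance scale
    n_eff <- round(1 / omega)
    rbinom(length(p), n_eff, p) / n_eff
  }
  p_ref <- runif(n_snp, 0.1, 0.9)
  p_obs <- drift_once(p_ref, 0.05)
  om <- estimate_omega(p_ref, p_obs)
  expect_equal(om, 0.05, tolerance = 0.2 * 0.05 / 0.05)  # within 20%
  expect_gt(om, 0.04); expect_lt(om, 0.06)
  # two successive drift rounds roughly double omega
  p_obs2 <- drift_once(drift_once(p_ref, 0.05), 0.05)
  om2 <- estimate_omega(p_ref, p_obs2)
  expect_equal(om2 / om, 2, tolerance = 0.25)
  # identical frequencies are degenerate
  expect_error(estimate_omega(p_ref, p_ref), "omega is zero")
  expect_error(estimate_omega(runif(50), runif(50)), "at least 100")
})

test_that("neutral log-likelihood has the stated limits and symmetries", {
  # omega -> 0 tends to the plain binomial likelihood
  expect_equal(neutral_loglik(7, 20, 0.35, 1e-8),
               dbinom(7, 20, 0.35, log = TRUE), tolerance = 1e-3)
  # mirror symmetry count <-> n - count, p_ref <-> 1 - p_ref
  for (cfg in list(c(3, 15, 0.2), c(10, 30, 0.7), c(0, 12, 0.45))) {
    expect_equal(neutral_loglik(cfg[1], cfg[2], cfg[3], 0.08),
                 neutral_loglik(cfg[2] - cfg[1], cfg[2], 1 - cfg[3], 0.08),
                 tolerance = 1e-10)
  }
  # quadrature self-convergence: doubling the grid changes little
  expect_equal(neutral_loglik(12, 40, 0.4, 0.1, n_quad = 201),
               neutral_loglik(12, 40, 0.4, 0.1, n_quad = 401),
               tolerance = 1e-4)
})

test_that("sweep log-likelihood embeds the neutral null and is boundary-driven at r = 0", {
  for (cfg in list(c(5, 20, 0.3), c(18, 20, 0.6), c(0, 20, 0.5))) {
    expect_equal(sweep_loglik(cfg[1], cfg[2], cfg[3], 0.05, s = 0, r_cm = 0.2),
                 neutral_loglik(cfg[1], cfg[2], cfg[3], 0.05))
  }
  # at r = 0 with strong selection only the boundary component remains
  ll_fix <- sweep_loglik(20, 20, 0.5, 0.05, s = 0.5, r_cm = 0)
  ll_mid <- sweep_loglik(10, 20, 0.5, 0.05, s = 0.5, r_cm = 0)
  expect_gt(ll_fix, ll_mid)
  expect_equal(exp(ll_fix), 0.5 * dbinom(20, 20, 0.99), tolerance = 1e-6)
})

test_that("sweep escape probability is monotone in distance and selection", {
  expect_equal(sweep_escape_prob(1, 0), 1)
  r <- seq(0, 2, by = 0.1)
  cc <- vapply(r, sweep_escape_prob, numeric(1), s = 0.05)
  expect_true(all(diff(cc) >= 0))
  s <- c(0.001, 0.01, 0.1, 0.5)
  cs <- vapply(s, function(si) sweep_escape_prob(0.5, si), numeric(1))
  expect_true(all(diff(cs) <= 0))
  expect_true(all(cc >= 0 & cc <= 1))
})

test_that("LD weights group correlated SNPs and sum to the group count", {
  set.seed(31)
  # 3 perfectly correlated SNPs + 2 independent ones
  base <- rbinom(40, 1, 0.5)
  h <- cbind(base, base, base, rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  hs <- haplotype_set(h, diploid = FALSE)
  w <- ld_weights(hs, 1:5, ld_r2_cutoff = 0.95)
  expect_equal(w[1:3], rep(1 / 3, 3))
  expect_equal(sum(w), 3)  # number of LD groups
  # mutually independent SNPs all get weight 1
  h2 <- matrix(rbinom(200 * 4, 1, 0.5), 200, 4)
  w2 <- ld_weights(haplotype_set(h2, diploid = FALSE), 1:4)
  expect_equal(w2, rep(1, 4))
})

test_that("window CLR is non-negative, zero for a null-only grid, and flip-invariant", {
  set.seed(37)
  model <- xpclr_model(omega = 0.05)
  p_ref <- runif(10, 0.2, 0.8)
  counts <- rbinom(10, 40, p_ref)
  r_cm <- abs(seq(-0.45, 0.45, length.out = 10))
  res <- xpclr_window(counts, 40, p_ref, r_cm, model)
  expect_gte(res$clr, 0)
  null_only <- xpclr_model(omega = 0.05, s_grid = 0)
  res0 <- xpclr_window(counts, 40, p_ref, r_cm, null_only)
  expect_equal(res0$clr, 0)
  expect_equal(res0$s_hat, 0)
  # global allele-label flip in both populations leaves the CLR unchanged
  res_f <- xpclr_window(40 - counts, 40, 1 - p_ref, r_cm, model)
  expect_equal(res_f$clr, res$clr, tolerance = 1e-8)
  # too few informative SNPs flags the window
  expect_true(is.na(xpclr_window(c(1, 2), 10, c(0.5, 0.5), c(0, 0.1),
                                 model)$clr))
})

test_that("the scan finds elevated CLR around a frequency-shifted block", {
  set.seed(41)
  n_hap <- 60; L <- 80
  p <- runif(L, 0.25, 0.75)
  ref <- matrix(rbinom(n_hap * L, 1, rep(p, each = n_hap)), n_hap, L)
  p_obs <- p; p_obs[35:45] <- 0.98   # near-fixed block in the observed pop
  obs <- matrix(rbinom(n_hap * L, 1, rep(p_obs, each = n_hap)), n_hap, L)
  map <- marker_map(paste0("s", 1:L), "X", (1:L) * 1e5)
  tr <- xpclr_scan(haplotype_set(obs, "obs", map$snp_id, diploid = FALSE),
                   haplotype_set(ref, "ref", map$snp_id, diploid = FALSE),
                   map, xpclr_model(omega = 0.02),
                   estimate_omega_from_data = FALSE)
  inside <- tr$grid_pos_bp >= 3.2e6 & tr$grid_pos_bp <= 4.8e6
  expect_gt(mean(tr$clr[inside], na.rm = TRUE),
            mean(tr$clr[!inside], na.rm = TRUE))
  expect_true(all(tr$clr >= 0, na.rm = TRUE))
})
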