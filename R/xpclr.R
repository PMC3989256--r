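#' Configuration of the cross-population composite-likelihood scan
#'
#' @param omega Drift intensity: variance scale of neutral frequency change
#'   between reference and observed population. Usually estimated with
#'   [estimate_omega()].
#' @param s_grid Candidate selection coefficients; must contain 0 (the neutral
#'   null is embedded in the alternative, so the CLR is never negative).
#' @param rho_scale Sweep-escape scaling constant; default `log(2 * N)` for
#'   `N = 100`.
#' @param window_cm Spacing of the scan grid in cM; SNPs within `window_cm`
#'   of a grid point (half-width, i.e. a window of `2 * window_cm`) enter its
#'   composite likelihood, so consecutive windows share half their span. At
#'   chip density (~110 kb spacing) this keeps enough SNPs per window for the
#'   composite likelihood to be defined.
#' @param max_snps_per_window Cap on SNPs entering one composite likelihood.
#' @param ld_r2_cutoff Pairs of SNPs above this r-squared (in the reference
#'   population) share a weight group.
#' @param n_quad Interior quadrature points for the drift integral.
#' @param boundary_eps Frequency offset of the boundary-concentrated sweep
#'   component (hitchhiking pushes frequencies to within `boundary_eps` of
#'   fixation).
#' @return An object of class `xpclr_model`.
#' @export
xpclr_model <- function(omega = 0.05,
                        s_grid = c(0, exp(seq(log(1e-4), log(0.5), length.out = 12))),
                        rho_scale = log(2 * 100), window_cm = 0.5,
                        max_snps_per_window = 100, ld_r2_cutoff = 0.95,
                        n_quad = 201, boundary_eps = 0.01) {
  stopifnot(omega > 0, 0 %in% s_grid, rho_scale > 0, window_cm > 0,
            max_snps_per_window >= 1, ld_r2_cutoff > 0, n_quad >= 11,
            boundary_eps > 0, boundary_eps < 0.5)
  structure(list(omega = omega, s_grid = sort(unique(s_grid)),
                 rho_scale = rho_scale, window_cm = window_cm,
                 max_snps_per_window = max_snps_per_window,
                 ld_r2_cutoff = ld_r2_cutoff, n_quad = n_quad,
                 boundary_eps = boundary_eps),
            class = "xpclr_model")
}

#' Estimate the neutral drift intensity omega
#'
#' Method-of-moments fit of `Var(p_obs - p_ref) = omega * p_ref * (1 - p_ref)`
#' over putatively neutral SNPs: `omega = sum(d^2) / sum(p_ref (1 - p_ref))`.
#'
#' @param ref_freqs,obs_freqs Allele frequencies in the reference and observed
#'   population at the same SNPs; only SNPs with `ref_freqs` strictly inside
#'   (0, 1) are informative.
#' @param min_snps Minimum number of informative SNPs (default 100).
#' @return The drift intensity (> 0).
#' @export
estimate_omega <- function(ref_freqs, obs_freqs, min_snps = 100) {
  stopifnot(length(ref_freqs) == length(obs_freqs))
  ok <- !is.na(ref_freqs) & !is.na(obs_freqs) &
    ref_freqs > 0 & ref_freqs < 1
  if (sum(ok) < min_snps)
    stop("need at least ", min_snps, " informative SNPs to estimate omega")
  d2 <- (obs_freqs[ok] - ref_freqs[ok])^2
  omega <- sum(d2) / sum(ref_freqs[ok] * (1 - ref_freqs[ok]))
  if (omega <= 0)
    stop("omega is zero: observed and reference frequencies are identical")
  omega
}

# Drift density of the observed frequency q given the reference frequency p:
# truncated normal centred at p with variance omega*p*(1-p), plus point
# masses at 0 and 1 absorbing the tails. Returns quadrature nodes, interior
# weights*density, and the two boundary masses.
drift_density <- function(p_ref, omega, n_quad) {
  sdv <- sqrt(omega * p_ref * (1 - p_ref))
  qs <- seq(0, 1, length.out = n_quad)
  h <- qs[2] - qs[1]
  if (sdv < 2 * h) {
    # narrower than the grid can resolve: degenerate at p_ref
    return(list(q = qs, w_dens = rep(0, n_quad), mass0 = 0, mass1 = 0,
                point = p_ref, point_mass = 1))
  }
  dens <- stats::dnorm(qs, mean = p_ref, sd = sdv)
  w <- c(h / 2, rep(h, n_quad - 2), h / 2)      # trapezoid weights
  mass0 <- stats::pnorm(0, mean = p_ref, sd = sdv)
  mass1 <- stats::pnorm(1, mean = p_ref, sd = sdv, lower.tail = FALSE)
  list(q = qs, w_dens = dens * w, mass0 = mass0, mass1 = mass1,
       point = p_ref, point_mass = 0)
}

#' Log-likelihood of an observed allele count under neutral drift
#'
#' `log integral Binomial(count | n, q) f_drift(q | p_ref, omega) dq`, where
#' the drift density is a truncated normal centred at the reference frequency
#' with variance `omega * p_ref * (1 - p_ref)` plus boundary point masses;
#' the integral uses fixed-grid trapezoidal quadrature.
#'
#' @param count Observed-population count of the allele, `0 <= count <= n`.
#' @param n Observed-population allele sample size.
#' @param p_ref Reference-population frequency in (0, 1).
#' @param omega Drift intensity.
#' @param n_quad Quadrature points (default 201).
#' @return Log-likelihood (finite; the integrand is bounded away from 0).
#' @export
neutral_loglik <- function(count, n, p_ref, omega, n_quad = 201) {
  stopifnot(count >= 0, count <= n, p_ref > 0, p_ref < 1, omega > 0)
  dd <- drift_density(p_ref, omega, n_quad)
  lik <- sum(stats::dbinom(count, n, dd$q) * dd$w_dens) +
    dd$mass0 * stats::dbinom(count, n, 0) +
    dd$mass1 * stats::dbinom(count, n, 1) +
    dd$point_mass * stats::dbinom(count, n, dd$point)
  log(max(lik, 1e-300))
}

#' Log-likelihood of an observed allele count under a hitchhiking sweep
#'
#' Two-component mixture: a lineage escapes the sweep with probability
#' `c = 1 - exp(-rho_scale * r / s)` and then follows the neutral drift
#' density; with probability `1 - c` it is dragged to near-fixation of the
#' hitchhiking allele class (boundary-concentrated component at
#' `1 - boundary_eps` or `boundary_eps`, weighted by the reference frequency
#' of each allele). `s = 0` forces `c = 1`, recovering [neutral_loglik()].
#'
#' @inheritParams neutral_loglik
#' @param s Selection coefficient (>= 0).
#' @param r_cm Genetic distance (cM) of the SNP from the putative sweep site.
#' @param rho_scale,boundary_eps See [xpclr_model()].
#' @return Log-likelihood.
#' @export
sweep_loglik <- function(count, n, p_ref, omega, s, r_cm,
                         rho_scale = log(200), n_quad = 201,
                         boundary_eps = 0.01) {
  stopifnot(s >= 0, r_cm >= 0)
  cc <- sweep_escape_prob(r_cm, s, rho_scale)
  ll_neutral <- neutral_loglik(count, n, p_ref, omega, n_quad)
  if (cc >= 1) return(ll_neutral)
  lik_boundary <- p_ref * stats::dbinom(count, n, 1 - boundary_eps) +
    (1 - p_ref) * stats::dbinom(count, n, boundary_eps)
  log(max(cc * exp(ll_neutral) + (1 - cc) * lik_boundary, 1e-300))
}

#' Probability that a lineage escapes a sweep by recombination
#'
#' `c = 1 - exp(-rho_scale * r / s)` with `r` the recombination distance in
#' Morgans (`r_cm / 100`): the chance that recombination during the sweep
#' moves a lineage off the selected background. Increases with distance,
#' decreases with the selection strength; `s = 0` gives `c = 1` (everything
#' escapes, i.e. neutrality). With the default `rho_scale = log(2N)` and
#' `s = 0.05` the characteristic footprint half-width is about 1 cM.
#'
#' @param r_cm Genetic distance in cM.
#' @param s Selection coefficient.
#' @param rho_scale Scaling constant.
#' @return Escape probability in `[0, 1]`.
#' @export
sweep_escape_prob <- function(r_cm, s, rho_scale = log(200)) {
  if (s <= 0) return(1)
  min(1, max(0, 1 - exp(-rho_scale * (r_cm / 100) / s)))
}

#' Linkage-disequilibrium weights for a window of SNPs
#'
#' SNPs whose pairwise r-squared (in the reference population) exceeds the
#' cutoff are placed in the same group (transitively); each SNP is weighted by
#' the reciprocal of its group size, so a block of perfectly correlated SNPs
#' contributes like a single SNP.
#'
#' @param haps_ref Reference-population [haplotype_set()].
#' @param window_snps Column indices of the window SNPs.
#' @param ld_r2_cutoff r-squared threshold (default 0.95).
#' @return Numeric weights in (0, 1], one per window SNP; they sum to the
#'   number of LD groups.
#' @export
ld_weights <- function(haps_ref, window_snps, ld_r2_cutoff = 0.95) {
  k <- length(window_snps)
  stopifnot(k >= 1)
  if (k == 1) return(1)
  h <- haps_ref$haplotypes[, window_snps, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(h))^2
  r2[is.na(r2)] <- 0
  adj <- r2 > ld_r2_cutoff
  diag(adj) <- TRUE
  # transitive closure: connected components via repeated neighbour expansion
  grp <- seq_len(k)
  repeat {
    new <- vapply(seq_len(k), function(i) min(grp[adj[i, ]]), numeric(1))
    if (all(new == grp)) break
    grp <- new
  }
  size <- table(grp)[as.character(grp)]
  1 / as.numeric(size)
}

#' Composite likelihood ratio for one scan window
#'
#' `CLR = 2 * max_s [ sum_i w_i ll_sweep(i; s) - sum_i w_i ll_neutral(i) ]`,
#' maximized over the selection-coefficient grid. Since the grid contains
#' `s = 0`, the CLR is never negative.
#'
#' @param counts_obs Observed-population allele counts at the window SNPs.
#' @param n_obs Observed-population allele sample size(s).
#' @param p_ref Reference-population frequencies at the window SNPs.
#' @param r_cm Genetic distances of the SNPs from the window centre.
#' @param model An [xpclr_model()].
#' @param weights LD weights (default all 1), see [ld_weights()].
#' @return list with `clr`, `s_hat` (argmax, 0 if neutral wins), `n_snps`.
#' @export
xpclr_window <- function(counts_obs, n_obs, p_ref, r_cm, model,
                         weights = rep(1, length(counts_obs))) {
  k <- length(counts_obs)
  stopifnot(length(p_ref) == k, length(r_cm) == k)
  n_obs <- rep_len(n_obs, k)
  ok <- p_ref > 0 & p_ref < 1
  if (sum(ok) < 3) return(list(clr = NA_real_, s_hat = NA_real_, n_snps = sum(ok)))
  ll0 <- vapply(which(ok), function(i)
    neutral_loglik(counts_obs[i], n_obs[i], p_ref[i], model$omega,
                   model$n_quad), numeric(1))
  base <- sum(weights[ok] * ll0)
  best <- -Inf; s_hat <- 0
  for (s in model$s_grid) {
    if (s == 0) { lls <- base }
    else {
      ll <- vapply(seq_along(which(ok)), function(ii) {
        i <- which(ok)[ii]
        cc <- sweep_escape_prob(r_cm[i], s, model$rho_scale)
        if (cc >= 1) return(ll0[ii])
        lb <- p_ref[i] * stats::dbinom(counts_obs[i], n_obs[i],
                                       1 - model$boundary_eps) +
          (1 - p_ref[i]) * stats::dbinom(counts_obs[i], n_obs[i],
                                         model$boundary_eps)
        log(max(cc * exp(ll0[ii]) + (1 - cc) * lb, 1e-300))
      }, numeric(1))
      lls <- sum(weights[ok] * ll)
    }
    if (lls > best) { best <- lls; s_hat <- s }
  }
  list(clr = max(2 * (best - base), 0), s_hat = s_hat, n_snps = sum(ok))
}

#' Cross-population composite-likelihood sweep scan
#'
#' Slides a grid of putative sweep positions along the chromosome (spacing
#' `model$window_cm`); at each grid point the SNPs within half a window on
#' each side (capped at `max_snps_per_window`, nearest first) enter a
#' composite likelihood contrasting hitchhiking against neutral drift, with
#' LD-based down-weighting computed in the reference population. The score is
#' reported for the observed population; scanning the reciprocal direction
#' requires a second run with the populations swapped.
#'
#' @param haps_obs,haps_ref [haplotype_set()]s over the same SNPs (the
#'   reference set also provides the LD weights). Alternatively `counts_obs`
#'   and `freqs_ref` may be supplied directly with `haps_ref = NULL` (then all
#'   weights are 1).
#' @param map A [marker_map()] aligned to the data.
#' @param model An [xpclr_model()]; if `omega` is `NULL` in `...` it is
#'   estimated from the data via [estimate_omega()].
#' @param estimate_omega_from_data Replace `model$omega` by the
#'   method-of-moments estimate (default `TRUE`).
#' @return A data.frame of class `xpclr_track`: `grid_pos_bp`, `grid_pos_cm`,
#'   `n_snps`, `clr`, `s_hat`, `flag`.
#' @export
xpclr_scan <- function(haps_obs, haps_ref, map, model = xpclr_model(),
                       estimate_omega_from_data = TRUE) {
  p_obs <- colMeans(haps_obs$haplotypes)
  p_ref <- colMeans(haps_ref$haplotypes)
  n_obs <- nrow(haps_obs$haplotypes)
  if (estimate_omega_from_data) {
    # on short simulated chromosomes fewer informative SNPs are accepted
    om <- try(estimate_omega(p_ref, p_obs, min_snps = 20), silent = TRUE)
    if (!inherits(om, "try-error")) model$omega <- om
    else warning("omega not estimable from data; keeping model$omega = ",
                 model$omega)
  }
  counts_obs <- round(p_obs * n_obs)
  grid_cm <- seq(min(map$pos_cm), max(map$pos_cm), by = model$window_cm)
  half <- model$window_cm
  out <- data.frame(grid_pos_bp = stats::approx(map$pos_cm, map$pos_bp,
                                                xout = grid_cm, rule = 2)$y,
                    grid_pos_cm = grid_cm, n_snps = 0L, clr = NA_real_,
                    s_hat = NA_real_, flag = "", stringsAsFactors = FALSE)
  for (g in seq_along(grid_cm)) {
    d <- abs(map$pos_cm - grid_cm[g])
    idx <- which(d <= half)
    if (length(idx) > model$max_snps_per_window)
      idx <- idx[order(d[idx])][seq_len(model$max_snps_per_window)]
    idx <- sort(idx)
    if (length(idx) < 3) { out$flag[g] <- "too_few_snps"; next }
    w <- ld_weights(haps_ref, idx, model$ld_r2_cutoff)
    res <- xpclr_window(counts_obs[idx], n_obs, p_ref[idx], d[idx], model,
                        weights = w)
    out$n_snps[g] <- res$n_snps
    out$clr[g] <- res$clr
    out$s_hat[g] <- res$s_hat
    if (is.na(res$clr)) out$flag[g] <- "too_few_informative"
  }
  attr(out, "model") <- model
  class(out) <- c("xpclr_track", "data.frame")
  out
}
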