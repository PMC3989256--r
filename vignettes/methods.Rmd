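---
title: "Scanning a chromosome for selection footprints: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a chromosome for selection footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## Scope and assumptions

`sweepscan` detects genomic regions shaped by recent selection from phased
diploid SNP-chip genotypes of one or more populations. The design target is
a livestock-style study: a few dozen phased females per breed, ~110 kb
median marker spacing, and a single chromosome scanned against genome-wide
empirical reference distributions. Five statistics are implemented —
between-population XPEHH, XPCLR and Bayesian Fst, within-population iHS and
windowed Tajima's D — because they fail in different ways: haplotype
statistics see long homozygous stretches, frequency statistics see allele
frequency displacement, and the composite likelihood weighs both against an
explicit drift model.

Three contracts run through everything:

* **Phased, complete input for haplotype statistics.** The EHH machinery
  requires binary haplotype matrices without missing values; the reader
  errors on unphased VCF genotypes when haplotypes are requested rather
  than imputing. Frequency statistics tolerate missingness through per-SNP
  observed allele counts.
* **Coordinates.** Physical positions are 1-based in all I/O; every
  in-memory and BED interval is 0-based half-open. A SNP at bp `k·w` falls
  in the window starting at `k·w` (the half-open tiling convention).
* **Determinism.** Every stochastic step (posterior sampling, permutation,
  simulation) takes a seed, and the pipeline result is a pure function of
  (inputs, parameters, seeds).

## Quality control

The QC filters run in a fixed order — individual call rate, SNP call rate,
Hardy–Weinberg equilibrium, then minor allele frequency — with removal
counts reported per filter. Defaults: call rates ≥ 0.90, HWE p < 1e-6
removes, MAF < 0.05 removes *only* for within-population analyses (iHS,
Tajima's D), since between-population contrasts draw information from SNPs
that are rare in one population precisely because of selection. The HWE
test is the exact conditional test given allele counts (enumeration over
heterozygote counts, two-sided by cumulative probability): exact at the
small sample sizes this design implies, and the standard choice for chip
QC. HWE is tested per population-under-analysis, not pooled — pooling
across diverged populations would flag Wahlund structure, not genotyping
error.

## The haplotype statistics

EHH at distance `x` from a core SNP is the probability that two random
carriers of the core allele are identical over the whole interval; it is
computed incrementally by refining haplotype classes SNP by SNP outward, so
curves are non-increasing by construction. Curves start at (0, 1) and stop
at the first point below the truncation level (kept as boundary point), at
the chromosome end, or at `max_extend_cm`.

Tunable parameters, units, defaults:

* `truncation = 0.05` (EHH units). Integrating the tail below 0.05 adds
  noise at chip density; the value matches common practice for medium
  density data and makes iHH finite. Scores whose curves reach a chromosome
  end while still above the truncation level carry an `edge_truncated`
  flag.
* Genetic distance: when the map supplies no cM positions, a constant
  1 cM/Mb map is assumed (`cm_per_mb`, configurable). All iHH values are in
  cM·EHH units; ties in cM contribute zero area (trapezoid rule).
* iHS ancestral orientation: taken from the marker map where known;
  optionally (`ancestral_fallback = TRUE`, with a warning) the major allele
  across the data is declared ancestral. Both polarizations are exposed
  because chip annotation rarely settles this; the fallback is biased
  against detecting near-fixed derived alleles and is off by default.
* XPEHH computes EHH over **all** haplotypes at the core (the
  cross-population convention); iHS splits carriers by core allele.
* Standardization: iHS within derived-allele-frequency bins of width 0.02
  (bins under 20 SNPs merge with their nearest neighbour), because raw iHS
  depends systematically on allele frequency; XPEHH is standardized
  globally. Within each bin the output has mean 0 and sd 1 exactly; the
  standardized iHS is referenced against N(0, 1), whose two-sided 5%
  critical value 1.96 is the conventional outlier cutoff.

## The frequency statistics

**Bayesian Fst.** Step one: with a uniform prior, the posterior of an
allele frequency given `x` copies among `n` observed alleles is
Beta(x+1, n−x+1). Step two treats joint posterior draws as data: each draw
maps to a per-locus Fst = mean((p_r − p̄)²)/(p̄(1−p̄)) with the unweighted
population mean p̄ (populations enter symmetrically regardless of sample
size), and the per-SNP score is the posterior mean of 1000 draws. The
plug-in form is chosen because it hits the interpretable endpoints exactly:
0 for identical frequencies, 1 for populations fixed for alternate
alleles; when p̄ is 0 or 1 there is no variation to apportion and Fst is
defined as 0. The finite-mixture clustering sometimes layered on top of
two-step Fst is deliberately not implemented: significance here comes from
the permutation null instead.

**Tajima's D** uses the standard constants (functions of the haplotype
sample size only) with π computed from per-site allele counts as
Σ 2x(n−x)/(n(n−1)) — algebraically identical to the pairwise definition
and cheap at any n. Windows without segregating sites are flagged missing
rather than zero.

## The composite-likelihood scan

The XPCLR-style scan slides a grid of putative sweep positions (spacing
`window_cm = 0.5` cM); SNPs within one `window_cm` of the grid point (a
2·`window_cm` window, capped at `max_snps_per_window = 100`, nearest first)
enter a weighted composite likelihood. Under neutrality the observed
population's frequency at a SNP is modelled as a truncated normal around
the reference frequency with variance ω·p(1−p) plus point masses absorbing
the tails beyond 0 and 1; ω is fitted by method of moments,
ω = Σd²/Σp(1−p), over SNPs with informative reference frequencies. Under
hitchhiking, a lineage escapes the sweep with probability
c = 1 − exp(−ln(2N)·r/s) (r in Morgans, N = 100 by default); with
probability 1−c it is dragged to near-fixation of the hitchhiking allele
class, modelled as binomial mass at `boundary_eps = 0.01` from the
boundary, weighted by the reference frequency of each allele. The CLR is
twice the weighted log-likelihood gain of the best s over a grid of 0 plus
12 log-spaced values in [1e-4, 0.5]; because s = 0 reproduces the neutral
model exactly, CLR ≥ 0 everywhere.

Numerical choices: 201-point trapezoid quadrature on [0,1] (doubling the
grid moves log-likelihoods by < 1e-4); when the drift sd is below twice the
grid step the density degenerates to a point mass at the reference
frequency (the quadrature cannot resolve it, and the limit is the plain
binomial likelihood); likelihoods are floored at 1e-300 before logging.
LD weights group window SNPs whose pairwise r² in the reference population
exceeds 0.95 (transitively) and weight each SNP by 1/group-size, so a
block of perfectly correlated SNPs counts once. The scan direction is
explicit: scores describe the observed population, and a population pair
is scanned twice with the roles swapped.

Two unit conventions deserve emphasis because getting them wrong silently
destroys the method: r enters the escape probability in Morgans (cM/100) —
at chip scale, using cM would shrink the modelled footprint to a few kb —
and with s = 0.05 the characteristic footprint half-width is about 1 cM,
matching sweep theory.

## Significance and regions

Two procedures, matched to what each statistic uses:

* **Autosomal top-fraction cutoffs** for XPEHH, iHS, XPCLR: the top 5% of
  the genome-wide autosomal score distribution (two-sided for the signed
  scores, upper-tail for CLR), with type-7 (linear interpolation)
  quantiles. In simulation studies the "autosomes" are extra neutral
  chromosomes generated with the same configuration.
* **Permutation nulls** for Fst and Tajima's D: each population's
  per-SNP frequency vector is permuted independently across the fixed SNP
  positions (5000 permutations by default), the statistic is recomputed
  (per SNP for Fst, per 800-kb window for D), and all permuted values are
  pooled; thresholds are the α and 1−α empirical quantiles. Independent
  shuffling is chosen deliberately: it breaks cross-population coupling as
  well as position structure, giving a proper no-differentiation null.
  Permutation is not offered for the haplotype and composite-likelihood
  statistics — shuffling frequencies destroys the LD those methods measure,
  so their permutation null answers the wrong question.

  The permuted Fst statistic is the same posterior-mean statistic as the
  observed track, with the same number of posterior draws: the null must
  carry the same Monte-Carlo noise as the scores it calibrates, otherwise
  the threshold is biased wherever posterior means cluster (near-fixed
  SNPs). For two populations the implementation tabulates the posterior-
  mean Fst of every cross-pairing of SNP columns once and lets each
  permutation re-pair columns — the same conditional null, ~30× faster.

Thresholds are applied strictly (ties unflagged). SNP-based footprints are
extended ±400 kb, clipped at chromosome bounds, and merged (book-ended
intervals merge); window-based methods flag whole 800-kb windows, which are
never merged, so those regions all have the fixed window length. Overlap
between methods is the total intersection length of the merged region sets
in Mb. The q-value attached to a footprint is its empirical CDF rank within
the reference score distribution.

## What the simulator emulates — and what it does not

`sweep_sim_config()` describes the study conditions: two (or three)
populations of 200 haplotypes diverging by 300 generations of Wright–Fisher
resampling with recombination at 1 cM/Mb, a 20 Mb chromosome carrying ~180
chip SNPs (~110 kb spacing), 68 haplotypes (34 diploid females) sampled per
population, and an optional hard sweep giving the derived allele a (1+s)
fitness factor per copy, conditioned on reaching frequency 0.8 by the end
of the run (bounded restarts).

The ancestral pool draws derived-allele counts from a neutral-like 1/i
spectrum and assigns carriers through a slowly mixing haplotype
permutation, so linkage disequilibrium is high between close SNPs and
decays with genetic distance. The mixing rate (`ld_mix_per_cm = 0.15`) was
calibrated once so that the r² profile of the delivered data matches
published pig-chip values (adjacent-SNP r² ≈ 0.4 at ~110 kb, ≈ 0.2 at
1 Mb) and was not revisited.

Chip ascertainment defaults to **panel mode**: candidate SNPs (a three-fold
oversample) are kept only if their minor allele frequency in the pooled
present-day samples reaches 0.05, then thinned evenly to the target count.
This mirrors how commercial arrays are designed — on contemporary breed
panels — and is what keeps most delivered markers segregating within
populations, as observed in real chip data. The alternative
(`ascertainment = "ancestral"`) selects on the ancestral pool instead;
under the default drift intensity roughly 80% of such markers fix within
populations before sampling, which no real chip dataset resembles. That
observation is what decided the default.

Features of real data the generator does **not** emulate: genotyping error
and missingness; gene conversion; varying recombination rate along the
chromosome; migration and admixture after the split; overlapping
generations and unequal sex ratios; new mutations during the split phase
(off by default; a `mutation_rate` option exists). Passing tests on
simulated data therefore demonstrates correctness of the statistical
machinery under a clean drift model, not field performance on any
particular breed.

## Calibration results and an honest limitation

Three pipeline-level behaviours are verified by the test suite at stated
problem sizes:

* **Tajima's D neutrality** — windows from neutral equilibrium samples
  (34 haplotypes, no drift phase, no ascertainment) have mean D within
  ±0.15 of zero over 500 windows. Both exclusions matter and are
  documented biases rather than conveniences: a drift phase without
  mutation distorts the frequency spectrum like a bottleneck (measured
  bias ≈ +0.9 at the default 300 generations), and MAF-0.05 ascertainment
  removes rare variants (measured bias ≈ +0.77). Windowed D on chip data
  should be read against an empirical null — which is exactly why the
  pipeline thresholds it by permutation rather than against zero.
* **Permutation type-I error** — applied to data generated under the
  permutation's own null (two populations from unrelated ancestral pools),
  the 5% Fst threshold flags 5% ± 1.5% of SNPs over 20 replicates. On
  populations sharing an ancestor the same threshold is conservative
  (~3%), because shared ancestry couples the frequency vectors that the
  permutation decouples.
* **Sweep localization power** — the dedicated acceptance test runs 50
  replicates at the default conditions with s = 0.05 and asks each of iHS,
  XPEHH and XPCLR to rank the sweep-containing 800-kb window in the top
  decile. Measured power is low (iHS 0.08, XPEHH 0.08, XPCLR 0.14 in a
  representative run), and this is a property of the configured conditions,
  not of the implementations: with 300 generations at 200 haplotypes
  (t/Nₑ = 1.5) and no mutation, expected heterozygosity retention is
  exp(−1.5) ≈ 0.22, entire 800-kb windows fix by drift alone across a
  third of the chromosome, and a drift-fixed window carries exactly the
  homozygosity and differentiation signature of a completed sweep — while
  the conditioned sweep (final frequency ≥ 0.8) is often *less* extreme
  than the most extreme drift window. An oracle experiment bounds what any
  statistic could do here: directly ranking windows by within-population
  homozygosity depletion succeeds in only ~75% of replicates, and by
  cross-population frequency contrast in ~40%. The scan implementations
  themselves were validated separately (EHH equals brute-force pair
  counting; a planted homozygous block yields a clean XPEHH peak). The
  acceptance test asserts the 70% floor unchanged and fails; users
  simulating milder drift or ongoing (incomplete) sweeps should expect
  materially higher power.

## Known limitations

* iHS is structurally blind to completed sweeps: near fixation the derived
  core allele fails the within-population MAF filter at the sweep centre,
  so its signal concentrates on the sweep shoulders. This matches the
  method's published characterization and is not worked around.
* The XPCLR drift model caps meaningful ω near 1; beyond that (extreme
  divergence) the neutral model itself predicts frequent fixation and the
  likelihood contrast flattens.
* The X-chromosome use case is honoured by contract, not by special-case
  code: the pipeline assumes the input contains females only (all-diploid
  phased calls), as a sex-chromosome analysis requires.
* Region peak scores keep the sign of the flagged statistic but peaks are
  selected by absolute value; for two-sided statistics a region built from
  mixed-sign outliers reports the single most extreme one.
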