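---
title: "Methods: selection scans and landscape-genetic dissection with selscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans and landscape-genetic dissection with selscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`selscape` implements the analytical core of a whole-genome climate-adaptation
scan for a coastal species sampled along a latitudinal sea-surface-temperature
(SST) gradient: windowed selection-signature statistics and their composite
score, positively-selected-region (PSR) and gene (PSG) calling,
genotype–environment association (GEA), bespoke geographic/climatic distance
construction, and a multivariable dissection of isolation by distance (IBD)
versus isolation by environment (IBE). A forward simulator generates every
input the pipeline reads, with planted truth for recovery experiments.

The package assumes three differentiated populations along the gradient; the
two extremes are called **BH** (northern, cold) and **BB** (southern, warm)
throughout, with **IM** in between. Population A in two-population statistics
is conventionally BH.

# Windowed selection statistics

All window statistics run on one shared grid: windows of `size` (default
50 kb) advanced by `step` (default 10 kb), anchored at position 1 of each
chromosome; a final partial window is kept when it is at least `step` long.

* **FST** — Weir & Cockerham's (1984) two-population variance components per
  SNP; windows aggregate by ratio of sums (`sum(a) / sum(a+b+c)`), which keeps
  the estimator unbiased under varying SNP density. Monomorphic SNPs
  contribute nothing. Small negative per-window values are possible and kept.
* **π and ω** — per-SNP diversity `2p(1-p)n/(n-1)` summed over the window and
  divided by the full window span; `ω = log2(π_A/π_B)`. Windows with zero
  diversity in either population have undefined ω and are excluded from
  percentile ranks (they carry no usable contrast, and a log of zero would
  otherwise dominate the tails).
* **Tajima's D** — the 1989 standardization computed from segregating sites
  and mean pairwise differences per window; undefined (NA) when a window has
  no segregating site.
* **Rsb** — per SNP, the site-EHH (EHHS) is the allele-frequency-weighted
  average of per-allele extended haplotype homozygosity, integrated
  (trapezoid, physical bp) away from the focal SNP until it decays below
  `cutoff` (default 0.05). Integration is in physical distance because no
  genetic map exists for the target species. `ln(iES_A/iES_B)` is
  standardized genome-wide; median centering is the default (robust to the
  sweep tail itself), mean centering is available. Standardization happens
  per SNP *before* window averaging, so a window mean is a mean of
  comparable z-like quantities.

## Composite selection score

Each statistic column (oriented so that larger = more selected; the pipeline
uses FST, |ω|, |Rsb|) is converted to fractional ranks `rank/(n+1)` with
average ranks on ties, probit-transformed, and averaged. The mean z is
rescaled by `sqrt(k)` so its null reference is standard normal — with k
independent rank-uniform statistics, `var(mean z) = 1/k`, and the rescaling
makes `p = 1 - pnorm(z̄√k)` calibrated (the Monte-Carlo check in the test
suite: type-I fraction 0.05 ± 0.01 at n = 2000 windows, k = 3, 200
replicates). `CSS = -log10(p)`.

## PSR/PSG calling

A window qualifies when FST, |ω| and |Rsb| all sit at or above their
genome-wide 95th percentiles (the percentile is computed genome-wide, not per
chromosome — the tails of interest are genome-level outliers). The side
assignment uses sign concordance: a sweep in population A lowers π_A (ω < 0)
and extends A haplotypes (Rsb > 0); the opposite signs mark B. Windows whose
signs disagree are discarded and counted — they are percentile-tail noise
without a coherent sweep interpretation. Qualifying windows of the same side
that overlap or abut merge into maximal regions (a configurable merge gap
defaults to 0). Genes whose bodies overlap a region by ≥ 1 bp (1-based
inclusive coordinates) are PSGs. CSS is reported alongside the three base
statistics but does not gate PSR calling.

# Genotype–environment association

Two deliberately different routes are intersected:

* **Covariance-corrected Bayes factors.** Per-site allele frequencies are
  standardized per SNP and whitened by `Ω^(-1/2)`, where Ω is the sample
  covariance of standardized frequencies across SNPs — the shared-drift
  structure. Per SNP, a linear model of whitened frequencies on the whitened,
  z-scored covariate is compared against an intercept-only model through the
  BIC approximation `BF = exp((BIC0 - BIC1)/2)`, reported in deciban
  (10·log10 BF). This is a deterministic, desk-scale stand-in for an MCMC
  covariate model with the same decision rule — decisive evidence means
  strictly `BF > 20 dB` — and the candidate-intersection step equally accepts
  an externally computed BF table.
* **RDA outliers.** Centered dosages are regressed on the covariates; the SVD
  of the fitted matrix gives the constrained axes; per-SNP loadings are
  z-standardized per axis and `sum z²` is referred to chi-square with one df
  per retained axis (default: as many axes as covariates). The default outlier
  cut is `p < 0.001`; this threshold is genuinely open in the source method
  descriptions and is exposed as `gea.rdaAlpha`.

Candidates are SNPs decisive in both routes; genes within 5 kb (inclusive) of
a candidate SNP are reported as temperature-associated genes.

# Geography and climate

* Great-circle distance uses the haversine form with Earth radius
  6371.393 km; the meridional ("latitudinal") distance is `2πR·Δlat/360`.
  "Distance along latitude" is read as the north–south meridional arc, the
  interpretation consistent with a latitudinal gradient design.
* Coastline distance is the shortest 8-connected path through water cells of
  a planar raster, axial steps costing one cell and diagonals √2 — a
  reproducible reading of a summed grid-diagonal path that respects coastal
  barriers (peninsulas, straits). Any locally length-preserving projection is
  adequate at the ~1000 km scale; the synthetic tests use a flat plane so no
  projection error enters. The generator's default raster cell is 10 km at a
  ~2000 km coastline; unit tests exercise the path arithmetic at 0.1 km.
* SST climatology: SST_max/SST_min are means over calendar years of the
  annual maximum/minimum daily value (mean-of-annual-extremes; the
  alternative overall-extreme reading is more noise-sensitive), SST_med the
  median of all daily values. Gridded sources should be averaged within the
  site's grid cell first; the package reads per-site daily CSV series.

# IBD/IBE dissection

Pairwise genetic distance between sites is Weir–Cockerham FST computed within
each chromosome (ratio of sums), averaged across chromosomes weighted by
polymorphic SNP count, then linearized as `FST/(1-FST)`.

* **Single-factor OLS** reports the standard Gaussian-likelihood fit
  (R², adjusted R², log-likelihood, `AIC = 2k - 2ll`, `BIC = k·ln(n) - 2ll`
  with k counting the error variance).
* **Regularized regression**: a cross-validated LASSO discards unimportant
  predictors, an elastic net with mixing 0.5 refits the survivors.
  Coefficient SE/t/p follow the post-selection OLS-refit convention; dropped
  predictors keep coefficient 0 and p = 1. Cross-validation folds are a
  deterministic function of the RNG state (set a seed for exact
  reproducibility).
* **GDM**: three order-2 I-spline basis functions per predictor with knots at
  the min/median/max of site values; `d = 1 - exp(-η)` with non-negative
  coefficients fitted by Gauss–Newton iterated non-negative least squares on
  the link scale (Δdeviance < 1e-8). The response is rescaled by
  `1/(1.01·max)` since `FST/(1-FST)` can exceed 1. Predictor importance is
  the mean % decrease in deviance explained under site-label permutations;
  significance is the fraction of permutations reaching the observed deviance
  explained. GDM predictors are site-level values (coastline arc position,
  latitude, SST summaries); the great-circle distance has no one-dimensional
  site coordinate and therefore does not enter the GDM (it remains in the
  OLS/RLS/commonality predictors).
* **Commonality analysis**: all-subsets R² decomposition into unique and
  common components, structure coefficients, Pratt measures, and Johnson's
  orthogonal-approximation relative weights (components sum to R² to 1e-8 by
  construction; asserted in tests). Because the C(S,2) pairs are not
  independent observations, the plain OLS p-values are reproduced *and*
  site-bootstrap percentile CIs are reported — the bootstrap unit is the
  site, and the pair table is rebuilt from each resample (resampling pairs
  would break exchangeability). Draws that leave too few distinct sites are
  rejected; with very few sites the CIs may be skipped with a warning.
* **PSR contrast**: per-pair FST is recomputed by ratio of sums over SNPs
  inside the PSRs and over SNPs outside, each division gets its own GDM, and
  spline maximum heights are compared side by side.

# The synthetic study system

`simConfig()` describes a one-dimensional stepping-stone chain of demes along
a synthetic coastline with monotone latitude. Neutral evolution: ancestral
frequencies Beta(0.8, 0.8) clamped to (0.02, 0.98), `T` generations of
binomial drift (2N draws) with symmetric nearest-neighbour migration `m`,
then sampled haplotypes copied from a per-deme pool of 2N haplotypes — pool
reuse creates background identity without explicit recombination tracking, a
transparent and seed-stable alternative to coalescent machinery that produces
exactly the rank-based signals the scan consumes.

Hard sweeps are planted by replacing a fraction `q0` of target-deme
haplotypes with copies of one core haplotype whose identity decays as
`exp(-d/r)` from the sweep center: diversity loss, frequency differentiation
and extended haplotype homozygosity all decay with distance, as in a real
sweep's footprint. Two planting modes exist: *block* sweeps put the full
`q0` into one extreme population (the cleanest conditions for testing
PSR calling and side assignment), while *environment-driven* sweeps
(`envDriven = TRUE`) grade the carrier fraction along the realized
winter-SST cline — the condition under which genetic distance inside
selected regions tracks temperature difference rather than geography, used
for the selected-vs-neutral GDM contrast. Environment-associated loci get final deme frequencies on
a latitudinal cline. Daily SST follows a seasonal sinusoid whose mean falls
and whose amplitude grows with latitude, so winter SST spreads far more
across sites than summer SST — the asymmetry of the north-west Pacific
margin that motivates using annual extremes as covariates; per-site offsets
add gradient-independent local variation so the three SST summaries are not
collinear.

Default scale: **12 demes × 5 diploid samples, 4 chromosomes × 5 Mb, 40,000
SNPs, 10 A-side + 10 B-side sweeps** (half-width 25 kb, `q0 = 0.9`,
`r = 50` kb), N = 50, m = 0.1, T = 150. Two sizing considerations fixed these
defaults: a 95th-percentile outlier rule needs neutral windows to dominate,
so 20 sweeps require ≥ ~2000 windows (20 Mb); and a GDM with 3 splines per
predictor needs more site pairs than parameters, so 12 sites (66 pairs)
rather than 6 (15). The full pipeline completes in ~2 minutes on one CPU.

What the generator does *not* emulate: recombination maps and LD decay with
genuine genealogies, site-frequency spectra from real demography (Tajima's D
magnitudes are therefore only sign-interpretable), sequencing error and
missingness, and selection acting through time (sweeps are planted on the
final state). Passing recovery tests therefore demonstrates the estimators
and decision rules, not robustness to those real-data complications.

The GEA and GDM recovery experiments in the tests and the acceptance script
use dedicated replicate conditions (12 demes × 10 samples, deme size 500 —
weak drift typical of large marine populations — for GEA; 66-pair GDM with
generating weights 0.7/0.3) so that the planted signal, not drift noise,
decides the outcome; sizes were fixed from power reasoning at design time.

# Numerical choices and degenerate inputs

* Missing genotypes are excluded pairwise per SNP in all frequency
  computations; missingness is reported by `show()`.
* LD pruning keeps the earlier-position SNP of a correlated pair and repeats
  passes until a fixed point, making it idempotent; monomorphic SNPs have
  undefined r² (treated as 0, never pruned). Per-population pruned sets are
  intersected for structure analyses.
* VCF/GFF coordinates are 1-based inclusive; all reported intervals are too;
  BED exports are 0-based half-open.
* Rank ties take average ranks (keeps probit z finite); a constant statistic
  column yields all-zero z with a warning.
* The NNLS intercept is also constrained non-negative; the GDM refuses
  constant predictors (dropped with a warning).
* Ω is symmetrized and ridge-regularized (`1e-8` of the spectral max) before
  whitening; exact collinearity between covariates is an error naming the
  pair.
* EHH treats a missing call as a third allele (conservative: it breaks
  homozygosity rather than inventing it).

# Known limitations

* The BIC Bayes factor is an approximation to the full MCMC treatment; its
  neutral tail at small site counts is heavier, so the strict 20 dB rule
  keeps some false positives that the intersection with RDA must remove.
* Rsb at chromosome edges integrates a truncated EHHS and is mildly deflated
  there.
* With unphased input, all haplotype-based statistics refuse to run rather
  than guess phase.
* The pair-level regressions inherit the non-independence of distance
  matrices; the permutation and site-bootstrap procedures are the honest
  uncertainty statements, the OLS p-values are reported for comparability.
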