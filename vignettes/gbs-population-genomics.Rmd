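---
title: "Methods: GBS locus delineation, SNP filtering, outlier scans, and population structure"
author: "gbspop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GBS population genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbspop)
```

`gbspop` implements the post-alignment half of a GBS population-genomics
study: everything from mapped-read positions and a called VCF to outlier
panels, F-statistics, and individual assignment. This vignette documents
the models, the tunable parameters, the numerical choices, and what the
simulation-based tests do and do not establish.

## The genotype model and the simulator

The simulator draws data from the Balding–Nichols island model. For each
locus an ancestral allele frequency $p$ is drawn uniformly on a
configurable minor-allele range (default 0.01–0.5, mirrored to $1-p$
with probability 1/2), and each population's frequency is

$$p_k \sim \mathrm{Beta}\!\left(p\,\frac{1-F}{F},\; (1-p)\,\frac{1-F}{F}\right),$$

which has mean $p$ and variance $F\,p(1-p)$. $F$ is the per-locus
differentiation parameter: `background_f` for neutral loci, `outlier_f`
for a planted fraction of loci standing in for selection targets.
Diploid genotypes are two binomial allele draws; an optional inbreeding
coefficient (default 0) lets a fraction of draws be identical by
descent. Missingness is completely at random, and per-call read depths
come from a negative binomial (mean 20, dispersion 5 by default). The
degenerate cases are defined explicitly: $F = 0$ copies the ancestral
frequency, $F = 1$ fixes each population by a Bernoulli draw.

What the generator emulates: a background differentiation level, a
planted outlier fraction, a skewed frequency spectrum with many rare
alleles, missing calls, and (separately) per-library read stacks with
variable depth and partially overlapping intervals. What it does not
emulate: linkage between loci, sequencing or genotyping error,
depth-dependent missingness, batch effects, and selfing by default —
so passing recovery tests demonstrate estimator correctness under the
island model, not robustness to those real-data features. The defaults
(2 populations × 50 diploids × 2000 loci) are the sizes used throughout
the recovery tests; the outlier-scan evaluations instead use a 7-region
× 20-individual design (n = 140), the shape of a typical multi-region
GBS survey, for the reason given under *Outlier scans* below.

Monomorphic simulated loci are deliberately retained in the output so
the downstream filters have something to remove.

## Locus delineation

Reads passing a mapping-quality threshold (default 20) and sharing a
start coordinate on a contig form a *stack*; stacks whose intervals
partially overlap are merged transitively into loci, so the final
catalog intervals are exactly the per-base coverage union (strand is
ignored: single-enzyme GBS reads from both strands interrogate the same
restriction site). Depth is then counted per library per locus, and
depth below `min_depth` (default 6) flags the locus *missing in that
library* without deleting it — completeness is a cross-library notion
and is evaluated later. Internal coordinates are 0-based half-open; GFF3
export converts to 1-based inclusive.

Library QC keeps libraries with at least `min_loci` (default 40 000)
present loci. Saturation curves subsample reads without replacement
(seeded), and the shared-loci curve ranks libraries by mapped-read count
— both support restriction-enzyme and library triage.

## The SNP filter cascade

Steps run in a fixed order, each a projection (applying it twice equals
applying it once), with a chained accounting report:

1. **Call rate** (default ≥ 80% of individuals called);
2. **Depth excess**: mean depth across called samples above an absolute
   ceiling or, by default, above the 99th percentile — high-depth loci
   typically collapse paralogs. The percentile default is a documented
   choice; there is no canonical value;
3. **HWE heterozygote excess**: exact test (samples pooled), removing
   loci with $p < 0.01$ *and* $H_o > H_e$. Heterozygote-deficit loci
   are kept: deficits arise from real differentiation (Wahlund effect)
   or partial fixation, whereas excess at a sequencing locus is the
   signature of collapsed paralogs. $H_e$ uses the unbiased
   small-sample form $2p(1-p)\cdot 2n/(2n-1)$;
4. **MAF** (default ≥ 1%), computed on called alleles only.

The order matters (a monomorphic, half-missing locus is removed by a
different step depending on order), which is why the report records the
order and the test suite asserts the order-sensitivity on a hand-built
toy.

The exact HWE p-value is the sum, over all heterozygote counts
compatible with the observed allele counts, of the probabilities of
configurations no more probable than the observed one — computed in log
space and verified against full enumeration for every table with
n ≤ 30.

The 1–5% MAF band gets a dedicated regional-distribution check: carriers
of the minor allele are counted per region and compared against region
sample sizes with a Pearson chi-square statistic. An even distribution
suggests the band is noise; an uneven one indicates low-frequency
alleles carry geographic signal and argues for the permissive 1%
threshold.

## Outlier scans

**PCA scan.** Genotypes are mean-imputed and scaled; a PCA is fitted on
an LD-thinned panel (greedy window thinning, defaults window 200 SNPs,
$r^2 > 0.1$, lower-MAF member dropped); every SNP — including thinned
ones, which are projected onto the fitted components — is regressed on
the $k$ retained PCs to give a z-score vector. The statistic is the
squared Mahalanobis distance of the z-vectors under a robust scatter:
a minimum-covariance-determinant estimate with the standard one-step
reweighting (classical covariance of the points inside the 97.5%
chi-square envelope times the hard-rejection consistency factor). The
reweighting matters: the raw MCD scatter is biased low in finite
samples, which would inflate every statistic and the realized FDR.
Under neutrality the statistic is $\chi^2_k$; the genomic inflation
factor (observed median over $\chi^2_k$ median) is reported but *not*
used for rescaling by default — with real background differentiation
the chi-square fit is typically better without it. MCD subsampling is
stochastic, so the scan seeds it locally (restoring the caller's RNG
state) to stay deterministic.

**FST scan.** Per-locus Weir–Cockerham θ *without* the finite-sample
correction terms ($a = (\bar n/n_c)s^2$,
$b = \bar p(1-\bar p) - s^2(r-1)/r - \bar h/4$, $c = \bar h/2$) is
scanned against a neutral null
$F_{ST} \sim (\bar F/\mathrm{df})\,\chi^2_{\mathrm{df}}$ fitted to the
central part of the distribution after trimming the lower and upper
tails. The fit is by *truncated* maximum likelihood — the density is
renormalized to the trim cut points — because a plain ML fit to trimmed
observations is biased by several percent even at a 5%/5% trim. Both
tail p-values are computed; high-FST outliers are flagged at
Benjamini–Hochberg q < 0.10. An `auto_trim` mode raises the upper trim
in 5% steps while every locus above the trim point is being flagged
(the signature of a null still contaminated by the outliers); the step
size is a choice, as only the idea of incrementally raising the trim is
given in the practice this follows.

**Consensus.** The neutral panel is the set of loci flagged by
*neither* scan; its dual, the consensus outlier set, is the loci
flagged by *both*. The package evaluates power and FDR on the
flagged-by-both set. The union is not a usable outlier set at a
controlled FDR: the chi-square(k) null of the PCA scan cannot absorb
the process variance of genuinely drifted neutral loci, so the union
inherits its liberality, while the FST scan's fitted null absorbs that
variance by construction.

**Why the scan evaluation uses 7 regions.** With 2 demes the realized
per-locus differentiation under the island model is approximately
$F\cdot\chi^2_1$, and the overlap between $0.05\,\chi^2_1$ and
$0.4\,\chi^2_1$ caps the power of *any* per-locus test near 25–30% at
FDR ≤ 0.2 — more samples do not help, because the binding constraint is
the process variance of the Beta draws, not sampling noise. With $r$
demes the realized differentiation concentrates (≈ $r-1$ df), and a
7 × 20 design reaches ~70% power at ~10% FDR for the same effect sizes.
The two-deme setting is still exercised for calibration (enrichment and
FDR control), just not for a power floor.

## Population structure

**Diversity.** Per region: $H_o$ (heterozygote fraction), unbiased
$H_e$, and rarefied allelic richness
$A_r = \sum_i [1 - \binom{2N-N_i}{g}/\binom{2N}{g}]$ at a rarefaction
size $g$ defaulting to twice the smallest region sample count.

**Nei distance.** $D = -\ln(J_{xy}/\sqrt{J_x J_y})$ with the gene
identities averaged over pairwise-complete loci; individual-level
"frequencies" are the dosage values {0, ½, 1}. Pairs with disjoint
alleles at every shared locus have infinite $D$; these are clamped to
twice the largest finite distance with a warning — a documented
convention, chosen over dropping the pair so that downstream AMOVA and
clustering keep their dimensions.

**AMOVA.** Distance-based, with
$SS_{total} = \sum_{i<j} d_{ij}^2/N$ and the within-group term summing
$\sum_{i<j \in g} d_{ij}^2 / n_g$; variance components come from the
expected mean squares with unequal group sizes
($n_0 = (N - \sum n_g^2/N)/(G-1)$). Significance is by permutation of
individuals among groups (default 100 permutations, matching common
practice for this analysis), one-sided on the between-group variance
component with add-one correction. Permutation ties count as
exceedances, so the p-value is exact under exchangeability.

**Pairwise θ.** Loci are combined as a ratio of summed components,
$\hat\theta = \sum_l a_l / \sum_l (a_l+b_l+c_l)$ — the standard
combination; bootstrap over loci (default 100) gives percentile 95%
CIs; the reported p is the bootstrap mass at or below zero, and
negative point estimates are clamped to zero *after* the CI is formed.
For genuinely panmictic pairs this produces the characteristic
"0.00 (p non-significant)" pattern, with p approaching 1 when the raw
estimate is negative.

**DAPC.** Mean-imputation, scaling, PCA to `n_pcs` (default 20,
mirroring common practice for datasets of this size), then canonical
discriminant analysis on the PC scores with at most $G-1$ axes.
Assignment probabilities come from the Gaussian model on the
discriminant space (group centroids, pooled within-group covariance);
an individual whose maximum-probability group differs from its origin
label is a putative migrant. Mean imputation before PCA is a documented
choice; with the low missingness typical after an 80% completeness
filter its effect is minor.

## Numerical choices and degenerate inputs

* HWE: monomorphic tables return p = 1; the observed configuration is
  included in the tail with a $1+10^{-12}$ relative tolerance so
  floating-point noise cannot drop it.
* BH: p-values are floored at machine epsilon before adjustment.
* WC components: loci with fewer than two populations carrying data, or
  monomorphic overall, are NA and excluded from multi-locus sums.
* Scaled-chi-square fit: Nelder–Mead on $(\log \mathrm{df}, \log \bar F)$,
  initialized from trimmed moments; zero-variance input is an error, as
  is a trimmed set smaller than 50 loci.
* PCA scan: zero-variance loci get p = 1; `k` must be below the sample
  count.
* Saturation subsampling is without replacement; fraction 0 yields the
  point (0, 0) by definition.

## Problem sizes in the test suite

The recovery tests run at 2 × 50 × 2000 loci (θ, CI coverage, migrant
detection), 7 × 20 × 2000 (outlier scans, AMOVA on structured data),
200 replicates × 100 permutations (AMOVA null calibration), 20 000 draws
(null-fit recovery), and an exhaustive sweep of all ~5 500 genotype
tables with n ≤ 30 (HWE). These sizes keep Monte-Carlo standard errors
well below the assertion tolerances while the full suite stays fast.

## Known limitations

* No linkage model in the simulator, so LD thinning is exercised only
  on chance correlations and planted duplicates.
* The AMOVA is single-level (no region/population hierarchy).
* The FST scan assumes a shared demographic null across loci; strong
  hierarchical structure would need the trim raised (or `auto_trim`).
* Individual-level Nei distances from dosages are noisy at low locus
  counts; the population-level variant is preferable below a few
  hundred SNPs.
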