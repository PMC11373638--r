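---
title: "Simulating and analyzing synthetic generations of an outcrossing crop"
author: "synpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing synthetic generations of an outcrossing crop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Commercial varieties of outcrossing perennial crops such as intermediate
wheatgrass are usually *synthetic* (SYN) populations: a handful of selected
parent clones are planted in an isolated crossing block (SYN0), their
open-pollinated seed is the SYN1 generation, and further panmictic seed
increases — with no selection at any step — give SYN2, SYN3, SYN4. Breeders
test an early generation and release a later one, so two questions matter:

1. How similar are successive SYN generations, genetically and in trait
   performance?
2. How many parents should found a synthetic so that additive genetic
   variance is preserved across the multiplication generations?

`synpop` answers both with a forward-in-time simulator of SYN advancement,
population-genetic summaries of genotyped generations, and ridge-regression
BLUP (RR-BLUP) genomic prediction. Everything runs on synthetic data built
by the package itself, so the full analysis is testable without any
external download.

## The simulation model

### State and inheritance

A population is a set of phased diploid genomes over mapped biallelic loci
(`haplotype_population`). Meiosis follows Haldane's model: per chromosome
the crossover count is Poisson with mean (map length in cM)/100, crossover
positions are uniform on the genetic map, there is no interference, and the
starting haplotype is a fair coin. `advance_generation()` implements one
panmictic seed increase: each of `n_crosses` crosses pairs two distinct
parents drawn uniformly (selfing excluded, a parent may serve in several
crosses), and each cross contributes `progeny_per_cross` offspring, each
the union of two independent meioses. No selection, mutation, or migration
enters anywhere; drift is the only force.

### Trait architecture

The trait is purely additive: `n_qtl` causative loci (default 1000) are
sampled uniformly from the loci segregating in the founder pool, raw
effects are standard normal, and the effects are rescaled so that the
variance of genetic values over the *full founder pool* equals the base
additive variance `v0` exactly; an intercept shifts the mean genetic value
to `target_mean` (default 1). Dominance, epistasis and genotype-by-
environment interaction are absent by design, so the additive variance
equals the total genetic variance at every step.

`v0` is not identified by the published summaries the package emulates; the
default `v0 = 0.3` puts the absolute variances on the scale reported for
such populations, and every scale-free output (realized heritability,
variance ratios, orderings, Tukey letters) is independent of it.

The error variance is calibrated **once**, on the founder pool:
`var_e = v0 (1 - h2) / h2`. It is *not* re-tuned per generation; the
target heritability is treated as a property of the trait, so realized
heritability drifts slightly as genetic variance drifts. Because SYN
variances sit a little below `v0` (the founder bottleneck removes
`~1/(2N)` of the variance), realized heritability runs slightly *below*
each input level; the acceptance suite checks it stays within 0.1 of the
input. Real founder panels carry linkage disequilibrium (LD) whose
recombination can release variance and push realized heritability the
other way; a linkage-equilibrium synthetic pool cannot show that effect.

### Two variance measures, and the drift law

Two related quantities are tracked:

- `estimate_variances()` returns the *sample variance of genetic values*
  of the individuals actually simulated — the machine twin of a reported
  variance table.
- `expected_additive_variance()` returns `sum(2 p (1-p) a^2)` over QTL:
  the variance the population would show at panmictic (Hardy-Weinberg,
  linkage) equilibrium given its current allele frequencies — the natural
  population-level variance of a panmictic SYN generation.

The classical neutral-drift recursion `E[var(t+1)] = var(t) (1 - 1/(2N))`
applies to the second measure, and the package's strongest oracle verifies
it for bottlenecks of N = 7 and N = 20 parents. The first measure shows an
additional transient worth knowing about: offspring of a *small* parent
panel mated without selfing have genotypic variance depressed by a further
`~1/(2N)` (the two alleles of an offspring are drawn from the parent panel
without replacement, which induces a small negative covariance). One more
round of panmixia among the many SYN1 individuals restores the equilibrium
value, so the genotypic variance *recovers* slightly from SYN1 to SYN2 and
is essentially flat afterwards. This is a property of the mating scheme,
not a numerical artifact.

### The founder-number experiment

`run_syn_experiment()` runs the full factorial: founder counts
7/10/15/20/25, input heritabilities 0.4/0.6/0.8, four generations, with
parents *and* QTL architecture resampled every iteration (so replicate
spread reflects founder and architecture sampling, as the reported
replicate SDs require). The desk-scale defaults are 100 crosses x 20
progeny and 25 iterations (~2.5 min on one core); the full published scale
(1000 x 100, 100 iterations) is reached by passing those values.

With a linkage-equilibrium founder pool the expected deficit of 7-parent
populations relative to 10+ parents is of order `v0 (1/13 - 1/19)` —
enough to rank 7 lowest in every generation, but small against the
replicate SD of a bottlenecked population (whose realized variance behaves
like a chi-square with roughly `2N` effective degrees of freedom). The
α = 0.001 Tukey separation of 7 from the larger founder counts therefore
needs either the full iteration count or founder panels whose relatedness
and LD amplify the bottleneck, as real breeding panels do. The acceptance
suite states the check at desk scale and reports the outcome as computed.

### Tukey HSD

`tukey_hsd()` is the conventional procedure: one-way ANOVA mean square
error, `HSD = q(1 - alpha, k, df) sqrt(MSE / n_h)` with `n_h` the harmonic
mean group size, and a compact letter display in which groups share a
letter exactly when their means differ by less than the HSD. `alpha =
0.001` is the default used throughout for generation and founder-count
comparisons. Zero within-group variance is flagged as degenerate rather
than silently producing letters.

## The synthetic-data generator

`generate_founder_pool()` emulates a GBS-genotyped breeding panel:

- 21 chromosomes, 649 SNPs each (a ~13.6k panel) by default; map length
  150 cM and 1e8 bp per chromosome — typical grass-genome scale; genetic
  positions follow physical positions linearly.
- Minor allele frequencies are drawn as `0.5 * Beta(a, b)` with `b` solved
  so the mean MAF is `target_maf` (default 0.22), an L-shaped spectrum
  like a filtered GBS panel.
- Haplotypes are drawn site-independently in Hardy-Weinberg proportions —
  no ancestral LD — so LD-based statistics see a clean null. The optional
  `ld_blocks` mode copies blocks of consecutive SNPs from a few ancestral
  haplotypes, planting strong local LD for the imputation and LD-decay
  analyses.

What the generator does *not* emulate: real GBS allele-depth errors,
polyploid dosage ambiguity (the hexaploid crop is genotyped and modelled
as diploid dosages throughout), selection footprints, family structure of
a real breeding cycle, and genome-wide LD decay profiles. Tests passing on
synthetic data therefore validate the algorithms and their contracts, not
field-data effect sizes.

`degrade_to_gbs()` masks entries of a complete dosage matrix (per-SNP and
per-individual rates compose), recording every masked position and its
true dosage so imputation accuracy is measurable. `generate_phenotypes()`
adds fixed year effects and Normal noise to genetic values, one record per
individual and year.

## Genotype QC and imputation

`filter_genotypes()` applies the standard GBS filters in a fixed order —
individuals by call rate (>= 0.80), then SNPs by missingness (<= 0.10),
then SNPs by minor allele frequency (>= 0.03) computed on the retained
individuals — and reports counts removed at each step. The order matters
and is part of the contract; filtering is idempotent.

`ld_knni_impute()` fills missing dosages by LD-kNN: for a missing cell the
`l` markers in highest r² with the target SNP (composite r² on unphased
dosages, pairwise-complete individuals — appropriate for unphased GBS
data) define a distance (mean per-site absolute dosage difference,
mutually missing sites ignored) from the focal individual to every
individual called at that SNP; the `k` nearest contribute a 1/distance-
weighted mean, rounded to an integer call. Defaults `l = 30`, `k = 10` are
common for the method. Numerical choices: a zero distance is treated as
1e-6 (an identical neighbor dominates but cannot produce division by
zero); ranking ties break by individual index, so results are
deterministic; a SNP with no usable LD markers falls back to the rounded
mean of its observed dosages; a SNP with no observations at all is left
missing and reported.

## Population-genetic summaries

- **Fst**: per-SNP Weir-Cockerham theta for a two-group contrast. The
  reported per-generation layout does not pin down the contrast; the
  adopted convention is each generation against the pooled remainder,
  summarized min/max/mean, with `others=` available for pairwise
  contrasts. Negative per-SNP estimates are retained — they are the
  estimator's behaviour near zero differentiation and the reported minima
  are indeed negative.
- **Nei's D** (1972): `-ln(Jxy / sqrt(Jx Jy))` accumulated over loci with
  calls in both groups; an identity of ~0 (opposite fixation) is reported
  as the numerical cap `-log(.Machine$double.eps)` (~36) with a warning.
- **Shannon's H** is computed per *individual* over its dosage
  proportions (via `vegan::diversity`), the only reading under which the
  reported per-group maxima sit at `ln(m)` for an m-SNP panel
  (`ln(13633) = 9.52`). Group summaries are min/max/mean over individuals.
- **PCA**: per-SNP mean imputation, then centered (unscaled) `prcomp` —
  the conventional treatment of dosage matrices.
- **LD decay**: composite r² for intra-chromosomal pairs within 1e7 bp,
  a `lowess` curve with span 0.3 (configurable) on r² versus distance, and
  the decay distance where the curve first crosses r² = 0.2 from above
  (linearly interpolated; 0 if it starts below, NA if it never crosses).

## Genomic prediction

`fit_rrblup()` fits `y = X beta + Z u + e` with year fixed effects (first
year as reference), marker effects `u ~ N(0, sigma2_u I)` and dosages
centered by training-set column means (the centering vector is stored and
re-applied to prediction targets). REML profiles the variance ratio
`lambda = sigma2_e / sigma2_u` via one eigendecomposition and a 1-D search
in `log(lambda)` over e^[-25, 25] at tolerance 1e-8. A numerical detail:
the projected matrix that is decomposed is `S (K + I) S` rather than
`S K S` — the shift separates the fixed-effect null space from the null
space of `K`, which matters when individuals have repeated records across
years (then `K` is rank-deficient and the two null spaces would otherwise
mix). `beta` and `u` solve the mixed-model equations at the optimum via
generalized least squares on `(K + lambda I)`; a dense mixed-model-
equation solve serves as an independent oracle in the tests.

`cross_validate()` repeats a random k-fold partition of individuals
(default 4 folds, i.e. 75/25 train/validation); predictive ability is the
Pearson correlation between validation GEBV and year-adjusted observed
means. Whether ability should be computed against raw or year-adjusted
records is not settled by the published description; year-adjusted was
chosen because the year effects are nuisance fixed effects estimated from
the training folds. `predict_populations()` averages predictions of
target generations over repeated fits on random 75% subsamples of the
training individuals (the reading adopted for "model replications") and
compares generations with `tukey_hsd()`; unphenotyped individuals receive
the average of the fitted year levels as their fixed part.

## Problem sizes used by the test suite

The suite runs the drift oracle on a 200-locus genome (4 chromosomes x 50
loci, 600 replicates per founder count), the founder-number factorial at
100 crosses x 20 progeny x 25 iterations on a 21 x 50-locus pool, the
cross-validation band on a 400-individual breeding-cycle panel with ~1000
markers (one round of random mating among 60 founders — chosen to emulate
the family structure of a real training population), and the imputation
benchmark on 40 x 120 block-LD matrices with 10% masking, 20 replicates.
These sizes were chosen so each check isolates its property at desk scale.

## Known limitations

- Diploid dosages throughout; the generator does not model polyploid
  inheritance even though the motivating crop is hexaploid.
- The founder generator's linkage-equilibrium default understates
  bottleneck effect sizes relative to real, related, LD-bearing breeding
  panels (see the founder-number discussion above); the `ld_blocks` mode
  plants local LD but not realistic genome-wide decay or relatedness.
- `v0` (hence all absolute variances) is a calibration choice.
- LD-kNN imputation recomputes the full marker r² matrix; fine for
  desk-scale panels, quadratic in SNP count for very large ones.
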