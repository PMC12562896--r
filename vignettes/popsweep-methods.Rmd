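---
title: "Methods: diversity, LD and selective-sweep scans in popsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, LD and selective-sweep scans in popsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popsweep implements the downstream-of-variant-calling portion of a
resequencing population-genomics study of structured livestock cohorts (the
motivating design is three sheep breeds with 90 ewes each): SNP filtering,
per-population diversity, LD decay, population structure, and a selective
sweep scan that intersects the upper tails of windowed FST and the
between-population diversity ratio. This vignette records the statistical
models, the defaults and why they were chosen, and the places where the
design was genuinely open.

## Filtering model

Four rules are applied in a fixed, logged order; each stage's report chains
into the next (`sites_out` of one equals `sites_in` of the next).

1. **Hard INFO filter.** A site is removed when any *present* metric
   violates QD < 2.0, FS > 60.0, MQ < 40.0, SOR > 3.0, MQRankSum < -12.5,
   or ReadPosRankSum < -8.0. The inequalities are strict: a site sitting
   exactly on a threshold passes, and an absent metric never triggers
   removal. These operators and values are the conventional GATK
   `VariantFiltration` set for hard-filtering SNPs.
2. **Cluster rule.** Any window of 5 consecutive bases containing more than
   2 SNPs disqualifies every SNP inside it (the "no more than 2 SNPs within
   5 bp" rule, with both window endpoints inclusive, matching SnpCluster
   semantics). The implementation scans consecutive SNP triples; an
   exhaustive base-by-base window oracle in the test suite pins this
   reading.
3. **Indel proximity.** A SNP within 5 bp (inclusive) of any record
   carrying an indel allele on the same chromosome is removed. Multiallelic
   pure-SNV records are excluded from the genotype matrix (the dosage
   coding and the diversity formulas assume biallelic sites) but do *not*
   enter the indel side list — only alleles longer than one base do.
4. **GQ masking.** Individual genotype calls with GQ < 20 are set to
   missing. This is a per-call mark, not a site filter: downstream
   statistics use population-local pairwise-complete data.

The order (hard, cluster, indel, GQ) is a package decision — the
constituent rules commute in their effect on which site survives all of
them except through the report bookkeeping — and is exposed only as the
fixed cascade of `filter_variants()` so reports stay comparable across
runs.

## Diversity statistics

All per-population statistics use the calls of that population only. A
global site call-rate floor (default 0.8) is applied once, before all
statistics, so the five summary columns describe the same site set.

With alt-allele frequency $p$, $q = 1 - p$, and $n$ called alleles at a
site:

* **Pn** — proportion of callable sites with within-population MAF > 0
  (the MAF floor is configurable; 0 means "any segregating site").
* **He** — Nei's plug-in expected heterozygosity $1 - p^2 - q^2$.
  No $2n/(2n-1)$ correction is applied.
* **Ho** — fraction of called diploids that are heterozygous.
* **Pi** — the unbiased average pairwise difference
  $c_{\mathrm{ref}} c_{\mathrm{alt}} / \binom{n}{2}$, i.e.
  $2pq \cdot n/(n-1)$. Averaged over SNP sites (not divided by genome
  length), which puts it on the same per-variant-site scale as He.
* **PIC** — $1 - (p^2 + q^2) - 2 p^2 q^2$, the biallelic reduction of the
  classic marker-informativeness index
  $1 - \sum_i p_i^2 - \sum_i \sum_{j>i} 2 p_i^2 p_j^2$.

The estimator split — plug-in He, unbiased Pi — makes
$\mathrm{Pi} \ge \mathrm{He}$ at every site, with equality only as
$n \to \infty$. Published three-breed tables of this kind show exactly
that ordering (Pi slightly above He in every breed), which is why this
pairing is the default; both conventions are simple one-line variants of
`pi_site()`/`het_exp_site()` if a user needs the other pairing.
`relative_difference(a, b)` implements the "a is $100 (b-a)/b$ percent
lower than b" convention, rounded to two decimals, and
`table1_report()` applies it to all population pairs.

## LD decay

$r^2$ is computed from unphased genotypes by maximum likelihood: with the
allele frequencies fixed by the genotype counts, the two-locus haplotype
distribution has one free parameter, and only the double heterozygote is
phase-ambiguous. The EM iteration (initialized at linkage equilibrium,
tolerance $10^{-8}$, max 1000 iterations) resolves it; with no double
heterozygotes the first step already equals direct counting. A grid search
over the free parameter serves as the independent oracle in the tests. The
composite (squared dosage correlation) estimator is available via
`method = "composite"` for PLINK-style compatibility.

$D' = D / D_{\max}$ uses $D_{\max} = \min(p_A q_B, q_A p_B)$ for $D > 0$
and $\min(p_A p_B, q_A q_B)$ for $D < 0$; $D = 0$ gives $D' = 0$. For
biallelic loci $r^2 \le D'^2$ always holds and is property-tested.

Defaults: pairs to 300 kb, 1 kb bins, within-population MAF floor 0.05.
None of these have a canonical value; they follow common practice for
livestock resequencing panels and are echoed in the output. LD is computed
within populations only — a pooled computation confounds structure with
linkage and is deliberately not offered.

## Population structure

PCA drops monomorphic and high-missingness (> 20%) sites, mean-imputes
the remaining missing dosages (equivalently, sets them to the centered
zero), centers at $2\hat p$ and by default applies Patterson scaling
$\sqrt{2 \hat p (1 - \hat p)}$. Variance explained is the eigenvalue share
of the total variance of the retained matrix, so it is non-increasing
across components by construction.

IBS distance is $1 - \text{(shared alleles)}/(2\,n_{\text{complete}})$
over pairwise-complete sites. The NJ tree uses the Saitou–Nei
agglomeration via ape; on additive (tree-metric) matrices it is exact,
which the tests verify by round-tripping random trees through their
path-length matrices. Negative branch lengths (possible on noisy
matrices) are clamped to zero in output with a count kept in the
`negative_branches` attribute. Model-based ancestry (ADMIXTURE-style) is
out of scope; the CLI documents the omission rather than silently lacking
it.

## Sweep scan

Windows are half-open `[start, end)` tilings from position 1 with
configurable size and step (defaults 100 kb / 100 kb; terminal windows are
truncated). Per window:

* **FST** — Weir–Cockerham (1984) variance components $a, b, c$ per site,
  combined as the ratio of sums $\sum a / \sum (a+b+c)$. Ratio-of-sums is
  the standard windowed form and is stable for low-SNP windows;
  windows with fewer than `min_snps` (default 3) usable sites are
  undefined.
* **θπ ratio** — window diversity (sum of per-site unbiased π over SNPs,
  divided by SNP count by default, or by span via `pi_mode = "per_bp"`) in
  a reference population divided by the target population, so high values
  mean diversity *loss* in the target. The orientation is a config axis,
  not an assumption.

Selection takes the empirical upper `q` quantile of each axis (ties
included) and intersects them. Windows with undefined FST or ratio are
excluded from both the quantile computation and selection; windows whose
target diversity is exactly zero (candidate complete sweeps) would make
the ratio infinite, so they are reported separately as `fixed_regions`
rather than being allowed to dominate the tail silently. Selected windows
merge into regions when overlapping or within `gap_tolerance` (default 0,
which merges touching step-tiled windows); regions carry peak statistics
and, given a GFF3, the IDs of genes whose intervals intersect them
(1-based inclusive interval overlap; BED output converts to 0-based
half-open).

The default `q = 1e-4` reads "top 0.01%" literally. Published scans of
this design report hundreds of surviving regions, which is hard to
reconcile with a literal 0.01% of any plausible window count — the
proportion may well mean 0.01 — so the quantile is an explicit,
always-echoed parameter rather than a hidden constant, and the validation
experiments choose `q` to match the expected tail size of the truth they
inject.

## The synthetic cohort generator

The simulator exists to give every statistic a truth-known validation
surface; it is first-class, tested code.

* **Differentiation** follows the Balding–Nichols model: ancestral
  frequency $p \sim \mathrm{Beta}(a, b)$ (default uniform), population
  frequency $p_k \sim \mathrm{Beta}(p(1-F_k)/F_k,\, (1-p)(1-F_k)/F_k)$,
  with $F_k = 0$ handled as the exact copy case. Its closed-form expected
  differentiation makes FST recovery a sharp acceptance check: two
  populations at $F = 0.10$ with 90 diploids each and 10,000 sites give a
  genome-median windowed Weir–Cockerham FST within ±0.015 of 0.10.
* **Ascertainment**: ancestral MAF is floored at 0.05 by default,
  emulating the discovery bias of a resequencing SNP panel; this is why
  simulated He sits near 0.35 rather than the ~0.26 of real ovine panels
  (real panels carry a rare-allele tail the generator deliberately does
  not model).
* **Sweeps** are injected as a monotone push of the target population's
  frequencies toward the nearest fixation boundary:
  $p' = p(1-s)$ for $p < 0.5$, $p' = p + s(1-p)$ otherwise, with
  intensity $s \in (0, 1]$. This is the identity as $s \to 0$ and full
  fixation at $s = 1$. (A power-transform convention $p^{1/s}$ was
  considered and rejected: it does not have the identity limit.) The
  transform creates exactly the localized diversity deficit and inflated
  differentiation the scan detects, deterministically given the seed;
  forward-time selection would add realism the validation does not need.
* **Genotypes** are independent Binomial(2, $p_k$) draws
  (Hardy–Weinberg within populations) with uniform per-call missingness
  and per-call GQ from a two-component model (a small `low_gq_rate`
  fraction below 20).
* **INFO artifacts**: each site is labeled clean or artifact; clean sites
  draw every metric from ranges that strictly pass the hard filter,
  artifact sites draw one randomly chosen metric from beyond its
  threshold. Filter sensitivity/specificity against the label is exact by
  construction — which is precisely what makes the filter tests sharp and
  is a deliberate idealization of real INFO-field noise.
* **Linkage**: Balding–Nichols sites are independent, so LD-decay behavior
  is validated with a separate founder-haplotype mosaic generator
  (`simulate_ld_cohort()`): haplotypes copy from a founder pool of size
  $K$ with a per-base switch probability. Small $K$ is a drift/small-$N_e$
  proxy: it raises $r^2$ at all distances and slows its relative decay,
  reproducing the qualitative fast/slow decay ordering between
  high-diversity and drifted populations.

What passing these tests does *not* show: robustness to realistic
recombination maps, demography beyond star divergence, allele-frequency
spectra with rare-variant tails, linked selection, or sequencing-error
genotype miscalls. Those are listed limitations, not covered claims.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive (VCF convention); windows and regions
  are half-open `[start, end)`; BED output is 0-based half-open.
* Quantiles use R's default type-7 empirical quantile; selection uses
  `>=`, so ties at the threshold are all included.
* Monomorphic sites: FST components are undefined (no allelic variance to
  partition) and such sites drop out of window sums; diversity statistics
  count them as zero-diversity callable sites.
* EM guards: zero denominators in the double-heterozygote weight fall back
  to 1/2; pairs with a monomorphic locus return `NA` r².
* NJ ties break deterministically inside ape; negative branch lengths are
  clamped in output and flagged.
* All randomness flows from a single integer seed per simulation config;
  identical configs are byte-identical, which the manifest's config hash
  and the determinism tests rely on.

## Problem sizes used in validation

The test and acceptance runs are dimensioned for a single CPU: FST
recovery uses 2 × 90 diploids × 10,000 sites × 5 seeds; sweep recovery
uses 20 replicates of 2 × 60 diploids × 10,000 sites over a 20 Mb
chromosome (a 2 Mb sweep = 20 of 200 windows, hence the validation
quantile `q = 0.10` matched to the tail size); structure checks use
3 × 90 diploids × 3,000 sites. These sizes give stable statistics (the
acceptance quantities move by well under their tolerances across seeds)
while keeping a full run in minutes.
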