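# popsweep

Population-genomic analysis of structured resequencing cohorts, downstream
of variant calling: SNP filtering, per-population diversity, linkage
disequilibrium (LD) decay, population structure, and selective-sweep
detection by intersecting the upper tails of windowed F<sub>ST</sub> and the
between-population nucleotide-diversity ratio. It is aimed at
livestock/wildlife population genetics of the common "several breeds,
tens-to-hundreds of samples each, one multi-sample VCF" design, and ships a
truth-known cohort simulator so every statistic can be validated end to end.

## What it computes

**Filtering** (`filter_variants()`): hard INFO thresholds (site removed when
any present metric violates QD < 2.0, FS > 60.0, MQ < 40.0, SOR > 3.0,
MQRankSum < −12.5, ReadPosRankSum < −8.0; strict inequalities), SNP-cluster
removal (more than 2 SNPs within any 5 bp), indel proximity (SNPs within
5 bp of an indel), and per-call GQ < 20 masking.

**Diversity** (`diversity_table()`), per population with alt frequency *p*,
*q* = 1 − *p*, *n* called alleles:

- P<sub>n</sub> — proportion of callable sites segregating in the population
- H<sub>E</sub> = 1 − *p*² − *q*² (Nei plug-in), H<sub>O</sub> = observed
  heterozygote fraction
- π = c<sub>ref</sub>·c<sub>alt</sub> / C(*n*, 2), the unbiased average
  pairwise difference, averaged over SNP sites
- PIC = 1 − (*p*² + *q*²) − 2*p*²*q*² (biallelic reduction of
  1 − Σp<sub>i</sub>² − ΣΣ2p<sub>i</sub>²p<sub>j</sub>²)

plus a pairwise comparison report (`table1_report()`) in the
"*a* is 100(*b* − *a*)/*b* % lower than *b*" convention.

**LD decay** (`decay_curve()`): r² between unphased genotype pairs via EM
maximum-likelihood haplotype frequencies (grid-search-verified), D′, and
distance-binned decay curves per population.

**Structure**: genotype PCA with Patterson scaling and variance explained
(`pca_genotypes()`), identity-by-state distances (`ibs_distance()`),
neighbor-joining trees (`nj_tree()`, Newick output).

**Sweep scan** (`sweep_scan()`): sliding-window Weir–Cockerham (1984)
F<sub>ST</sub> as Σa / Σ(a+b+c), window π per population, the θπ ratio
π<sub>ref</sub>/π<sub>target</sub> (high = diversity loss in the target),
empirical joint top-quantile selection, merging into candidate regions, and
gene annotation by GFF3 interval overlap.

**Simulation** (`simulate_cohort()`): Balding–Nichols populations with known
F, injected frequency-push sweeps with known coordinates, missing data, GQ,
and clean/artifact INFO fields — written as VCF + popmap + truth table.

## Worked example

Simulate three populations of 90 diploids (the target population carries a
1 Mb sweep), filter, and scan:

```r
library(popsweep)

cfg <- sim_config(n_pops = 3, samples_per_pop = 90, n_sites = 5000,
                  chrom_length = 1e7, fst = c(0.12, 0.08, 0.10),
                  missing_rate = 0.02, artifact_rate = 0.05, seed = 2024,
                  pop_names = c("ZY", "HY", "XWHY"),
                  sweep_specs = list(list(pop = "ZY", start = 4e6 + 1,
                                          end = 5e6, intensity = 0.9)))
cohort <- simulate_cohort(cfg)
res <- filter_variants(cohort$geno)
res$reports$hard
#> [hard_filter] 5000 sites in, 242 removed, 4758 out

diversity_table(res$geno, cohort$popmap)
#>   group    Pn    He    Ho    Pi   PIC
#> 1    HY 0.987 0.332 0.334 0.334 0.265
#> 2  XWHY 0.980 0.329 0.330 0.331 0.263
#> 3    ZY 0.957 0.294 0.297 0.296 0.236

scan <- sweep_scan(res$geno, cohort$popmap, target = "ZY", reference = "HY",
                   window_size = 1e5, step = 1e5, q_fst = 0.10, q_ratio = 0.10)
scan
#> sweep_scan: 100 windows, 10 selected, 1 regions
#>   thresholds: fst >= 0.1796 , pi_ratio >= 1.783
scan$regions
#>   chrom   start     end n_windows peak_fst peak_pi_ratio
#> 1  chr1 4000001 5000001        10   0.4684         8.755
```

The 242 removed sites are exactly the simulated artifact-INFO sites; the
swept population (ZY) shows the depressed H<sub>E</sub>/π, and the single
merged candidate region reproduces the injected sweep interval
[4,000,001, 5,000,001) with its peak F<sub>ST</sub> and θπ ratio. The
quantile `q = 0.10` here matches the simulated tail (10 sweep windows of
100); for genome-scale scans the default is the literal top 0.01%
(`q = 1e-4`), and the choice is always echoed in the output.

`run_pipeline()` (or the thin CLI at `inst/cli/popsweep.R`) chains all
stages — filter report, diversity table and comparisons, LD curves,
PCA/IBS/NJ, window statistics, regions BED/TSV with genes — into an output
directory with a reproducibility manifest.

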