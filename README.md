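# poolscan

Genome scans for replicated experimental evolution from pool-seq data.

When replicate populations are evolved under two mating-system treatments —
enforced monogamy (M) vs elevated polyandry (E) — and each line is
sequenced as a pool of individuals, the loci that responded to the
treatment are those whose allele frequencies diverged *consistently across
all replicate pairs*. poolscan implements that analysis end to end:

* **SNP calling** from popoolation-style sync count tables with
  PoolSNP-style heuristics (total coverage > 17 and below the
  per-chromosome 95th percentile; allele count > 16 and pooled frequency
  > 0.001 across pools).
* **Divergence scan**: per-SNP quasibinomial GLM of major-allele frequency
  on treatment (`y ~ treatment` with a free dispersion, t test on
  n_pools − 2 df), Storey q-values (top SNPs: q < 0.05), whole-genome and
  per-SNP treatment-label permutation nulls (68 unique relabellings for
  the 4-vs-4 paired design), 50-kb single-linkage clustering of top SNPs
  into divergence peaks, per-chromosome excess tests, coverage sanity
  checks and fixed-difference flags.
* **Diversity**: pool-corrected π, Watterson's θ and Tajima's D in 50-kb
  windows with 10-kb overlap, per-gene means, in/out-of-peak contrasts.
* **Differentiation**: per-SNP pairwise pool FST from identity
  probabilities (read- and pool-sampling corrected), window averages, the
  neutral X-chromosome expectation
  `F_X = 1 − 9(z+1)(1−F_A) / (8(2z+1) − (1−F_A)(7z−1))`
  with 1000-iteration bootstrap bands (z = 1 and 6), and X:A ratios.
* **LD decay** from read-pair co-observations: direct two-locus haplotype
  counting, `r² = D²/(p₁q₁p₂q₂)`, exact-distance classes (≥ 5 pairs), and
  the decay fit `r² ~ a + log(bp)`.
* **Expression integration**: genes within 10 kb of top SNPs, a
  1000-draw resampled overlap test against DE gene sets, DE vs non-DE
  contrasts, and the ΔSB ANCOVA of sex-bias change on Tajima's D.
* **Synthetic data**: a Wright–Fisher forward simulator of the replicated
  design (4 paired lines, Ne ≈ 120, 160 generations, divergent selection,
  X-linked loci at N_eX = ¾N_eA, pools of 40 females, binomial read
  sampling) that provides ground truth for every test in the package.

See `vignettes/poolscan-methods.Rmd` for the statistical details and the
design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # design: 8 pools, 5 chromosomes, 5000 loci
Rscript analysis/02_call_snps.R
Rscript analysis/03_scan.R
Rscript analysis/04_diversity.R
Rscript analysis/05_fst.R
Rscript analysis/06_ld.R
Rscript analysis/07_expression.R
```

A run with the default seed prints, among other things:

```
called 4345 biallelic SNPs from 5000 sites (0 multi-allelic dropped)
9 of 4345 SNPs are top SNPs (q < 0.05)
observed 139 SNPs with p < 0.05; permutation max 116 (n = 68 permutations)
3 clusters, 0 with > 10 SNPs
X:A window-FST ratio 1.24 (95% CI 1.19-1.29)
window FST in peaks 0.671 vs outside 0.384 (p = 4.34e-05)
DE overlap 0.593 vs resampled mean 0.173 (empirical p = 0.000999, significant)
```

Reading this: of 5000 simulated loci, 4345 pass the calling filters; nine
change consistently enough across all four replicate pairs to clear
q < 0.05, and they fall into three clusters — exactly the three planted
sweep regions (chromosome 3, XL, XR). The observed number of nominally
significant SNPs exceeds every one of the 68 treatment-label permutations,
differentiation is elevated on the X (ratio > 1) and inside the divergence
peaks, and genes near top SNPs overlap the differentially expressed gene
set far more than resampled gene sets of the same size.

The same pipeline runs as one call:

```r
library(poolscan)
res <- run_pipeline(run_config(seed = 1), "out/")
str(res$summary)
```

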