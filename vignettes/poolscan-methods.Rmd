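---
title: "Methods: pool-seq genome scans for replicated experimental evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq genome scans for replicated experimental evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

poolscan detects consistent allele-frequency divergence between replicated
experimental-evolution treatments from pooled sequencing. The design it
targets is a paired one: several replicate line pairs, one line per pair
evolved under each of two treatments (here labelled E, elevated polyandry,
and M, enforced monogamy), each line pool-sequenced as a single DNA pool of
many individuals. This vignette describes the statistical machinery, the
synthetic-data generator used to exercise it, the numerical choices, and
the known limitations.

## The divergence scan

For every biallelic SNP the scan models the per-pool major-allele count
(out of the pool's read coverage) as a binomial-logit GLM with treatment as
the only predictor and a free (quasi-likelihood) dispersion:

y ~ treatment, Var(y) = phi * binomial variance.

Because the model is a saturated two-group comparison, the maximum
quasi-likelihood fit has a closed form: the fitted group probabilities are
the pooled (read-weighted) major-allele frequencies of the E and M pools,
and the treatment coefficient is their logit difference. `glm_scan()`
computes exactly this, vectorised over all SNPs; the test suite checks it
against `stats::glm(family = quasibinomial)` to below 1e-6 relative error.
The dispersion is the Pearson chi-square divided by (n_pools - 2) and is
deliberately not floored at 1 (conventional quasi-likelihood behaviour);
inference uses a two-sided t statistic with n_pools - 2 degrees of freedom
and dispersion-scaled variance.

Counts of zero would make the logit undefined, so a pseudocount rule is
applied first: if any major or minor count of a SNP is zero in any pool,
+1 is added to every major and minor count of that SNP. A per-pool-only
variant is available (`pseudocount_scope = "per_pool"`).

P-values are converted to Storey-Tibshirani q-values (`storey_qvalues()`):
pi0 is estimated on the grid lambda = 0, 0.05, ..., 0.90, smoothed with a
cubic smoothing spline (df = 3), evaluated at lambda = 0.90 and clipped to
(0, 1]. "Top SNPs" are those with q < 0.05.

Two permutation nulls accompany the scan. In whole-genome mode every SNP is
refit under one shared relabelling of the pools, which preserves the
correlation of allele frequencies at linked SNPs; for the 4-vs-4 paired
design there are C(8,4) - 2 = 68 unique relabellings after removing the
observed assignment and its complement (complements of other assignments
are retained — this is the counting that yields 68). In per-SNP mode each
SNP draws an independent relabelling, deliberately destroying the spatial
correlation structure.

Top SNPs are chained into clusters by single linkage: consecutive top SNPs
on a chromosome join one cluster if their gap is at most 50 kb (inclusive
at exactly 50,000 bp). Clusters with more than 10 member SNPs are flagged
as "peaks". Supporting checks: a per-chromosome exact binomial test of
top-SNP counts against each chromosome's share of background SNPs
(Bonferroni-adjusted; the method is a documented choice, since excess
could also be measured against chromosome length), a coverage comparison
of peak regions against randomly placed regions with a matched length
distribution, and a flag for SNPs that are fixed differences between the
treatments in every replicate (evaluated on raw, pre-pseudocount counts).

## Diversity and differentiation

Per-site diversity uses the two-stage pool-seq correction: with read
coverage C, estimated frequency p, and n diploids in the pool,

pi_site = C/(C-1) * 2p(1-p) * 2n/(2n-1),

the first factor unbiasing read sampling from the pool and the second pool
sampling from the population. Windows of 50 kb at a 40-kb step (a 10-kb
overlap; the step is a `step_bp` parameter) accumulate site pi; Watterson's
theta is S / a1(2n) over SNPs segregating within the pool, and Tajima's D
uses the classical variance with sample size 2n (the pool's chromosome
count). D is reported only when a window has at least `min_snps` (default
10) segregating sites, since D on a handful of SNPs is unstable. The pi
denominator is the window length unless a mask of adequately covered sites
is supplied. Per-gene statistics are unweighted means over all windows
intersecting the gene span by at least 1 bp.

Pairwise FST between the E and M pools of each replicate uses the
identity-probability (ANOVA) formulation of a pool-seq FST estimator:
within-pool identity Q1 estimated from read pairs with a correction for
two reads hitting the same pool chromosome (probability 1/2n), between-pool
identity Q2 from cross-pool read pairs, and FST = (Q1bar - Q2)/(1 - Q2).
Negative per-SNP values are retained in window averages (clamping would
bias means upward); window FST is the arithmetic mean of member SNPs
(average of ratios). The test suite verifies the estimator against
Weir-Cockerham computed on the true frequencies in deep-pool, deep-coverage
simulations.

The neutral X-chromosome expectation given autosomal FST (F_A) and the
breeding-sex ratio z (males : females) is

F_X = 1 - 9(z+1)(1-F_A) / (8(2z+1) - (1-F_A)(7z-1)).

The final term is read as a product, (1-F_A)(7z-1); this reading is forced
by the boundary conditions F_X(0, z) = 0 and F_X(1, z) = 1, which the
alternative (power) reading violates. z = 1 and z = 6 bracket the two
mating-system extremes. Bootstrap bands draw, per iteration, a number of
windows equal to the autosomal window count with replacement from the set
of all windows (X included — the literal protocol; an autosomes-only
variant is a flag), convert the mean to F_X and take the 2.5/97.5
percentiles. Bootstrap means are clamped to [0, 1] before conversion, since
resampled means of a noisy estimator can stray marginally outside the
domain of the closed form.

## Linkage disequilibrium

Haplotype information within an insert-sized neighbourhood is recovered
from read pairs: for two sites covered by the same pair, two-locus
haplotype counts are tallied directly (no EM over unphased data, which is
unnecessary at within-fragment distances) and r2 = D^2/(p1 q1 p2 q2).
Sites are filtered to minor allele frequency > 0.1, coverage within
[10, 400] and base quality > 20; pairs monomorphic among their joint
observations are skipped. Mean r2 per exact integer distance class (classes
with fewer than five pairs dropped) is regressed on the natural log of
distance; the slope measures LD decay. The log base only rescales the
slope and is held fixed at e. Regional and treatment contrasts fit a
linear model with interaction terms on the pooled class-level data.

## Expression integration

Genes (and lncRNAs, treated as ordinary gene intervals) within 10 kb of a
top SNP — inclusive boundaries, ties kept — form the query set. Its overlap
with a differential-expression (DE) gene list is compared with 1000
resamples of equally many genes drawn without replacement from the
annotation; the empirical p-value uses the add-one correction
(1 + #{resamples >= observed}) / (n + 1), while the significance flag
applies the 95th-percentile rule verbatim. Both are reported because the
add-one p can never be zero while the percentile rule is the original
decision criterion. DE vs non-DE contrasts of gene-level FST or Tajima's D
compare DE genes against the single value given by the non-DE mean with a
one-sample Wilcoxon signed-rank test per stratum (a two-sample rank-sum
test is internally inconsistent with a single reference value; a
two-sample option exists). The sex-bias analysis regresses the change in
sex-biased expression between treatments, delta_SB = log2FC_E - log2FC_M,
on chromosome type, gene-level Tajima's D in E and in M, and both
interactions, by OLS with sequential F-tests.

## The synthetic-data generator

The generator emulates the study design rather than any particular dataset:
4 replicate E/M line pairs from one ancestral population (identical
starting frequencies across all 8 lines), effective size 120 per line, 160
generations, pools of 40 diploid females, Poisson read depth (default 50x)
with binomial read sampling on top of binomial pool sampling. X-linked loci
(declared by chromosome name, default XL and XR) drift with
round(1.5 * Ne) gene copies (N_eX = 3/4 N_eA); because only females are
pooled, X-linked loci still contribute 2 * pool_size chromosomes to the
pool. Selection is the standard deterministic viability update with
genotype fitnesses 1, 1-hs, 1-s followed by binomial drift.

Choices made where the design was genuinely open:

* Ancestral frequencies are Uniform(0.05, 0.95) by default; a neutral-SFS
  option (density 1/p) exists for equilibrium-like checks. The uniform
  default over-represents intermediate frequencies relative to a neutral
  equilibrium, which — together with drift and the SNP-calling ascertainment
  against rare alleles — makes window Tajima's D strongly positive on these
  simulations. That is a property of the emulated design (common standing
  variation, no new mutation), not an estimator defect; the estimator is
  validated separately against classical D computed from true haplotype
  pools.
* Divergent selection is symmetric by default: the focal allele is favoured
  in E (s_e = +0.05) and disfavoured in M (s_m = -0.05). The experiment
  manipulates the direction of sexual selection in both treatments, and
  opposed coefficients are the minimal encoding of "treatment-specific
  divergent selection"; s_m = 0 (relaxed selection in M) is a parameter
  away.
* The pipeline default places selected loci in clustered sweep regions
  (one 50-kb region each on chromosome 3, XL and XR) rather than scattering
  them: the phenomenon of interest is localised, clustered divergence, and
  without genome-wide linkage in the simulator only clustered placement can
  produce divergence peaks. Random placement remains the `sim_config()`
  default for locus-level calibration and recovery runs.
* Read-pair LD uses dedicated linked-haplotype regions (a forward
  Wright-Fisher simulation of 2*Ne haplotypes with per-interval
  recombination) rather than genome-wide haplotype tracking, which the
  statistics do not need. Fragment size is Normal(340, 10) to match a
  short-insert library; read length 100.
* Synthetic DE gene sets tile non-overlapping intervals and raise the DE
  odds by a configurable factor near selected loci; sex-bias fold changes
  are bivariate normal (sd 1, correlation 0.8).

What the generator does not emulate: genome-wide linkage and hitchhiking,
new mutation, inversion polymorphism, mapping error and reference bias,
overdispersed coverage (Poisson only by default). Passing tests therefore
demonstrate correctness of the estimators and the qualitative behaviour of
the pipeline under the stated design, not performance on real libraries.

## Numerical choices and degenerate inputs

* Coverage quantile ceilings use linear interpolation (type-7 quantiles),
  per chromosome; a site on a chromosome with a single site can never pass
  the strict "below the ceiling" rule.
* Ties for the major allele are broken in A, T, C, G order.
* A SNP with exactly balanced counts has beta = 0 and dispersion 0; the t
  statistic is defined as 0 there (p = 1). Perfectly consistent divergence
  gives dispersion 0 with nonzero beta, hence p = 0.
* pi0 estimates are clipped to (0, 1]; q-values are capped at 1.
* FST is undefined (NA) when a pool has coverage < 2 or both pools are
  fixed for the same allele; such SNPs are skipped by window averages.
* Windows with no SNPs report pi = 0 (over the window-length denominator)
  and missing D and FST.
* All stage seeds derive from one global seed by fixed offsets, so a run
  is byte-identical under a fixed seed and stages can be rerun
  independently.

## Problem sizes

The default pipeline run simulates 5 chromosomes (2, 3, 4, XL, XR) of 2 Mb
and 1000 loci each — 5000 loci, of which roughly 70 fall in the three sweep
regions — and completes in well under a minute on one core. Calibration and
recovery checks average 20 independent simulations of the same size. The
estimator-oracle checks use deep pools (up to 20,000 diploids at 20,000x)
so that sampling noise does not obscure estimator agreement; these sizes
satisfy the stated lower bounds of the corresponding checks.

## Known limitations

* Power at the study's own scale: with 4 replicates the dispersion-scaled
  t test has 6 degrees of freedom, and its p-values are bounded below by
  the line-to-line drift scatter. After 160 generations at Ne = 120 a
  locus under s = +/-0.05 divergent selection is usually strongly but not
  perfectly consistent across replicates, giving p around 1e-3 — above the
  q < 0.05 rank threshold when thousands of SNPs are tested. Only loci
  fixed (or nearly fixed) in opposite directions in all replicates are
  recovered, about a fifth of selected loci under these conditions. The
  acceptance suite records this honestly: the scan's calibration, the
  permutation null and the qualitative genome-scan headlines reproduce,
  but majority recovery of individually selected loci at q < 0.05 is not
  attainable under the stated design parameters, mirroring the fact that
  the original scan reported a few hundred top SNPs out of ~2 million.
* Storey's pi0 on a few thousand p-values is itself noisy; with strong
  signals the q threshold moves accordingly.
* The t-based scan is slightly conservative on fully null data (the
  p < 0.05 fraction sits near the bottom of the accepted [0.02, 0.08]
  band), as expected for dispersion estimated with 6 df.
* LD estimates are confined to within-fragment distances (here <= ~340 bp)
  and exact-distance classes need deep pair sampling to populate.
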