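Package: poolscan
Title: Genome Scans for Replicated Experimental Evolution with Pool-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects consistent allele-frequency divergence between replicated
    experimental-evolution treatments from pooled sequencing (pool-seq) count
    data. Provides a PoolSNP-style heuristic SNP caller for sync-format count
    tables, a per-SNP quasibinomial GLM scan with Storey q-values and
    treatment-label permutation nulls, 50-kb single-linkage clustering of top
    SNPs into divergence peaks, pool-corrected nucleotide diversity and
    Tajima's D in overlapping windows, pairwise pool FST with neutral
    X-chromosome expectations and bootstrap intervals, short-range linkage
    disequilibrium decay from read-pair haplotype observations, and
    integration with differential-expression gene sets. Includes a
    Wright-Fisher forward simulator of the replicated monogamy/polyandry
    design (selection, drift, X-linkage, pool and read sampling) that
    provides ground truth for calibration and recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
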