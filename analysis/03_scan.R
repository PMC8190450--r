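#!/usr/bin/env Rscript
# Per-SNP quasibinomial GLM of major-allele frequency on treatment,
# Storey q-values (top SNPs: q < 0.05), the 68-permutation null, 50-kb
# clustering of top SNPs, per-chromosome excess and fixed differences.

library(poolscan)
library(data.table)

sheet <- read_sample_sheet("results/sample_sheet.tsv", paired = TRUE)
sites <- read_sync("results/sites.sync", sheet)
snps <- call_snps(sites)

scan <- glm_scan(snps, sheet, q_threshold = 0.05)
top <- scan[is_top == TRUE]
message(sprintf("%d of %d SNPs are top SNPs (q < 0.05)", nrow(top), nrow(scan)))

perm <- permutation_scan(snps, sheet, mode = "whole_genome")
message(sprintf("observed %d SNPs with p < 0.05; permutation max %d (n = %d permutations)",
                perm$observed, max(perm$counts), length(perm$counts)))

peaks <- cluster_top_snps(top[, .(chrom, pos)], link_bp = 50000L)
message(sprintf("%d clusters, %d with > 10 SNPs", nrow(peaks), sum(peaks$is_peak)))

bg <- table(scan$chrom); bg <- bg[bg > 0]
excess <- chromosome_excess_test(table(factor(top$chrom, levels = names(bg))), bg)
fixed <- fixed_difference_flags(subset_snps(snps, which(scan$is_top)), sheet)
message(sprintf("%.0f%% of top SNPs are fixed differences in all replicates",
                100 * mean(fixed)))

write_tsv(scan, "results/scan.tsv")
write_tsv(peaks, "results/peaks.tsv")
write_tsv(excess, "results/chromosome_excess.tsv")
write_tsv(data.table(perm_count = perm$counts), "results/permutation_counts.tsv")
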