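#!/usr/bin/env Rscript
# Integration with expression inputs: genes within 10 kb of top SNPs, the
# 1000-draw resampled overlap with the DE gene set, DE vs non-DE FST
# contrasts per chromosome type, and the sex-bias-change ANCOVA.

library(poolscan)
library(data.table)

sheet <- read_sample_sheet("results/sample_sheet.tsv", paired = TRUE)
genes <- read_gene_annotation("results/genes.tsv")
scan <- fread("results/scan.tsv", na.strings = ".")
wfst <- fread("results/window_fst.tsv", na.strings = ".")
div <- fread("results/diversity.tsv", na.strings = ".")
x_chroms <- c("XL", "XR")

top <- scan[is_top == TRUE, .(chrom, pos)]
near <- genes_near_snps(top, genes, flank_bp = 10000L)
message(sprintf("%d genes within 10 kb of a top SNP", nrow(near)))

ovl <- overlap_resampling_test(near$gene_id, genes[is_de == TRUE, gene_id],
                               genes$gene_id, n_resample = 1000L, seed = 7L)
message(sprintf("DE overlap %.3f vs resampled mean %.3f (empirical p = %.4g, %s)",
                ovl$observed_overlap_prop, ovl$resample_mean, ovl$empirical_p,
                if (ovl$significant) "significant" else "not significant"))

wmean <- wfst[, .(fst = mean(fst, na.rm = TRUE)), by = .(chrom, start, end)]
gene_fst <- gene_mean_stat(wmean, genes, stat_col = "fst")
gene_fst <- merge(gene_fst, genes[, .(gene_id, chrom, is_de)], by = "gene_id")
gene_fst[, chrom_type := fifelse(chrom %in% x_chroms, chrom, "autosome")]
contrast <- de_contrast(gene_fst, stat_col = "mean_stat",
                        strata_cols = "chrom_type")
write_tsv(contrast, "results/de_contrast_fst.tsv")
print(contrast)

# gene-level Tajima's D per treatment feeds the sex-bias ANCOVA
anc_in <- genes[, .(gene_id, chrom, log2fc_e, log2fc_m)]
for (tr in c("E", "M")) {
  dtr <- div[treatment == tr, .(tajd = mean(tajd, na.rm = TRUE)),
             by = .(chrom, start, end)]
  gtr <- gene_mean_stat(dtr, genes, stat_col = "tajd")
  anc_in <- merge(anc_in, gtr[, .(gene_id, mean_stat)], by = "gene_id")
  setnames(anc_in, "mean_stat", paste0("tajd_", tolower(tr)))
}
anc_in[, chrom_type := fifelse(chrom %in% x_chroms, chrom, "autosome")]
anc <- ancova_delta_sb(anc_in)
write_tsv(as.data.table(anc$anova, keep.rownames = "term"),
          "results/ancova_delta_sb.tsv")
message("ANCOVA sequential F-tests written to results/ancova_delta_sb.tsv")
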