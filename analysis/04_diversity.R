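#!/usr/bin/env Rscript
# Pool-corrected pi, Watterson's theta and Tajima's D in 50-kb windows
# (40-kb step), per pool; treatment means and the in/out-of-peak contrast.

library(poolscan)
library(data.table)

sheet <- read_sample_sheet("results/sample_sheet.tsv", paired = TRUE)
sites <- read_sync("results/sites.sync", sheet)
snps <- call_snps(sites)
peaks <- fread("results/peaks.tsv")

chrom_lengths <- tapply(sites$pos, sites$chrom, max)
windows <- window_plan(chrom_lengths)
div <- window_diversity(snps, sheet, windows, min_snps = 10L)
div <- merge(div, sheet[, .(pool = pool_id, treatment)], by = "pool")
write_tsv(div, "results/diversity.tsv")

for (tr in c("E", "M"))
  message(sprintf("treatment %s: mean pi %.3g, mean Tajima's D %.2f", tr,
                  mean(div[treatment == tr, pi], na.rm = TRUE),
                  mean(div[treatment == tr, tajd], na.rm = TRUE)))

if (nrow(peaks)) {
  de <- div[treatment == "E", .(tajd = mean(tajd, na.rm = TRUE)),
            by = .(chrom, start, end)]
  rc <- tryCatch(region_contrast(de, peaks, stat_col = "tajd"),
                 error = function(e) NULL)
  if (!is.null(rc))
    message(sprintf("E-line Tajima's D in peaks %.2f vs outside %.2f (V = %s, p = %.3g)",
                    rc$mean_in, rc$mean_out, format(rc$statistic), rc$p_value))
}
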