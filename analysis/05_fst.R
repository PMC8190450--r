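#!/usr/bin/env Rscript
# Pairwise pool FST per replicate E/M pair, 50-kb window averages, the
# neutral X expectation F_X (z = 1 and 6) with 1000-iteration bootstrap
# bands, X:A ratios, and the in/out-of-peak FST contrast.

library(poolscan)
library(data.table)

sheet <- read_sample_sheet("results/sample_sheet.tsv", paired = TRUE)
sites <- read_sync("results/sites.sync", sheet)
snps <- call_snps(sites)
peaks <- fread("results/peaks.tsv")
x_chroms <- c("XL", "XR")

chrom_lengths <- tapply(sites$pos, sites$chrom, max)
windows <- window_plan(chrom_lengths)
rec <- replicate_pair_fst(snps, sheet)
wfst <- window_fst(rec, windows, group_col = "replicate")
write_tsv(wfst, "results/window_fst.tsv")

fx <- bootstrap_fx(wfst, x_chroms = x_chroms, z = c(1, 6),
                   n_boot = 1000L, seed = 4L, group_col = "replicate")
write_tsv(fx, "results/fx_expectation.tsv")

wmean <- wfst[, .(fst = mean(fst, na.rm = TRUE)), by = .(chrom, start, end)]
xa <- xa_ratio(wmean, "fst", x_chroms, seed = 5L)
message(sprintf("X:A window-FST ratio %.2f (95%% CI %.2f-%.2f)",
                xa$ratio, xa$ci_low, xa$ci_high))
for (zz in c(1, 6))
  message(sprintf("z = %d: observed X FST %.3f vs drift expectation %.3f [%.3f, %.3f]",
                  zz, mean(fx[z == zz, f_x_observed]),
                  mean(fx[z == zz, f_x_expected]),
                  mean(fx[z == zz, ci_low]), mean(fx[z == zz, ci_high])))

if (nrow(peaks)) {
  rc <- tryCatch(region_contrast(wmean, peaks, stat_col = "fst"),
                 error = function(e) NULL)
  if (!is.null(rc))
    message(sprintf("window FST in peaks %.3f vs outside %.3f (p = %.3g)",
                    rc$mean_in, rc$mean_out, rc$p_value))
}
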