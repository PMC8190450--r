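#!/usr/bin/env Rscript
# PoolSNP-style calling on the simulated sync table: total coverage > 17
# and below the per-chromosome 95th percentile; an allele needs count > 16
# and pooled frequency > 0.001 across pools.

library(poolscan)
library(data.table)

sheet <- read_sample_sheet("results/sample_sheet.tsv", paired = TRUE)
sites <- read_sync("results/sites.sync", sheet)
snps <- call_snps(sites, site_filter_config())

out <- cbind(snps$info, as.data.table(snps$maj), as.data.table(snps$mino))
write_tsv(out, "results/snps.tsv")
message(sprintf("called %d biallelic SNPs from %d sites (%d multi-allelic dropped)",
                n_snps(snps), n_sites(sites), snps$n_multiallelic))
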