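# Integration of the genomic scan with expression inputs: genes near top
# SNPs, resampled overlap with DE gene sets, DE vs non-DE contrasts of
# gene-level FST / Tajima's D, and the sex-bias-change ANCOVA.

#' Genes within a flank of top SNPs
#'
#' A gene is included iff any top SNP lies within
#' `[start - flank_bp, end + flank_bp]` (inclusive boundaries); one SNP may
#' implicate several genes (ties kept). `flank_bp = 0` returns exactly the
#' genes containing a top SNP.
#'
#' @param top_snps `data.table`/data.frame with chrom, pos of top SNPs.
#' @param genes Gene annotation (gene_id, chrom, start, end).
#' @param flank_bp Flank distance in bp (default 10000).
#' @return The subset of `genes` near a top SNP, original column set.
#' @export
genes_near_snps <- function(top_snps, genes, flank_bp = 10000L) {
  ts <- data.table::as.data.table(top_snps)
  g <- data.table::as.data.table(genes)
  if (nrow(ts) == 0L || nrow(g) == 0L) return(g[0])
  flanked <- g[, .(gene_id, chrom, start = start - flank_bp,
                   end = end + flank_bp)]
  data.table::setkey(flanked, chrom, start, end)
  q <- ts[, .(chrom, start = pos, end = pos)]
  ov <- data.table::foverlaps(q, flanked, type = "within", nomatch = NULL)
  g[gene_id %in% unique(ov$gene_id)]
}

#' Resampling test of overlap with a DE gene set
#'
#' Each of `n_resample` draws takes `|query|` genes without replacement
#' from the universe and records the proportion also in the DE set. The
#' empirical p-value uses the add-one correction
#' `(1 + #{resamples >= observed}) / (n_resample + 1)`; the significance
#' flag applies the 95th-percentile rule verbatim (observed >= 95th
#' percentile of the resampled proportions). Both are reported.
#'
#' @param query_ids Genes near top SNPs (subset of `universe_ids`).
#' @param de_ids DE gene set (subset of `universe_ids`).
#' @param universe_ids All annotated genes.
#' @param n_resample Resampling iterations (default 1000).
#' @param seed Integer seed.
#' @return List (`OverlapTestResult`): n_query, observed_overlap_prop,
#'   resample_quantiles, empirical_p, significant.
#' @export
overlap_resampling_test <- function(query_ids, de_ids, universe_ids,
                                    n_resample = 1000L, seed = 1L) {
  stopifnot(length(query_ids) >= 1L)
  if (length(query_ids) > length(universe_ids))
    stop("query larger than universe")
  if (!all(query_ids %in% universe_ids) || !all(de_ids %in% universe_ids))
    stop("query and DE sets must be subsets of the universe")
  set.seed(seed)
  observed <- mean(query_ids %in% de_ids)
  res <- vapply(seq_len(n_resample), function(b)
    mean(sample(universe_ids, length(query_ids)) %in% de_ids), numeric(1))
  q95 <- quantile(res, 0.95, names = FALSE)
  list(n_query = length(query_ids),
       observed_overlap_prop = observed,
       resample_quantiles = quantile(res, c(0.025, 0.5, 0.95, 0.975)),
       resample_mean = mean(res),
       empirical_p = (1 + sum(res >= observed)) / (n_resample + 1),
       significant = observed >= q95)
}

#' DE vs non-DE contrast of a gene-level statistic
#'
#' Per stratum (e.g. chromosome type, optionally crossed with treatment),
#' the mean of the non-DE genes is used as a single reference value and the
#' DE-gene values are compared to it with a one-sample Wilcoxon signed-rank
#' test (two-sided; the rank statistic is housed as V). A two-sample
#' rank-sum option is available.
#'
#' @param gene_stats `data.table` with gene_id, value column, stratum
#'   column(s), and a logical `is_de` column.
#' @param stat_col Value column name.
#' @param strata_cols Character vector of stratum column names.
#' @param two_sample If `TRUE`, use a two-sample rank-sum test instead.
#' @return `data.table`: strata, n_de, n_non_de, mean_de, mean_non_de,
#'   statistic, p_value (missing row if a stratum has no usable DE gene).
#' @export
de_contrast <- function(gene_stats, stat_col = "mean_stat",
                        strata_cols = "chrom_type", two_sample = FALSE) {
  gs <- data.table::as.data.table(gene_stats)
  gs <- gs[!is.na(gs[[stat_col]])]
  gs[, .val := .SD[[stat_col]], .SDcols = stat_col]
  out <- gs[, {
    de <- .val[is_de == TRUE]
    nde <- .val[is_de == FALSE]
    if (length(de) < 1L || length(nde) < 1L) {
      list(n_de = length(de), n_non_de = length(nde),
           mean_de = NA_real_, mean_non_de = NA_real_,
           statistic = NA_real_, p_value = NA_real_)
    } else {
      wt <- suppressWarnings(
        if (two_sample) wilcox.test(de, nde)
        else wilcox.test(de, mu = mean(nde)))
      list(n_de = length(de), n_non_de = length(nde),
           mean_de = mean(de), mean_non_de = mean(nde),
           statistic = unname(wt$statistic), p_value = wt$p.value)
    }
  }, by = strata_cols]
  out[]
}

#' ANCOVA of sex-bias change on diversity
#'
#' Fits `delta_sb ~ chrom_type + tajd_e + tajd_m + tajd_e:chrom_type +
#' tajd_m:chrom_type` by ordinary least squares, where `delta_sb` is the
#' change in sex-biased expression between treatments
#' (`log2fc_e - log2fc_m`) and `tajd_e` / `tajd_m` are gene-level Tajima's
#' D in E and M lines. Returns the coefficient table and the sequential F
#' table.
#'
#' @param records `data.table` with columns delta_sb (or log2fc_e and
#'   log2fc_m), tajd_e, tajd_m, chrom_type, and optionally `tissue`.
#' @param tissue Optional tissue label to filter on.
#' @return List: coefficients (matrix), anova (data.frame), model.
#' @export
ancova_delta_sb <- function(records, tissue = NULL) {
  r <- data.table::as.data.table(records)
  if (!is.null(tissue) && "tissue" %in% names(r)) r <- r[r$tissue == tissue]
  if (!"delta_sb" %in% names(r)) r[, delta_sb := log2fc_e - log2fc_m]
  r <- r[complete.cases(r[, .(delta_sb, tajd_e, tajd_m, chrom_type)])]
  r[, chrom_type := factor(chrom_type)]
  if (length(levels(r$chrom_type)) < 2L)
    stop("need at least 2 chromosome types")
  if (any(table(r$chrom_type) < 2L))
    stop("a chromosome type has fewer than 2 records (rank deficient)")
  fit <- lm(delta_sb ~ chrom_type + tajd_e + tajd_m +
              tajd_e:chrom_type + tajd_m:chrom_type, data = r)
  list(coefficients = summary(fit)$coefficients,
       anova = as.data.frame(anova(fit)), model = fit)
}
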