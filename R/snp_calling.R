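# PoolSNP-style heuristic SNP calling from sync count tables.
# A site is considered only if total A/T/C/G coverage (summed across pools)
# is above a minimum and below a per-chromosome quantile ceiling; an allele
# is called only if its summed count and pooled frequency clear thresholds.

#' Site filter configuration for SNP calling
#'
#' Defaults encode the strictly-greater readings of the original filters:
#' total coverage "more than 17" (>= 18), allele count across pools ">16"
#' (>= 17), pooled allele frequency "> 0.001" (strict), and a per-chromosome
#' 95th-percentile coverage ceiling (strictly below).
#'
#' @param min_total_cov Minimum total coverage summed across pools.
#' @param max_cov_quantile Per-chromosome coverage quantile used as ceiling.
#' @param min_allele_count Minimum allele count summed across pools.
#' @param min_allele_freq Pooled allele frequency must strictly exceed this.
#' @param per_pool_ceiling If `TRUE`, apply the coverage ceiling to each
#'   pool's coverage rather than the pooled total (alternative reading).
#' @return A list of class `site_filter_config`.
#' @export
site_filter_config <- function(min_total_cov = 18L, max_cov_quantile = 0.95,
                               min_allele_count = 17L,
                               min_allele_freq = 0.001,
                               per_pool_ceiling = FALSE) {
  stopifnot(min_total_cov >= 1, max_cov_quantile > 0, max_cov_quantile <= 1)
  structure(list(min_total_cov = as.integer(min_total_cov),
                 max_cov_quantile = max_cov_quantile,
                 min_allele_count = as.integer(min_allele_count),
                 min_allele_freq = min_allele_freq,
                 per_pool_ceiling = per_pool_ceiling),
            class = "site_filter_config")
}

#' Per-chromosome coverage ceilings
#'
#' Empirical `q`-quantile (linear interpolation, [stats::quantile()] type 7)
#' of total-across-pools A/T/C/G coverage, computed separately per
#' chromosome.
#'
#' @param sites A `sync_sites` object.
#' @param q Quantile in (0, 1].
#' @return Named numeric vector, one ceiling per chromosome present.
#' @export
max_cov_thresholds <- function(sites, q = 0.95) {
  tot <- site_total_coverage(sites)
  tapply(tot, sites$chrom, quantile, probs = q, names = FALSE)
}

# Total A/T/C/G coverage per site, summed across pools (N/del excluded).
site_total_coverage <- function(sites) {
  acgt <- sites$counts[, 1:4, , drop = FALSE]
  apply(acgt, 1L, sum)
}

#' Call biallelic SNPs from sync sites
#'
#' A site is retained iff its total A/T/C/G coverage (summed across pools)
#' is `>= min_total_cov` and strictly below its chromosome's coverage
#' ceiling. An allele is called iff its count summed across pools is
#' `>= min_allele_count` and its pooled frequency strictly exceeds
#' `min_allele_freq`. Sites with exactly two called alleles become SNP
#' records (major = larger pooled count, ties broken in A,T,C,G order);
#' sites with more than two called alleles are dropped and tallied.
#'
#' @param sites A `sync_sites` object.
#' @param cfg A [site_filter_config()].
#' @return A `snp_set`: list with `info` (`data.table`: chrom, pos, major,
#'   minor), count matrices `maj` and `mino` (sites x pools), `pools`,
#'   and `n_multiallelic` (dropped sites with > 2 called alleles).
#' @export
call_snps <- function(sites, cfg = site_filter_config()) {
  n <- n_sites(sites)
  k <- length(sites$pools)
  acgt <- sites$counts[, 1:4, , drop = FALSE]
  pooled <- apply(acgt, c(1L, 2L), sum)          # site x 4 allele totals
  if (n == 0L) pooled <- matrix(0L, 0L, 4L)
  tot <- rowSums(pooled)

  if (cfg$per_pool_ceiling) {
    # alternative reading: ceiling on each pool's own coverage, from the
    # per-chromosome quantile of the per-pool coverage distribution
    pool_cov <- apply(acgt, c(1L, 3L), sum)      # site x pool coverage
    ceilings <- tapply(as.vector(pool_cov),
                       rep(sites$chrom, times = k),
                       quantile, probs = cfg$max_cov_quantile, names = FALSE)
    under <- rowSums(pool_cov >= ceilings[sites$chrom]) == 0L
  } else {
    ceilings <- if (n > 0L) max_cov_thresholds(sites, cfg$max_cov_quantile)
                else numeric(0)
    under <- tot < ceilings[sites$chrom]
  }
  cov_ok <- tot >= cfg$min_total_cov & under

  freq <- pooled / pmax(tot, 1L)
  called <- pooled >= cfg$min_allele_count & freq > cfg$min_allele_freq
  n_called <- rowSums(called)

  keep <- cov_ok & n_called == 2L
  n_multi <- sum(cov_ok & n_called > 2L)

  idx <- which(keep)
  if (length(idx) == 0L) {
    return(structure(list(
      info = data.table::data.table(chrom = character(0), pos = integer(0),
                                    major = character(0),
                                    minor = character(0)),
      maj = matrix(0L, 0L, k, dimnames = list(NULL, sites$pools)),
      mino = matrix(0L, 0L, k, dimnames = list(NULL, sites$pools)),
      pools = sites$pools, n_multiallelic = n_multi), class = "snp_set"))
  }
  a1 <- a2 <- integer(length(idx))
  for (i in seq_along(idx)) {
    al <- which(called[idx[i], ])
    # major = larger pooled count; tie broken by A,T,C,G order (which())
    if (pooled[idx[i], al[2L]] > pooled[idx[i], al[1L]]) al <- rev(al)
    a1[i] <- al[1L]; a2[i] <- al[2L]
  }
  maj <- mino <- matrix(0L, length(idx), k,
                        dimnames = list(NULL, sites$pools))
  for (j in seq_len(k)) {
    maj[, j] <- acgt[cbind(idx, a1, j)]
    mino[, j] <- acgt[cbind(idx, a2, j)]
  }
  structure(list(
    info = data.table::data.table(chrom = sites$chrom[idx],
                                  pos = sites$pos[idx],
                                  major = NUCS[a1], minor = NUCS[a2]),
    maj = maj, mino = mino, pools = sites$pools,
    n_multiallelic = n_multi), class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat("snp_set:", nrow(x$info), "SNPs,", length(x$pools), "pools;",
      x$n_multiallelic, "multi-allelic sites dropped\n")
  invisible(x)
}

#' Number of SNPs in a snp_set
#' @param snps A `snp_set`.
#' @return Integer SNP count.
#' @export
n_snps <- function(snps) nrow(snps$info)

#' Subset a snp_set by row index
#' @param snps A `snp_set`.
#' @param i Integer or logical index over SNP rows.
#' @return A `snp_set` with the selected SNPs.
#' @export
subset_snps <- function(snps, i) {
  structure(list(info = snps$info[i],
                 maj = snps$maj[i, , drop = FALSE],
                 mino = snps$mino[i, , drop = FALSE],
                 pools = snps$pools,
                 n_multiallelic = snps$n_multiallelic), class = "snp_set")
}
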