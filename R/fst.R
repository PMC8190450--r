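# Pairwise pool FST from identity probabilities, window averages, the
# neutral X-chromosome expectation F_X and its bootstrap band, and X:A
# ratios.

#' Per-SNP pairwise pool FST
#'
#' Analysis-of-variance estimator in the identity-probability formulation.
#' Within each pool, the probability that two distinct reads carry the same
#' allele is corrected for reads resampling the same pool chromosome
#' (`Q1 = (Q1_reads - 1/n) / (1 - 1/n)` with `n = 2 * pool_size`
#' chromosomes); between pools two reads are already two distinct
#' population chromosomes. `FST = (mean(Q1) - Q2) / (1 - Q2)`; may be
#' negative and is not clamped.
#'
#' @param maj1,min1 Major/minor read counts in pool 1 (vectors).
#' @param maj2,min2 Major/minor read counts in pool 2.
#' @param pool_size1,pool_size2 Diploid pool sizes.
#' @return Per-SNP FST; `NA` where a pool has coverage < 2 or both pools
#'   are fixed for the same allele (Q2 = 1).
#' @export
snp_fst <- function(maj1, min1, maj2, min2, pool_size1, pool_size2) {
  c1 <- maj1 + min1
  c2 <- maj2 + min2
  q1r_1 <- (maj1 * (maj1 - 1) + min1 * (min1 - 1)) / (c1 * (c1 - 1))
  q1r_2 <- (maj2 * (maj2 - 1) + min2 * (min2 - 1)) / (c2 * (c2 - 1))
  n1 <- 2 * pool_size1
  n2 <- 2 * pool_size2
  q1_1 <- (q1r_1 - 1 / n1) / (1 - 1 / n1)
  q1_2 <- (q1r_2 - 1 / n2) / (1 - 1 / n2)
  q1 <- (q1_1 + q1_2) / 2
  q2 <- (maj1 * maj2 + min1 * min2) / (c1 * c2)
  fst <- (q1 - q2) / (1 - q2)
  fst[c1 < 2 | c2 < 2 | q2 >= 1] <- NA_real_
  fst
}

#' Per-SNP FST for every replicate E/M pair
#'
#' @param snps A `snp_set`.
#' @param sheet Paired sample sheet.
#' @return `data.table`: chrom, pos, replicate, fst.
#' @export
replicate_pair_fst <- function(snps, sheet) {
  sheet <- validate_sample_sheet(sheet, paired = TRUE)
  stopifnot(identical(sheet$pool_id, snps$pools))
  data.table::rbindlist(lapply(unique(sheet$replicate), function(r) {
    e <- which(sheet$treatment == "E" & sheet$replicate == r)
    m <- which(sheet$treatment == "M" & sheet$replicate == r)
    data.table::data.table(
      chrom = snps$info$chrom, pos = snps$info$pos, replicate = r,
      fst = snp_fst(snps$maj[, e], snps$mino[, e],
                    snps$maj[, m], snps$mino[, m],
                    sheet$pool_size[e], sheet$pool_size[m]))
  }))
}

#' Window-average FST
#'
#' Arithmetic mean of per-SNP FST within each window (average of ratios),
#' per grouping column when present; windows without SNPs are missing.
#'
#' @param fst_records `data.table` with chrom, pos, fst and optionally a
#'   grouping column (e.g. `replicate`).
#' @param windows Window plan from [window_plan()].
#' @param group_col Optional grouping column name.
#' @return `data.table`: chrom, start, end, (group), n_snps, fst.
#' @export
window_fst <- function(fst_records, windows, group_col = NULL) {
  fr <- data.table::as.data.table(fst_records)
  win <- data.table::copy(data.table::as.data.table(windows))
  win[, win_id := .I]
  data.table::setkey(win, chrom, start, end)
  dt <- fr[, .(chrom, start = pos, end = pos, fst)]
  if (!is.null(group_col)) dt[, (group_col) := fr[[group_col]]]
  ov <- data.table::foverlaps(dt, win, type = "within", nomatch = NULL)
  by_cols <- c("win_id", group_col)
  agg <- ov[, .(n_snps = sum(!is.na(fst)),
                fst = mean(fst, na.rm = TRUE)), by = by_cols]
  agg[is.nan(fst), fst := NA_real_]
  if (is.null(group_col)) {
    base <- win[, .(win_id, chrom, start, end)]
  } else {
    base <- data.table::CJ(win_id = win$win_id,
                           grp = unique(fr[[group_col]]))
    data.table::setnames(base, "grp", group_col)
    base <- merge(base, win[, .(win_id, chrom, start, end)], by = "win_id")
  }
  res <- merge(base, agg, by = by_cols, all.x = TRUE)
  res[is.na(n_snps), n_snps := 0L]
  res[, win_id := NULL]
  data.table::setcolorder(res, c("chrom", "start", "end"))
  data.table::setorderv(res, c(group_col, "chrom", "start"))
  res[]
}

#' Neutral X-chromosome FST expectation
#'
#' `F_X = 1 - 9(z+1)(1-F_A) / (8(2z+1) - (1-F_A)(7z-1))`, the FST expected
#' on the X under drift alone given the observed autosomal FST `f_a` and
#' the ratio `z` of breeding males to females. At `f_a = 0` this is 0 and
#' at `f_a = 1` it is 1 for any `z`.
#'
#' @param f_a Observed autosomal FST in `[0, 1]`.
#' @param z Ratio of breeding males to females (> 0).
#' @return Expected X-chromosome FST.
#' @export
fx_expected <- function(f_a, z) {
  stopifnot(all(f_a >= 0), all(f_a <= 1), all(z > 0))
  den <- 8 * (2 * z + 1) - (1 - f_a) * (7 * z - 1)
  if (any(den <= 0)) stop("F_X denominator not positive")
  1 - 9 * (z + 1) * (1 - f_a) / den
}

#' Bootstrap band for the neutral X expectation
#'
#' Per replicate pair and `z`: the observed autosomal mean window FST is
#' converted to `F_X`; for each of `n_boot` iterations, a number of windows
#' equal to the autosomal window count is drawn with replacement from the
#' set of all windows (X included, unless `autosomes_only`), the mean FST
#' converted via [fx_expected()], and the 95% percentile interval reported.
#' Bootstrap means are clamped to `[0, 1]` before conversion.
#'
#' @param win_fst Window FST table (chrom, fst, optional group column).
#' @param x_chroms Chromosome names treated as X-linked.
#' @param z Breeding-sex-ratio values (default `c(1, 6)`).
#' @param n_boot Bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param group_col Optional grouping column (e.g. `replicate`).
#' @param autosomes_only If `TRUE`, resample autosomal windows only.
#' @return `data.table`: (group), z, f_a, f_x_expected, ci_low, ci_high,
#'   f_x_observed.
#' @export
bootstrap_fx <- function(win_fst, x_chroms = c("XL", "XR"), z = c(1, 6),
                         n_boot = 1000L, seed = 1L, group_col = NULL,
                         autosomes_only = FALSE) {
  wf <- data.table::as.data.table(win_fst)
  set.seed(seed)
  groups <- if (is.null(group_col)) list(NULL) else unique(wf[[group_col]])
  out <- list()
  for (g in groups) {
    sub <- if (is.null(group_col)) wf else wf[wf[[group_col]] == g]
    auto <- sub[!chrom %in% x_chroms & !is.na(fst)]
    xwin <- sub[chrom %in% x_chroms & !is.na(fst)]
    if (nrow(auto) == 0L) stop("no autosomal windows with FST")
    pool <- if (autosomes_only) auto$fst else sub[!is.na(fst)]$fst
    f_a <- mean(auto$fst)
    f_x_obs <- if (nrow(xwin)) mean(xwin$fst) else NA_real_
    boots <- vapply(seq_len(n_boot), function(b)
      mean(sample(pool, nrow(auto), replace = TRUE)), numeric(1))
    boots <- pmin(pmax(boots, 0), 1)
    for (zz in z) {
      fx_b <- fx_expected(boots, zz)
      ci <- quantile(fx_b, c(0.025, 0.975), names = FALSE)
      row <- data.table::data.table(
        z = zz, f_a = f_a,
        f_x_expected = fx_expected(min(max(f_a, 0), 1), zz),
        ci_low = ci[1], ci_high = ci[2], f_x_observed = f_x_obs)
      if (!is.null(group_col)) row[, (group_col) := g]
      out[[length(out) + 1L]] <- row
    }
  }
  data.table::rbindlist(out, use.names = TRUE)
}

#' X : autosome ratio of a window statistic
#'
#' Ratio of the X-window mean to the autosomal-window mean, with a
#' percentile bootstrap 95% CI resampling windows within each stratum.
#'
#' @param win_stats Window table (chrom + value column).
#' @param stat_col Value column name (e.g. `"fst"` or `"pi"`).
#' @param x_chroms X-linked chromosome names.
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @return List: ratio, ci_low, ci_high, mean_x, mean_auto.
#' @export
xa_ratio <- function(win_stats, stat_col = "fst", x_chroms = c("XL", "XR"),
                     n_boot = 1000L, seed = 1L) {
  ws <- data.table::as.data.table(win_stats)
  v <- ws[[stat_col]]
  x <- v[ws$chrom %in% x_chroms & !is.na(v)]
  a <- v[!ws$chrom %in% x_chroms & !is.na(v)]
  if (length(x) == 0L || length(a) == 0L)
    stop("both X and autosomal strata must be non-empty")
  if (mean(a) == 0) stop("autosome mean is zero; ratio undefined")
  set.seed(seed)
  ratios <- vapply(seq_len(n_boot), function(b)
    mean(sample(x, length(x), replace = TRUE)) /
      mean(sample(a, length(a), replace = TRUE)), numeric(1))
  ci <- quantile(ratios, c(0.025, 0.975), names = FALSE)
  list(ratio = mean(x) / mean(a), ci_low = ci[1], ci_high = ci[2],
       mean_x = mean(x), mean_auto = mean(a))
}
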