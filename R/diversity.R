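# Pool-corrected nucleotide diversity (pi), Watterson's theta and Tajima's
# D in overlapping 50-kb windows, per-gene summaries and in/out-of-peak
# contrasts. Corrections follow the two-stage unbiasing used by the
# PoPoolation family: reads sampled from the pool, pool sampled from the
# population.

#' Classical Tajima constants for sample size n
#'
#' @param n Number of sampled chromosomes (here `2 * pool_size`).
#' @return List with a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Pool-corrected per-site diversity
#'
#' `pi_site = C/(C-1) * 2*p*(1-p) * 2n/(2n-1)` with `p = major / C`,
#' read coverage `C = major + minor` and `n = pool_size` diploids: the
#' first factor unbiases read sampling from the pool, the last pool
#' sampling from the population.
#'
#' @param major,minor Read counts (vectors).
#' @param pool_size Diploid individuals in the pool.
#' @return Per-site pi; `NA` where coverage < 2 (site skipped).
#' @export
site_pi <- function(major, minor, pool_size) {
  cov <- major + minor
  p <- major / cov
  out <- cov / (cov - 1) * 2 * p * (1 - p) *
    (2 * pool_size) / (2 * pool_size - 1)
  out[cov < 2] <- NA_real_
  out
}

#' Overlapping window plan
#'
#' Tiles each chromosome with windows of `window_bp` starting every
#' `step_bp` (default 50 kb windows, 40 kb step, i.e. 10 kb overlap);
#' the last partial window is kept and flagged.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param window_bp Window length.
#' @param step_bp Step between window starts.
#' @return `data.table`: chrom, start, end (1-based inclusive), partial.
#' @export
window_plan <- function(chrom_lengths, window_bp = 50000L, step_bp = 40000L) {
  data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, max(len, 1L), by = step_bp)
    starts <- starts[starts <= len]
    ends <- pmin(starts + window_bp - 1L, len)
    data.table::data.table(chrom = ch, start = as.integer(starts),
                           end = as.integer(ends),
                           partial = ends - starts + 1L < window_bp)
  }))
}

#' Windowed pool diversity statistics
#'
#' For each pool and window: pi (sum of pool-corrected site pi over SNPs in
#' the window, divided by the number of adequately covered sites if a
#' coverage mask is supplied, else by the window length), Watterson's
#' theta_w = S / a1(2n) where S counts SNPs segregating within the pool
#' (coverage >= 2, both alleles seen), and Tajima's D from the classical
#' variance with sample size 2n. D is missing when S < `min_snps`.
#'
#' @param snps A `snp_set`.
#' @param sheet Sample sheet (pool sizes).
#' @param windows Window plan from [window_plan()].
#' @param min_snps Minimum segregating sites for a D estimate (default 10).
#' @param covered_sites Optional `data.table` (chrom, pos) of all adequately
#'   covered sites (monomorphic included) defining the pi denominator.
#' @return `data.table`: chrom, start, end, pool, n_snps, pi (per bp or per
#'   covered site), theta_w (same scale), tajd.
#' @export
window_diversity <- function(snps, sheet, windows, min_snps = 10L,
                             covered_sites = NULL) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(identical(sheet$pool_id, snps$pools))
  win <- data.table::copy(data.table::as.data.table(windows))
  win[, win_id := .I]
  data.table::setkey(win, chrom, start, end)
  denom <- if (is.null(covered_sites)) {
    win[, .(win_id, denom = end - start + 1L)]
  } else {
    cs <- data.table::as.data.table(covered_sites)
    cs <- cs[, .(chrom, start = pos, end = pos)]
    ov <- data.table::foverlaps(cs, win, type = "within", nomatch = NULL)
    d <- ov[, .(denom = .N), by = win_id]
    merge(win[, .(win_id)], d, by = "win_id", all.x = TRUE)[
      , .(win_id, denom = data.table::fifelse(is.na(denom), 0L, denom))]
  }
  out <- vector("list", nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    n2 <- 2L * sheet$pool_size[j]
    const <- tajima_constants(n2)
    maj <- snps$maj[, j]; mino <- snps$mino[, j]
    sp <- site_pi(maj, mino, sheet$pool_size[j])
    seg <- (maj + mino) >= 2L & maj > 0L & mino > 0L
    dt <- data.table::data.table(chrom = snps$info$chrom,
                                 start = snps$info$pos,
                                 end = snps$info$pos,
                                 sp = sp, seg = seg)
    ov <- data.table::foverlaps(dt, win, type = "within", nomatch = NULL)
    agg <- ov[, .(pi_sum = sum(sp, na.rm = TRUE), s = sum(seg)),
              by = win_id]
    res <- merge(win, agg, by = "win_id", all.x = TRUE)
    res[is.na(pi_sum), `:=`(pi_sum = 0, s = 0L)]
    res <- merge(res, denom, by = "win_id")
    res[, theta_sum := s / const$a1]
    res[, vd := const$e1 * s + const$e2 * s * (s - 1)]
    res[, tajd := data.table::fifelse(
      s >= min_snps & vd > 0, (pi_sum - theta_sum) / sqrt(vd), NA_real_)]
    out[[j]] <- res[, .(chrom, start, end, pool = sheet$pool_id[j],
                        n_snps = s,
                        pi = data.table::fifelse(denom > 0, pi_sum / denom,
                                                 NA_real_),
                        theta_w = data.table::fifelse(denom > 0,
                                                      theta_sum / denom,
                                                      NA_real_),
                        tajd)]
  }
  data.table::rbindlist(out)
}

#' Per-gene mean of a window statistic
#'
#' Unweighted mean of `stat_col` over every window whose span intersects
#' the gene span (>= 1 bp overlap), computed separately per `group_col`
#' (e.g. pool or replicate pair) when present.
#'
#' @param win_stats Window statistic table (chrom, start, end, value, and
#'   optionally a grouping column).
#' @param genes Gene annotation (`gene_id`, chrom, start, end).
#' @param stat_col Name of the statistic column.
#' @param group_col Optional grouping column name.
#' @return `data.table`: gene_id, (group), mean_stat, n_windows; genes with
#'   no overlapping window get `NA` and `n_windows = 0`.
#' @export
gene_mean_stat <- function(win_stats, genes, stat_col = "tajd",
                           group_col = NULL) {
  ws <- data.table::as.data.table(win_stats)
  g <- data.table::as.data.table(genes)[, .(gene_id, chrom, start, end)]
  data.table::setkey(g, chrom, start, end)
  ov <- data.table::foverlaps(ws, g, type = "any", nomatch = NULL)
  by_cols <- c("gene_id", group_col)
  agg <- ov[, .(mean_stat = mean(.SD[[stat_col]], na.rm = TRUE),
                n_windows = .N), by = by_cols, .SDcols = stat_col]
  agg[is.nan(mean_stat), mean_stat := NA_real_]
  if (is.null(group_col)) {
    all_g <- g[, .(gene_id)]
  } else {
    all_g <- data.table::CJ(gene_id = g$gene_id,
                            grp = unique(ws[[group_col]]))
    data.table::setnames(all_g, "grp", group_col)
  }
  res <- merge(all_g, agg, by = by_cols, all.x = TRUE)
  res[is.na(n_windows), n_windows := 0L]
  res[]
}

#' Contrast a window statistic inside vs outside peak regions
#'
#' Windows are labelled in-peak iff they intersect any peak span. In
#' unpaired mode a Wilcoxon rank-sum test compares the in-peak and
#' out-of-peak values; in paired mode the per-group (e.g. per pool) in-peak
#' and out-of-peak means are compared with a Wilcoxon signed-rank test.
#'
#' @param win_stats Window statistic table (chrom, start, end, value,
#'   optional group column).
#' @param peaks Peak table (chrom, start, end).
#' @param stat_col Name of the value column.
#' @param paired If `TRUE`, pair per-group means.
#' @param group_col Grouping column for paired mode (default `"pool"`).
#' @return List: statistic (housed as V/W), p_value, mean_in, mean_out,
#'   n_in, n_out.
#' @export
region_contrast <- function(win_stats, peaks, stat_col = "tajd",
                            paired = FALSE, group_col = "pool") {
  ws <- data.table::copy(data.table::as.data.table(win_stats))
  pk <- data.table::as.data.table(peaks)
  ws[, in_peak := FALSE]
  if (nrow(pk) > 0L) {
    p2 <- pk[, .(chrom, start, end)]
    data.table::setkey(p2, chrom, start, end)
    ov <- data.table::foverlaps(
      ws[, .(chrom, start, end, row = .I)], p2, type = "any",
      nomatch = NULL)
    ws$in_peak[unique(ov$row)] <- TRUE
  }
  vals <- ws[[stat_col]]
  x <- vals[ws$in_peak & !is.na(vals)]
  y <- vals[!ws$in_peak & !is.na(vals)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 windows with values in each stratum")
  if (paired) {
    gi <- ws[in_peak == TRUE,
             .(m = mean(.SD[[stat_col]], na.rm = TRUE)),
             by = group_col, .SDcols = stat_col]
    go <- ws[in_peak == FALSE,
             .(m = mean(.SD[[stat_col]], na.rm = TRUE)),
             by = group_col, .SDcols = stat_col]
    mm <- merge(gi, go, by = group_col)
    wt <- suppressWarnings(wilcox.test(mm$m.x, mm$m.y, paired = TRUE))
  } else {
    wt <- suppressWarnings(wilcox.test(x, y))
  }
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       mean_in = mean(x), mean_out = mean(y),
       n_in = length(x), n_out = length(y))
}
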