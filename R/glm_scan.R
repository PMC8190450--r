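# Per-SNP quasibinomial GLM scan of major-allele frequency on treatment,
# Storey q-values, treatment-label permutation nulls, 50-kb clustering of
# top SNPs into peaks, and the associated sanity checks.
#
# For a saturated two-group binomial-logit model the IRLS fixed point is the
# group-pooled frequency, so the fit is computed in closed form and
# vectorised across SNPs; stats::glm(family = quasibinomial) serves as the
# independent oracle in the test suite.

# Apply the pseudocount rule: if any major or minor count of a SNP is zero,
# add 1 to every major and minor count of that SNP ("all" scope), or only
# to the pools that contain a zero ("per_pool" alternative).
apply_pseudocount <- function(maj, mino, scope = c("all", "per_pool")) {
  scope <- match.arg(scope)
  zero <- maj == 0L | mino == 0L
  if (scope == "all") {
    rows <- rowSums(zero) > 0L
    maj[rows, ] <- maj[rows, , drop = FALSE] + 1L
    mino[rows, ] <- mino[rows, , drop = FALSE] + 1L
  } else {
    maj[zero] <- maj[zero] + 1L
    mino[zero] <- mino[zero] + 1L
  }
  list(maj = maj, mino = mino)
}

# Closed-form two-group quasibinomial fit, vectorised over SNP rows.
# e_set: logical vector over pools marking the E group.
quasibinomial_two_group <- function(maj, mino, e_set) {
  k <- ncol(maj)
  stopifnot(length(e_set) == k, sum(e_set) >= 1, sum(!e_set) >= 1)
  cov <- maj + mino
  se_maj <- rowSums(maj[, e_set, drop = FALSE])
  se_tot <- rowSums(cov[, e_set, drop = FALSE])
  sm_maj <- rowSums(maj[, !e_set, drop = FALSE])
  sm_tot <- rowSums(cov[, !e_set, drop = FALSE])
  p_e <- se_maj / se_tot
  p_m <- sm_maj / sm_tot
  beta <- log(p_e / (1 - p_e)) - log(p_m / (1 - p_m))
  # Pearson X^2 against fitted group frequencies
  fitted <- matrix(p_m, nrow(maj), k)
  fitted[, e_set] <- p_e
  x2 <- rowSums((maj - cov * fitted)^2 / (cov * fitted * (1 - fitted)))
  df <- k - 2L
  if (df < 1L) stop("need at least 3 pools for a dispersion estimate")
  phi <- x2 / df
  var_beta <- phi * (1 / (se_tot * p_e * (1 - p_e)) +
                       1 / (sm_tot * p_m * (1 - p_m)))
  tstat <- beta / sqrt(var_beta)
  tstat[beta == 0] <- 0          # exact balance: 0/0 -> no effect
  p <- 2 * pt(-abs(tstat), df)
  list(beta = beta, phi = phi, t = tstat, p = p, df = df,
       p_e = p_e, p_m = p_m)
}

#' Quasibinomial GLM scan over all SNPs
#'
#' Fits, per SNP, a binomial-logit GLM of per-pool (major, minor) counts on
#' treatment with a quasi-likelihood dispersion (Pearson chi-square /
#' (n_pools - 2)) and a dispersion-scaled t test of the treatment
#' coefficient. Before fitting, the pseudocount rule is applied: if any
#' major or minor count of a SNP is zero, +1 is added to all of that SNP's
#' major and minor counts. The dispersion is not floored at 1.
#'
#' @param snps A `snp_set` from [call_snps()].
#' @param sheet Sample sheet matching the snp_set pools.
#' @param q_threshold Top-SNP q-value threshold (default 0.05).
#' @param pseudocount_scope `"all"` (default) or `"per_pool"`.
#' @param qvalues If `TRUE` (default), append Storey q-values and the
#'   `is_top` flag.
#' @return `data.table`: chrom, pos, beta_treatment (log-odds, E minus M),
#'   dispersion_phi, t, p_value, and (with `qvalues`) q_value and is_top.
#' @export
glm_scan <- function(snps, sheet, q_threshold = 0.05,
                     pseudocount_scope = "all", qvalues = TRUE) {
  sheet <- validate_sample_sheet(sheet)
  stopifnot(identical(sheet$pool_id, snps$pools))
  pc <- apply_pseudocount(snps$maj, snps$mino, pseudocount_scope)
  fit <- quasibinomial_two_group(pc$maj, pc$mino, sheet$treatment == "E")
  out <- data.table::data.table(
    chrom = snps$info$chrom, pos = snps$info$pos,
    beta_treatment = fit$beta, dispersion_phi = fit$phi,
    t = fit$t, p_value = fit$p)
  if (qvalues) {
    out[, q_value := storey_qvalues(p_value)]
    out[, is_top := q_value < q_threshold]
  }
  out[]
}

#' Fit the treatment GLM for a single SNP
#'
#' Single-SNP convenience wrapper around the vectorised scan (no q-value).
#'
#' @param major,minor Per-pool major/minor count vectors.
#' @param sheet Sample sheet (pool order matching the count vectors).
#' @param pseudocount_scope `"all"` (default) or `"per_pool"`.
#' @return List: beta_treatment, dispersion_phi, t, p_value, df.
#' @export
fit_snp_glm <- function(major, minor, sheet, pseudocount_scope = "all") {
  sheet <- validate_sample_sheet(sheet)
  if (nrow(sheet) < 3L) stop("need at least 3 pools (degrees of freedom)")
  pc <- apply_pseudocount(matrix(major, 1L), matrix(minor, 1L),
                          pseudocount_scope)
  fit <- quasibinomial_two_group(pc$maj, pc$mino, sheet$treatment == "E")
  list(beta_treatment = fit$beta, dispersion_phi = fit$phi, t = fit$t,
       p_value = fit$p, df = fit$df)
}

#' Storey-Tibshirani q-values
#'
#' pi0 is estimated as `mean(p > lambda) / (1 - lambda)` over
#' `lambda = 0, 0.05, ..., 0.90`, smoothed with a cubic smoothing spline
#' (df = 3) and evaluated at lambda = 0.90, clipped to (0, 1]. q-values are
#' the step-up minima `min_{j >= i} pi0 * m * p_(j) / j` mapped back to
#' input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
storey_qvalues <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1] and non-missing")
  m <- length(p)
  lambda <- seq(0, 0.90, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- if (m < 2L || length(unique(pi0_l)) == 1L) {
    pi0_l[length(pi0_l)]
  } else {
    fit <- smooth.spline(lambda, pi0_l, df = 3)
    predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Enumerate treatment-label permutations for a balanced design
#'
#' All assignments of the k "E" labels among the 2k pools, excluding the
#' observed assignment and its exact complement, in deterministic
#' lexicographic order. For the 4-vs-4 design this gives C(8,4) - 2 = 68.
#'
#' @param sheet Sample sheet with a balanced E/M design.
#' @return Logical matrix, one row per permutation, one column per pool
#'   (TRUE = relabelled "E").
#' @export
enumerate_label_permutations <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  k2 <- nrow(sheet)
  k <- sum(sheet$treatment == "E")
  if (k != k2 - k)
    stop("permutation scheme is defined only for balanced designs")
  sets <- combn(k2, k)
  obs <- which(sheet$treatment == "E")
  comp <- which(sheet$treatment == "M")
  keep <- vapply(seq_len(ncol(sets)), function(i) {
    !identical(sets[, i], obs) && !identical(sets[, i], comp)
  }, logical(1))
  sets <- sets[, keep, drop = FALSE]
  out <- matrix(FALSE, ncol(sets), k2)
  for (i in seq_len(ncol(sets))) out[i, sets[, i]] <- TRUE
  colnames(out) <- sheet$pool_id
  out
}

#' Permutation null for the GLM scan
#'
#' In `whole_genome` mode every SNP is refit under one shared relabelling
#' per permutation (preserving cross-SNP allele-frequency correlation); in
#' `per_snp` mode each SNP draws an independent relabelling per iteration.
#' Returns, per permutation, the count of SNPs with p below `alpha` and
#' optionally the q-value-based top-SNP set.
#'
#' @param snps A `snp_set`.
#' @param sheet Sample sheet.
#' @param mode `"whole_genome"` or `"per_snp"`.
#' @param n_perm Number of permutations; defaults to all enumerable
#'   relabellings in whole-genome mode (required in per-SNP mode).
#' @param seed Seed (required in per-SNP mode).
#' @param alpha p-value threshold for the per-permutation counts.
#' @param q_threshold Top-SNP threshold when `return_top = TRUE`.
#' @param return_top If `TRUE`, also return per-permutation top-SNP index
#'   sets (q < `q_threshold`).
#' @param pseudocount_scope Passed to the fit.
#' @return List: `observed` (count at the true labels), `counts` (per
#'   permutation), optionally `top_sets`.
#' @export
permutation_scan <- function(snps, sheet, mode = c("whole_genome", "per_snp"),
                             n_perm = NULL, seed = NULL, alpha = 0.05,
                             q_threshold = 0.05, return_top = FALSE,
                             pseudocount_scope = "all") {
  mode <- match.arg(mode)
  sheet <- validate_sample_sheet(sheet)
  perms <- enumerate_label_permutations(sheet)
  pc <- apply_pseudocount(snps$maj, snps$mino, pseudocount_scope)
  obs_fit <- quasibinomial_two_group(pc$maj, pc$mino,
                                     sheet$treatment == "E")
  observed <- sum(obs_fit$p < alpha, na.rm = TRUE)
  if (mode == "whole_genome") {
    if (is.null(n_perm)) n_perm <- nrow(perms)
    if (n_perm > nrow(perms))
      stop("n_perm exceeds the ", nrow(perms), " available relabellings")
    counts <- integer(n_perm)
    top_sets <- if (return_top) vector("list", n_perm) else NULL
    for (b in seq_len(n_perm)) {
      fit <- quasibinomial_two_group(pc$maj, pc$mino, perms[b, ])
      counts[b] <- sum(fit$p < alpha, na.rm = TRUE)
      if (return_top)
        top_sets[[b]] <- which(storey_qvalues(fit$p) < q_threshold)
    }
  } else {
    if (is.null(seed)) stop("seed is required in per-snp mode")
    if (is.null(n_perm)) stop("n_perm is required in per-snp mode")
    set.seed(seed)
    n <- nrow(pc$maj)
    counts <- integer(n_perm)
    top_sets <- if (return_top) vector("list", n_perm) else NULL
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nrow(perms), n, replace = TRUE)
      e_ind <- perms[idx, , drop = FALSE]
      p <- per_snp_relabel_pvalues(pc$maj, pc$mino, e_ind)
      counts[b] <- sum(p < alpha, na.rm = TRUE)
      if (return_top) top_sets[[b]] <- which(storey_qvalues(p) < q_threshold)
    }
  }
  out <- list(observed = observed, counts = counts)
  if (return_top) out$top_sets <- top_sets
  out
}

# Two-group fit where each SNP row has its own E/M relabelling (e_ind is a
# logical matrix, SNPs x pools).
per_snp_relabel_pvalues <- function(maj, mino, e_ind) {
  cov <- maj + mino
  k <- ncol(maj)
  se_maj <- rowSums(maj * e_ind)
  se_tot <- rowSums(cov * e_ind)
  sm_maj <- rowSums(maj * !e_ind)
  sm_tot <- rowSums(cov * !e_ind)
  p_e <- se_maj / se_tot
  p_m <- sm_maj / sm_tot
  beta <- log(p_e / (1 - p_e)) - log(p_m / (1 - p_m))
  fitted <- e_ind * p_e + (!e_ind) * p_m
  x2 <- rowSums((maj - cov * fitted)^2 / (cov * fitted * (1 - fitted)))
  df <- k - 2L
  phi <- x2 / df
  var_beta <- phi * (1 / (se_tot * p_e * (1 - p_e)) +
                       1 / (sm_tot * p_m * (1 - p_m)))
  tstat <- beta / sqrt(var_beta)
  tstat[beta == 0] <- 0
  2 * pt(-abs(tstat), df)
}

#' Cluster top SNPs into divergence peaks
#'
#' Single-linkage chaining: consecutive top SNPs on the same chromosome
#' join one cluster iff their gap is `<= link_bp` (inclusive at exactly
#' `link_bp`). The peak span is `[min pos, max pos]` of its members.
#'
#' @param top `data.table`/data.frame with columns `chrom`, `pos` for the
#'   top SNPs.
#' @param link_bp Linking distance in bp (default 50000).
#' @param peak_min Clusters with more than `peak_min` member SNPs are
#'   flagged as peaks (default 10, i.e. "> 10 SNPs").
#' @return `data.table`: peak_id, chrom, start, end, n_snps, is_peak.
#' @export
cluster_top_snps <- function(top, link_bp = 50000L, peak_min = 10L) {
  top <- data.table::copy(data.table::as.data.table(top))
  if (nrow(top) == 0L)
    return(data.table::data.table(peak_id = integer(0), chrom = character(0),
                                  start = integer(0), end = integer(0),
                                  n_snps = integer(0), is_peak = logical(0)))
  data.table::setorder(top, chrom, pos)
  top[, cl := cumsum(c(1L, diff(pos) > link_bp)), by = chrom]
  peaks <- top[, .(start = min(pos), end = max(pos), n_snps = .N),
               by = .(chrom, cl)]
  peaks[, peak_id := .I]
  peaks[, is_peak := n_snps > peak_min]
  peaks[, cl := NULL]
  data.table::setcolorder(peaks, c("peak_id", "chrom", "start", "end",
                                   "n_snps", "is_peak"))
  peaks[]
}

#' Per-chromosome excess of top SNPs
#'
#' Exact binomial test of each chromosome's top-SNP count against the
#' expectation proportional to its share of background SNPs; two-sided
#' p-values, Bonferroni-adjusted across chromosomes.
#'
#' @param top_counts Named vector of top-SNP counts per chromosome.
#' @param background_counts Named vector of background SNP counts per
#'   chromosome (all called SNPs).
#' @return `data.table`: chrom, n_top, n_background, expected_share,
#'   p_value, p_adj.
#' @export
chromosome_excess_test <- function(top_counts, background_counts) {
  chroms <- names(background_counts)
  stopifnot(!is.null(chroms), all(background_counts > 0))
  n_top <- sum(top_counts)
  out <- data.table::rbindlist(lapply(chroms, function(ch) {
    x <- if (ch %in% names(top_counts)) top_counts[[ch]] else 0L
    share <- background_counts[[ch]] / sum(background_counts)
    p <- binom.test(x, n_top, p = share)$p.value
    data.table::data.table(chrom = ch, n_top = x,
                           n_background = background_counts[[ch]],
                           expected_share = share, p_value = p)
  }))
  out[, p_adj := p.adjust(p_value, "bonferroni")]
  out[]
}

#' Compare coverage inside peaks to random regions
#'
#' Draws `n_random` non-peak regions with lengths resampled from the peak
#' length distribution, placed uniformly on the chromosomes carrying sites,
#' and compares mean site coverage inside peaks vs inside the random
#' regions with a Wilcoxon rank-sum test.
#'
#' @param peaks Peak table from [cluster_top_snps()].
#' @param sites A `sync_sites` object (coverage source).
#' @param n_random Number of random regions (> 0).
#' @param seed Integer seed.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   defaults to the maximum site position per chromosome.
#' @return List: `peak_cov` and `random_cov` (mean coverage per region),
#'   `statistic`, `p_value`.
#' @export
peak_coverage_check <- function(peaks, sites, n_random = 100L, seed = 1L,
                                chrom_lengths = NULL) {
  if (nrow(peaks) == 0L) stop("no peaks supplied")
  if (n_random < 1L) stop("n_random must be positive")
  set.seed(seed)
  cov_dt <- data.table::data.table(chrom = sites$chrom, pos = sites$pos,
                                   cov = site_total_coverage(sites))
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(cov_dt$pos, cov_dt$chrom, max)
  region_mean <- function(ch, s, e)
    cov_dt[chrom == ch & pos >= s & pos <= e, mean(cov)]
  peak_cov <- vapply(seq_len(nrow(peaks)), function(i)
    region_mean(peaks$chrom[i], peaks$start[i], peaks$end[i]), numeric(1))
  lens <- peaks$end - peaks$start + 1L
  chroms <- names(chrom_lengths)
  random_cov <- numeric(n_random)
  for (b in seq_len(n_random)) {
    len <- sample(lens, 1L)
    placed <- FALSE
    for (try in 1:200) {
      ch <- sample(chroms, 1L, prob = as.numeric(chrom_lengths))
      if (chrom_lengths[[ch]] <= len) next
      s <- sample.int(chrom_lengths[[ch]] - len, 1L)
      e <- s + len - 1L
      overlaps <- peaks[chrom == ch & start <= e & end >= s, .N] > 0L
      if (!overlaps) {
        m <- region_mean(ch, s, e)
        if (!is.nan(m)) { random_cov[b] <- m; placed <- TRUE; break }
      }
    }
    if (!placed) stop("could not place random region; genome too small")
  }
  wt <- suppressWarnings(wilcox.test(peak_cov, random_cov))
  list(peak_cov = peak_cov, random_cov = random_cov,
       statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Flag fixed differences between E and M lines
#'
#' A SNP is a fixed difference iff, within every replicate pair, the
#' observed major-allele frequency is 1 in all pools of one treatment and 0
#' in all pools of the other (evaluated on the raw counts, before any
#' pseudocount). Pools with zero coverage never qualify.
#'
#' @param snps A `snp_set`.
#' @param sheet Sample sheet (paired design).
#' @return Logical vector, one flag per SNP.
#' @export
fixed_difference_flags <- function(snps, sheet) {
  sheet <- validate_sample_sheet(sheet, paired = TRUE)
  stopifnot(identical(sheet$pool_id, snps$pools))
  cov <- snps$maj + snps$mino
  freq <- snps$maj / cov          # NaN when coverage 0
  flags <- rep(TRUE, nrow(snps$info))
  for (r in unique(sheet$replicate)) {
    e_cols <- which(sheet$treatment == "E" & sheet$replicate == r)
    m_cols <- which(sheet$treatment == "M" & sheet$replicate == r)
    fe <- freq[, e_cols, drop = FALSE]
    fm <- freq[, m_cols, drop = FALSE]
    e1 <- rowSums(fe == 1, na.rm = TRUE) == length(e_cols) &
      !apply(fe, 1L, anyNA)
    e0 <- rowSums(fe == 0, na.rm = TRUE) == length(e_cols) &
      !apply(fe, 1L, anyNA)
    m1 <- rowSums(fm == 1, na.rm = TRUE) == length(m_cols) &
      !apply(fm, 1L, anyNA)
    m0 <- rowSums(fm == 0, na.rm = TRUE) == length(m_cols) &
      !apply(fm, 1L, anyNA)
    flags <- flags & ((e1 & m0) | (e0 & m1))
  }
  flags
}
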