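# Classical (haplotype-matrix) Tajima's D, the oracle for the pooled
# estimator.
classical_tajima_d <- function(H) {
  n <- nrow(H)
  p <- colMeans(H)
  seg <- p > 0 & p < 1
  s <- sum(seg)
  const <- tajima_constants(n)
  pi_sum <- sum(2 * p[seg] * (1 - p[seg]) * n / (n - 1))
  theta <- s / const$a1
  (pi_sum - theta) / sqrt(const$e1 * s + const$e2 * s * (s - 1))
}

test_that("site pi applies read- and pool-sampling corrections", {
  expect_equal(site_pi(10, 0, 40), 0)
  # pool_size -> infinity limit of the stated formula
  expect_equal(site_pi(5, 5, 1e9), (10 / 9) * 0.5, tolerance = 1e-6)
  # both corrections vanish in the double limit
  expect_equal(site_pi(5e8, 5e8, 1e9), 0.5, tolerance = 1e-6)
  expect_true(is.na(site_pi(1, 0, 40)))
})

test_that("window plan tiles 50-kb windows every 40 kb with a kept partial", {
  w <- window_plan(c(chr = 130000L))
  expect_equal(w$start, c(1L, 40001L, 80001L, 120001L))
  expect_equal(w$end, c(50000L, 90000L, 130000L, 130000L))
  expect_equal(w$partial, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("pooled window Tajima's D tracks the haplotype-based classical D", {
  # one pool of 40 diploids; reads resample the 80-chromosome pool at 200x
  set.seed(31)
  n_hap <- 80L
  pool_sheet <- validate_sample_sheet(data.frame(
    pool_id = "p1", treatment = "E", replicate = 1, pool_size = 40))
  devs <- numeric(8)
  for (r in 1:8) {
    n_loci <- 120L
    pos <- sort(sample.int(50000L, n_loci))
    p_true <- rbeta(n_loci, 0.4, 0.4)
    H <- matrix(rbinom(n_hap * n_loci, 1, rep(p_true, each = n_hap)),
                nrow = n_hap)
    keep <- colMeans(H) > 0 & colMeans(H) < 1
    H <- H[, keep, drop = FALSE]; pos <- pos[keep]
    d_true <- classical_tajima_d(H)
    depth <- rpois(ncol(H), 200)
    maj_reads <- rbinom(ncol(H), depth, colMeans(H))
    snps <- structure(list(
      info = data.table::data.table(chrom = "2", pos = pos,
                                    major = "A", minor = "T"),
      maj = matrix(maj_reads, ncol = 1),
      mino = matrix(depth - maj_reads, ncol = 1),
      pools = "p1", n_multiallelic = 0L), class = "snp_set")
    win <- data.table::data.table(chrom = "2", start = 1L, end = 50000L,
                                  partial = FALSE)
    ws <- window_diversity(snps, pool_sheet, win, min_snps = 5)
    devs[r] <- ws$tajd - d_true
  }
  expect_lt(max(abs(devs)), 0.3)
})

test_that("windows without SNPs report zero pi and missing D", {
  sheet <- make_sheet(1)
  snps <- random_snp_set(20, sheet, seed = 3)
  snps$info[, chrom := "2"]
  snps$info[, pos := 1:20 * 100L]
  win <- window_plan(c("2" = 100000L, "9" = 50000L))
  ws <- window_diversity(snps, sheet, win, min_snps = 5)
  empty <- ws[chrom == "9"]
  expect_true(all(empty$pi == 0))
  expect_true(all(is.na(empty$tajd)))
  # identical pools give identical window statistics
  snps$maj[, 2] <- snps$maj[, 1]; snps$mino[, 2] <- snps$mino[, 1]
  ws2 <- window_diversity(snps, sheet, win, min_snps = 5)
  expect_equal(ws2[pool == "E1", .(pi, theta_w, tajd)],
               ws2[pool == "M1", .(pi, theta_w, tajd)])
})

test_that("gene means average windows that span the gene", {
  win <- data.table::data.table(
    chrom = "2", start = c(1L, 40001L), end = c(50000L, 90000L),
    tajd = c(-1, 1))
  genes <- data.table::data.table(
    gene_id = c("inside_one", "spans_two", "nowhere"),
    chrom = c("2", "2", "2"),
    start = c(10L, 45000L, 95000L), end = c(500L, 46000L, 99000L))
  gm <- gene_mean_stat(win, genes, stat_col = "tajd")
  expect_equal(gm[gene_id == "inside_one", mean_stat], -1)
  expect_equal(gm[gene_id == "spans_two", mean_stat], 0)
  expect_true(is.na(gm[gene_id == "nowhere", mean_stat]))
  expect_equal(gm[gene_id == "nowhere", n_windows], 0L)

  # brute-force interval-intersection oracle on a random fixture
  set.seed(12)
  win2 <- data.table::data.table(
    chrom = sample(c("2", "3"), 60, TRUE),
    start = sample.int(1e5, 60), tajd = rnorm(60))
  win2[, end := start + 9999L]
  g2 <- data.table::data.table(
    gene_id = paste0("g", 1:40), chrom = sample(c("2", "3"), 40, TRUE),
    start = sample.int(1e5, 40))
  g2[, end := start + 2000L]
  gm2 <- gene_mean_stat(win2, g2, stat_col = "tajd")
  for (i in seq_len(nrow(g2))) {
    hits <- win2[chrom == g2$chrom[i] & start <= g2$end[i] &
                   end >= g2$start[i], tajd]
    want <- if (length(hits)) mean(hits) else NA_real_
    expect_equal(gm2[gene_id == g2$gene_id[i], mean_stat], want)
  }
})

test_that("region contrast detects planted shifts and validates strata", {
  win <- data.table::data.table(
    chrom = "2", start = seq(1L, by = 50000L, length.out = 200))
  win[, end := start + 49999L]
  set.seed(5)
  win[, tajd := rnorm(200)]
  win[, pool := "p1"]
  peaks <- data.table::data.table(chrom = "2", start = 1L, end = 50000L * 50)
  in_peak <- win$start <= peaks$end
  shifted <- data.table::copy(win)
  shifted[in_peak == TRUE, tajd := tajd - 1]
  rc <- region_contrast(shifted, peaks, stat_col = "tajd")
  expect_lt(rc$p_value, 0.001)
  expect_lt(rc$mean_in, rc$mean_out)
  # null: p roughly uniform over seeds
  ps <- vapply(1:40, function(s) {
    w <- data.table::copy(win)
    set.seed(s); w[, tajd := rnorm(200)]
    region_contrast(w, peaks, stat_col = "tajd")$p_value
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.85)
  one_win <- win[1:2]
  expect_error(region_contrast(one_win, peaks, stat_col = "tajd"),
               "stratum")
})
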