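two_locus_haps <- function(n_ab, n_aB, n_Ab, n_AB) {
  H <- rbind(
    matrix(rep(c(0, 0), n_ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), n_aB), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), n_Ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 1), n_AB), ncol = 2, byrow = TRUE))
  H
}

test_that("haplotype r2 matches the squared allele correlation", {
  expect_equal(haplotype_r2(50, 0, 0, 50), 1)
  expect_equal(haplotype_r2(25, 25, 25, 25), 0)
  expect_true(is.na(haplotype_r2(50, 0, 50, 0)))
  set.seed(6)
  for (i in 1:50) {
    cnt <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    got <- haplotype_r2(cnt[1], cnt[2], cnt[3], cnt[4])
    H <- two_locus_haps(cnt[1], cnt[2], cnt[3], cnt[4])
    want <- suppressWarnings(cor(H[, 1], H[, 2])^2)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-12)
    # allele-label swap invariance
    expect_equal(got, haplotype_r2(cnt[3], cnt[4], cnt[1], cnt[2]))
  }
})

test_that("read pairs over coupled loci give r2 near 1, independent loci 0", {
  H <- two_locus_haps(50, 0, 0, 50)
  obs <- generate_read_pairs(H, positions = c(150, 250), n_pairs = 3000,
                             read_len = 100, insert_mean = 250,
                             insert_sd = 5, region = c(100, 300), seed = 2)
  pl <- pair_r2(obs, min_cov = 10, max_cov = 1e6)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$r2, 1)
  expect_equal(pl$distance_bp, 100L)

  # loci never co-covered produce no joint observations
  obs2 <- generate_read_pairs(two_locus_haps(25, 25, 25, 25),
                              positions = c(100, 5000), n_pairs = 500,
                              read_len = 50, insert_mean = 120,
                              insert_sd = 2, region = c(50, 5100), seed = 3)
  expect_equal(nrow(pair_r2(obs2, min_cov = 1, max_cov = 1e6)), 0L)
})

test_that("planted D is recovered within sampling error", {
  # frequencies 0.5/0.5 with D = 0.1: haplotype freqs 0.35/.15/.15/.35
  set.seed(9)
  H <- two_locus_haps(350, 150, 150, 350)
  obs <- generate_read_pairs(H, positions = c(120, 220), n_pairs = 10000,
                             read_len = 100, insert_mean = 230,
                             insert_sd = 5, region = c(100, 260), seed = 4)
  pl <- pair_r2(obs, min_cov = 10, max_cov = 1e6)
  se <- sqrt(2 * 0.16^2 / pl$n_joint)   # rough large-sample scale
  expect_lt(abs(pl$r2 - 0.16), max(3 * se, 0.02))
})

test_that("distance classes apply the five-pair minimum and exact distances", {
  pairs <- data.table::data.table(
    chrom = "2", pos1 = 1L, pos2 = 51L, distance_bp = 50L,
    n_joint = 20L, r2 = c(1, 1, 0, 0, 0.5))
  cls <- bin_by_distance(pairs)
  expect_equal(cls$mean_r2, 0.5)
  expect_equal(cls$n, 5L)
  expect_equal(nrow(bin_by_distance(pairs[1:4])), 0L)
  set.seed(11)
  rnd <- data.table::data.table(
    chrom = "2", pos1 = 1L,
    distance_bp = sample(c(10L, 20L, 30L), 300, TRUE), r2 = runif(300))
  rnd[, pos2 := pos1 + distance_bp]
  cls2 <- bin_by_distance(rnd)
  for (d in unique(rnd$distance_bp))
    expect_equal(cls2[distance_bp == d, mean_r2],
                 mean(rnd[distance_bp == d, r2]))
})

test_that("decay fits recover exact and noisy log-linear relationships", {
  d <- 10:200
  exact <- data.table::data.table(distance_bp = d,
                                  mean_r2 = 0.8 - 0.1 * log(d), n = 10L)
  # suppressWarnings: summary.lm flags the deliberately exact fit
  f <- suppressWarnings(fit_decay(exact))
  expect_equal(f$decay_slope, -0.1, tolerance = 1e-10)
  expect_equal(f$intercept, 0.8, tolerance = 1e-10)
  const <- data.table::data.table(distance_bp = d, mean_r2 = 0.3, n = 10L)
  expect_equal(suppressWarnings(fit_decay(const))$decay_slope, 0,
               tolerance = 1e-12)
  expect_error(fit_decay(exact[1]), "2 distance classes")

  covered <- logical(200)
  for (s in 1:200) {
    set.seed(s)
    noisy <- data.table::data.table(
      distance_bp = d, mean_r2 = 0.8 - 0.1 * log(d) + rnorm(length(d), 0, 0.02))
    fit <- fit_decay(noisy)
    covered[s] <- abs(fit$decay_slope - (-0.1)) < 3 * fit$slope_se
  }
  expect_gte(mean(covered), 0.95)
})

test_that("regional decay comparison flags a planted 2x slope", {
  d <- 10:209
  set.seed(21)
  mk <- function(slope) data.table::data.table(
    distance_bp = d, mean_r2 = 1.2 + slope * log(d) + rnorm(length(d), 0, 0.02),
    n = 10L)
  cd <- compare_decay(list(A = mk(-0.1), B = mk(-0.2)))
  expect_equal(nrow(cd$slopes), 2L)
  inter_p <- cd$anova["log(distance_bp):region", "Pr(>F)"]
  expect_lt(inter_p, 0.001)
  same <- compare_decay(list(A = mk(-0.1), B = mk(-0.1)))
  expect_gt(same$anova["log(distance_bp):region", "Pr(>F)"], 0.01)
})

test_that("recombination steepens the fitted decay slope", {
  pos <- seq(10, 300, by = 10)
  slope_at <- function(r, seed) {
    H <- simulate_haplotype_region(pos, p0 = 0.5, n_e = 60,
                                   generations = 60, recomb_rate = r,
                                   seed = seed)
    poly <- colMeans(H) > 0.1 & colMeans(H) < 0.9
    if (sum(poly) < 5) return(NA_real_)
    obs <- generate_read_pairs(H[, poly, drop = FALSE], pos[poly],
                               n_pairs = 2000, read_len = 100,
                               insert_mean = 220, insert_sd = 15,
                               region = c(1, 300), seed = seed + 1000)
    cls <- bin_by_distance(pair_r2(obs, min_cov = 10, max_cov = 1e6))
    if (nrow(cls) < 2) return(NA_real_)
    fit_decay(cls)$decay_slope
  }
  s_none <- vapply(1:12, function(s) slope_at(0, s), numeric(1))
  s_high <- vapply(1:12, function(s) slope_at(2e-3, s), numeric(1))
  expect_lt(mean(s_high, na.rm = TRUE), mean(s_none, na.rm = TRUE))
  expect_lt(abs(mean(s_none, na.rm = TRUE)), 0.05)
})
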