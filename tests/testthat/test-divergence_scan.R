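test_that("the two-group fit matches a reference quasibinomial GLM", {
  sheet <- make_sheet(4)
  set.seed(42)
  worst <- 0
  for (i in 1:200) {
    maj <- rpois(8, 30) + 1L
    mino <- rpois(8, 20) + 1L
    f <- fit_snp_glm(maj, mino, sheet)
    tr <- factor(rep(c("E", "M"), each = 4), levels = c("M", "E"))
    g <- stats::glm(cbind(maj, mino) ~ tr, family = stats::quasibinomial,
                    control = stats::glm.control(epsilon = 1e-12))
    sg <- summary(g)
    rel <- function(a, b) abs(a - b) / max(abs(b), 1e-12)
    worst <- max(worst,
                 rel(f$beta_treatment, unname(stats::coef(g)[2])),
                 rel(f$dispersion_phi, sg$dispersion),
                 rel(f$p_value, sg$coefficients[2, 4]))
  }
  expect_lt(worst, 1e-6)
})

test_that("balanced counts give no effect; consistent fixation is extreme", {
  sheet <- make_sheet(4)
  f0 <- fit_snp_glm(rep(50L, 8), rep(50L, 8), sheet)
  expect_equal(f0$beta_treatment, 0)
  expect_equal(f0$p_value, 1)
  # maximal consistent divergence triggers the pseudocount rule
  f1 <- fit_snp_glm(c(rep(30L, 4), rep(0L, 4)),
                    c(rep(0L, 4), rep(30L, 4)), sheet)
  expect_lt(f1$p_value, 1e-4)
  expect_error(fit_snp_glm(c(10L, 10L), c(5L, 5L), data.frame(
    pool_id = c("a", "b"), treatment = c("E", "M"),
    replicate = c(1, 1), pool_size = 40)), "3 pools")
})

test_that("pseudocount adds one to every count when any count is zero", {
  pc <- poolscan:::apply_pseudocount(matrix(c(30L, 0L, 10L, 10L), 2),
                                     matrix(c(5L, 8L, 3L, 4L), 2))
  expect_equal(pc$maj[2, ], c(1L, 11L))    # row with a zero: +1 everywhere
  expect_equal(pc$mino[2, ], c(9L, 5L))
  expect_equal(pc$maj[1, ], c(30L, 10L))   # untouched row keeps raw counts
  expect_equal(pc$mino[1, ], c(5L, 3L))
})

test_that("Storey q-values match the step-by-step reference", {
  set.seed(1)
  p <- c(runif(80), rbeta(20, 0.2, 5))
  expect_lt(max(abs(storey_qvalues(p) - storey_reference(p))), 1e-8)
  expect_equal(storey_qvalues(rep(1, 50)), rep(1, 50))
  expect_lte(storey_qvalues(0.01), 0.01)
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
  # q preserves the order of p
  q <- storey_qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("label permutations exclude the observed assignment and complement", {
  expect_equal(nrow(enumerate_label_permutations(make_sheet(4))), 68L)
  expect_equal(nrow(enumerate_label_permutations(make_sheet(1))), 0L)
  p2 <- enumerate_label_permutations(make_sheet(2))
  expect_equal(nrow(p2), 4L)
  # brute-force: all 2-of-4 subsets minus observed {1,2} and complement {3,4}
  all_sets <- utils::combn(4, 2)
  keep <- apply(all_sets, 2, function(s)
    !identical(s, c(1L, 2L)) && !identical(s, c(3L, 4L)))
  expect_equal(sum(keep), 4L)
  expect_error(enumerate_label_permutations(validate_sample_sheet(
    data.frame(pool_id = c("a", "b", "c"), treatment = c("E", "E", "M"),
               replicate = 1:3, pool_size = 40))), "balanced")
})

test_that("permutation scan is calibrated on null data and detects selection", {
  sheet <- make_sheet(4)
  # null: observed count should sit inside the permutation distribution
  inside <- logical(10)
  for (s in 1:10) {
    snps <- random_snp_set(400, sheet, seed = s)
    ps <- permutation_scan(snps, sheet)
    inside[s] <- mean(ps$counts >= ps$observed) > 0.05
  }
  expect_gte(mean(inside), 0.9)
  # strong consistent divergence: observed exceeds every permutation count
  set.seed(99)
  snps <- random_snp_set(400, sheet, seed = 3)
  idx <- 1:50
  snps$maj[idx, 1:4] <- 60L; snps$mino[idx, 1:4] <- 2L
  snps$maj[idx, 5:8] <- 2L;  snps$mino[idx, 5:8] <- 60L
  ps <- permutation_scan(snps, sheet)
  expect_true(all(ps$counts < ps$observed))
  # n_perm = 0 -> empty
  expect_length(permutation_scan(snps, sheet, n_perm = 0)$counts, 0L)
  # per-snp mode needs a seed and returns one count per iteration
  expect_error(permutation_scan(snps, sheet, mode = "per_snp", n_perm = 5),
               "seed")
  pp <- permutation_scan(snps, sheet, mode = "per_snp", n_perm = 5, seed = 1)
  expect_length(pp$counts, 5L)
})

test_that("top-SNP clustering is single linkage with an inclusive boundary", {
  one <- cluster_top_snps(data.frame(chrom = "2", pos = c(100, 50100)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start, 100)
  expect_equal(one$end, 50100)
  two <- cluster_top_snps(data.frame(chrom = "2", pos = c(100, 50101)))
  expect_equal(nrow(two), 2L)

  # brute-force transitive-closure oracle on random positions
  brute_clusters <- function(pos, link) {
    pos <- sort(pos)
    id <- cumsum(c(1, diff(pos) > link))
    tapply(pos, id, function(x) c(min(x), max(x), length(x)))
  }
  set.seed(8)
  pos <- sample.int(3e6, 500)
  got <- cluster_top_snps(data.frame(chrom = "3", pos = pos))
  want <- brute_clusters(pos, 50000)
  expect_equal(nrow(got), length(want))
  expect_equal(got$start, as.integer(vapply(want, `[`, numeric(1), 1)))
  expect_equal(got$n_snps, as.integer(vapply(want, `[`, numeric(1), 3)))
})

test_that("chromosome excess test matches the binomial computation", {
  bg <- c("2" = 1000, "3" = 1000, "4" = 1000, "XL" = 1000, "XR" = 1000)
  prop <- c("2" = 20, "3" = 20, "4" = 20, "XL" = 20, "XR" = 20)
  res <- chromosome_excess_test(prop, bg)
  expect_true(all(res$p_value > 0.9))
  conc <- c("2" = 100, "3" = 0, "4" = 0, "XL" = 0, "XR" = 0)
  res2 <- chromosome_excess_test(conc, bg)
  expect_lt(res2[chrom == "2", p_value], 1e-10)
  set.seed(4)
  rnd <- setNames(rmultinom(1, 80, prob = bg / sum(bg))[, 1], names(bg))
  res3 <- chromosome_excess_test(rnd, bg)
  for (ch in names(bg)) {
    expect_equal(res3[chrom == ch, p_value],
                 binom.test(rnd[[ch]], 80, 0.2)$p.value)
  }
})

test_that("coverage check flags planted coverage differences only", {
  cfg <- sim_config(chrom_plan = data.table::data.table(
    chrom = "2", length_bp = 1e6, n_loci = 2000L, x_linked = FALSE),
    selected_fraction = 0, seed = 6)
  truth <- simulate_wright_fisher(cfg)
  sites <- sample_pool_counts(truth, cfg)
  peaks <- data.table::data.table(chrom = "2",
                                  start = c(1e5, 3e5, 5e5, 8e5),
                                  end = c(1.5e5, 3.5e5, 5.6e5, 8.4e5))
  null_p <- vapply(1:10, function(s)
    peak_coverage_check(peaks, sites, seed = s)$p_value, numeric(1))
  expect_gte(mean(null_p > 0.05), 0.8)
  # double coverage inside the peaks
  boosted <- sites
  in_peak <- rowSums(vapply(seq_len(nrow(peaks)), function(i)
    sites$pos >= peaks$start[i] & sites$pos <= peaks$end[i],
    logical(length(sites$pos)))) > 0
  boosted$counts[in_peak, , ] <- boosted$counts[in_peak, , ] * 2L
  expect_lt(peak_coverage_check(peaks, boosted, seed = 1)$p_value, 0.01)
  expect_error(peak_coverage_check(peaks, sites, n_random = 0), "positive")
})

test_that("fixed differences require opposite fixation in every replicate", {
  sheet <- make_sheet(4)
  snps <- random_snp_set(60, sheet, seed = 2)
  snps$maj[1, 1:4] <- 30L; snps$mino[1, 1:4] <- 0L
  snps$maj[1, 5:8] <- 0L;  snps$mino[1, 5:8] <- 30L
  snps$maj[2, ] <- snps$maj[1, ]; snps$mino[2, ] <- snps$mino[1, ]
  snps$maj[2, 5] <- 1L; snps$mino[2, 5] <- 29L   # one M pool not fixed
  flags <- fixed_difference_flags(snps, sheet)
  expect_true(flags[1])
  expect_false(flags[2])
  # brute-force definition on the random remainder
  freq <- snps$maj / (snps$maj + snps$mino)
  brute <- vapply(seq_len(nrow(freq)), function(i) {
    all(vapply(1:4, function(r) {
      e <- freq[i, r]; m <- freq[i, r + 4]
      isTRUE((e == 1 && m == 0) || (e == 0 && m == 1))
    }, logical(1)))
  }, logical(1))
  expect_equal(flags, brute)
})
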