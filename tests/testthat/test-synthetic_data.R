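one_chrom_config <- function(n_loci, ...) {
  sim_config(chrom_plan = data.table::data.table(
    chrom = "2", length_bp = max(10 * n_loci, 1000), n_loci = n_loci,
    x_linked = FALSE), ...)
}

test_that("without selection or generations, frequencies stay ancestral", {
  cfg <- one_chrom_config(50, generations = 0, selected_fraction = 0,
                          seed = 11)
  truth <- simulate_wright_fisher(cfg)
  expect_true(all(abs(truth$freq - truth$loci$p0) < 1e-12))
})

test_that("neutral heterozygosity decays at the drift rate, X faster", {
  # loci are iid replicates of the drift process
  cfg <- sim_config(chrom_plan = data.table::data.table(
    chrom = c("A", "X"), length_bp = 30000, n_loci = 3000L,
    x_linked = c(FALSE, TRUE)),
    selected_fraction = 0, p0_min = 0.5, p0_max = 0.5, seed = 5)
  truth <- simulate_wright_fisher(cfg)
  het <- 2 * truth$freq * (1 - truth$freq)
  auto <- truth$loci$chrom == "A"
  h_auto <- mean(het[auto, ])
  h_x <- mean(het[!auto, ])
  exp_auto <- 0.5 * (1 - 1 / 240)^160
  exp_x <- 0.5 * (1 - 1 / 180)^160
  expect_lt(abs(h_auto - exp_auto) / exp_auto, 0.05)
  expect_lt(abs(h_x - exp_x) / exp_x, 0.05)
  expect_lt(h_x, h_auto)
})

test_that("neutral fixation probability approximates p0", {
  # small population run to (near) complete absorption
  cfg <- one_chrom_config(2000, selected_fraction = 0, n_e = 30,
                          generations = 600, p0_min = 0.3, p0_max = 0.3,
                          seed = 9)
  truth <- simulate_wright_fisher(cfg)
  expect_gt(mean(truth$freq[, 1] %in% c(0, 1)), 0.99)
  p_hat <- mean(truth$freq[, 1] == 1)
  se <- sqrt(0.3 * 0.7 / nrow(truth$loci))
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("selection pushes E lines above M lines at almost all loci", {
  cfg <- one_chrom_config(200, selected_fraction = 1, sel_coeff_e = 0.05,
                          sel_coeff_m = 0, p0_min = 0.5, p0_max = 0.5,
                          seed = 21)
  truth <- simulate_wright_fisher(cfg)
  sheet <- sim_sample_sheet(cfg)
  e <- rowMeans(truth$freq[, sheet$treatment == "E"])
  m <- rowMeans(truth$freq[, sheet$treatment == "M"])
  expect_gte(mean(e > m), 0.95)
})

test_that("pool count sampling is unbiased with two-stage variance", {
  cfg <- one_chrom_config(5000, selected_fraction = 0, generations = 0,
                          p0_min = 0.5, p0_max = 0.5,
                          mean_coverage = 1000, seed = 2)
  truth <- simulate_wright_fisher(cfg)
  sites <- sample_pool_counts(truth, cfg)
  acgt <- sites$counts[, 1:4, 1]
  depth <- rowSums(acgt)
  ref_idx <- match(sites$ref, c("A", "T", "C", "G"))
  ref_reads <- acgt[cbind(seq_len(nrow(acgt)), ref_idx)]
  f_alt <- 1 - ref_reads / depth
  expect_lt(abs(mean(f_alt) - 0.5), 0.01)
  v_exp <- 0.25 * (1 / 80 + 1 / 1000)
  expect_lt(abs(var(f_alt) - v_exp) / v_exp, 0.10)
})

test_that("degenerate frequencies and zero coverage behave", {
  cfg <- one_chrom_config(100, selected_fraction = 0, generations = 0,
                          p0_min = 0.05, p0_max = 0.95, seed = 3)
  truth <- simulate_wright_fisher(cfg)
  truth$freq[] <- 0          # focal allele absent everywhere
  sites <- sample_pool_counts(truth, cfg)
  ref_idx <- match(sites$ref, c("A", "T", "C", "G"))
  for (j in seq_len(dim(sites$counts)[3])) {
    acgt <- sites$counts[, 1:4, j]
    non_ref <- rowSums(acgt) - acgt[cbind(seq_len(nrow(acgt)), ref_idx)]
    expect_true(all(non_ref == 0))
  }
  cfg0 <- one_chrom_config(100, selected_fraction = 0, generations = 0,
                           mean_coverage = 0, seed = 3)
  t0 <- simulate_wright_fisher(cfg0)
  s0 <- sample_pool_counts(t0, cfg0)
  expect_true(all(s0$counts == 0L))
  expect_equal(n_snps(call_snps(s0)), 0L)
})

test_that("fixed seed gives byte-identical sync output", {
  cfg <- one_chrom_config(200, seed = 13)
  f1 <- tempfile(); f2 <- tempfile()
  write_sync(sample_pool_counts(simulate_wright_fisher(cfg), cfg), f1)
  write_sync(sample_pool_counts(simulate_wright_fisher(cfg), cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1) + 1),
                   readBin(f2, "raw", file.size(f2) + 1))
})

test_that("gene annotation generator respects the enrichment null", {
  cfg <- one_chrom_config(100, selected_fraction = 0.5, seed = 17)
  truth <- simulate_wright_fisher(cfg)
  genes <- generate_gene_annotation_and_de(truth, n_genes = 800,
                                           de_base_rate = 0.2,
                                           de_enrichment_near_selected = 1,
                                           seed = 4)
  expect_true(all(genes$start <= genes$end))
  expect_false(anyDuplicated(genes$gene_id) > 0)
  # non-overlapping within chromosome
  g <- genes[order(chrom, start)]
  ok <- g[, .(ok = .N < 2 || all(start[-1] > end[-.N])), by = chrom]$ok
  expect_true(all(ok))
  rate <- mean(genes$is_de)
  se <- sqrt(0.2 * 0.8 / nrow(genes))
  expect_lt(abs(rate - 0.2), 3 * se)
  single <- generate_gene_annotation_and_de(truth, n_genes = 1, seed = 4)
  expect_equal(nrow(single), 1L)
})
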