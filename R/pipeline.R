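# End-to-end orchestration: simulate -> call -> scan -> diversity -> fst ->
# ld -> expression integration, with a single global seed deterministically
# deriving per-stage seeds and a flat summary table.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`. The
#'   pipeline default uses clustered (sweep-region) selection placement,
#'   matching the localised divergence the design produces.
#' @param filter A [site_filter_config()].
#' @param q_threshold Top-SNP q-value threshold.
#' @param link_bp Peak linking distance (bp).
#' @param peak_min Peaks require more than this many member SNPs.
#' @param window_bp,step_bp Window length and step for diversity/FST.
#' @param min_snps_d Minimum segregating sites for a Tajima's D value.
#' @param z Breeding-sex-ratio values for the F_X expectation.
#' @param n_boot Bootstrap iterations for F_X and X:A intervals.
#' @param n_genes Synthetic annotation size.
#' @param de_base_rate,de_enrichment DE-flag generation parameters.
#' @param ld List of LD-simulation settings: n_loci, span_bp, recomb_rate,
#'   n_pairs, read_len, insert_mean, insert_sd.
#' @param sync_path,sheet_path Optional existing sync and sample-sheet
#'   files to analyse instead of simulating (both or neither).
#' @param seed Global seed; per-stage seeds are derived as fixed offsets.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(selected_placement = "clustered"),
                       filter = site_filter_config(),
                       q_threshold = 0.05, link_bp = 50000L,
                       peak_min = 10L, window_bp = 50000L,
                       step_bp = 40000L, min_snps_d = 10L, z = c(1, 6),
                       n_boot = 1000L, n_genes = 2000L,
                       de_base_rate = 0.15, de_enrichment = 10,
                       ld = list(n_loci = 40L, span_bp = 300L,
                                 recomb_rate = 1e-4, n_pairs = 600L,
                                 read_len = 100L, insert_mean = 340,
                                 insert_sd = 10),
                       sync_path = NULL, sheet_path = NULL, seed = 1L) {
  cfg <- list(sim = sim, filter = filter, q_threshold = q_threshold,
              link_bp = link_bp, peak_min = peak_min,
              window_bp = window_bp, step_bp = step_bp,
              min_snps_d = min_snps_d, z = z, n_boot = n_boot,
              n_genes = n_genes, de_base_rate = de_base_rate,
              de_enrichment = de_enrichment, ld = ld,
              sync_path = sync_path, sheet_path = sheet_path,
              seed = as.integer(seed))
  cfg$sim$seed <- cfg$seed
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#' @param cfg A `run_config`.
#' @return `cfg`, invisibly validated (errors before any stage runs).
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg$sim, "sim_config"),
            inherits(cfg$filter, "site_filter_config"))
  if (xor(is.null(cfg$sync_path), is.null(cfg$sheet_path)))
    stop("sync_path and sheet_path must be given together")
  if (!is.null(cfg$sync_path)) {
    if (!file.exists(cfg$sync_path)) stop("sync file not found: ",
                                          cfg$sync_path)
    if (!file.exists(cfg$sheet_path)) stop("sample sheet not found: ",
                                           cfg$sheet_path)
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing every module's output
#' table under `out_dir` and a flat `summary.tsv` of the headline
#' quantities. Reruns with the same config and seed are byte-identical.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a list with all stage results and the `summary`
#'   (named list of scalars).
#' @export
run_pipeline <- function(cfg, out_dir, quiet = FALSE) {
  cfg <- validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (!quiet) message("[poolscan] ", ...)
  seed <- cfg$seed

  # --- simulate (or load) -------------------------------------------------
  log_stage("stage simulate: seed ", seed)
  if (is.null(cfg$sync_path)) {
    truth <- simulate_wright_fisher(cfg$sim)
    sites <- sample_pool_counts(truth, cfg$sim, seed = seed + 1L)
    sheet <- sim_sample_sheet(cfg$sim)
    genes <- generate_gene_annotation_and_de(
      truth, n_genes = cfg$n_genes, de_base_rate = cfg$de_base_rate,
      de_enrichment_near_selected = cfg$de_enrichment, seed = seed + 2L)
    write_sync(sites, file.path(out_dir, "sites.sync"))
    write_tsv(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_tsv(genes, file.path(out_dir, "genes.tsv"))
    write_tsv(truth$loci, file.path(out_dir, "truth.tsv"))
  } else {
    truth <- NULL
    sheet <- read_sample_sheet(cfg$sheet_path, paired = TRUE)
    sites <- read_sync(cfg$sync_path, sheet)
    genes <- NULL
  }
  chrom_lengths <- setNames(cfg$sim$chrom_plan$length_bp,
                            cfg$sim$chrom_plan$chrom)
  x_chroms <- cfg$sim$chrom_plan$chrom[cfg$sim$chrom_plan$x_linked]

  # --- call ---------------------------------------------------------------
  snps <- call_snps(sites, cfg$filter)
  log_stage("stage call: ", n_snps(snps), " SNPs (",
            snps$n_multiallelic, " multi-allelic dropped)")
  write_tsv(cbind(snps$info,
                  data.table::as.data.table(snps$maj),
                  data.table::as.data.table(snps$mino)),
            file.path(out_dir, "snps.tsv"))

  # --- scan ---------------------------------------------------------------
  scan <- glm_scan(snps, sheet, q_threshold = cfg$q_threshold)
  top <- scan[is_top == TRUE]
  peaks <- cluster_top_snps(top[, .(chrom, pos)], cfg$link_bp, cfg$peak_min)
  excess <- if (nrow(top) > 0L) {
    bg <- table(factor(scan$chrom, levels = names(chrom_lengths)))
    bg <- bg[bg > 0]
    chromosome_excess_test(
      table(factor(top$chrom, levels = names(bg))), bg)
  } else NULL
  fixed <- if (nrow(top) > 0L)
    fixed_difference_flags(subset_snps(snps, which(scan$is_top)), sheet)
  else logical(0)
  log_stage("stage scan: ", nrow(top), " top SNPs, ", nrow(peaks),
            " clusters, ", sum(peaks$is_peak), " peaks (>",
            cfg$peak_min, " SNPs)")
  write_tsv(scan, file.path(out_dir, "scan.tsv"))
  write_tsv(peaks, file.path(out_dir, "peaks.tsv"))
  if (!is.null(excess)) write_tsv(excess, file.path(out_dir, "excess.tsv"))

  # --- diversity ----------------------------------------------------------
  windows <- window_plan(chrom_lengths, cfg$window_bp, cfg$step_bp)
  div <- window_diversity(snps, sheet, windows, min_snps = cfg$min_snps_d)
  div <- merge(div, sheet[, .(pool = pool_id, treatment)], by = "pool")
  write_tsv(div, file.path(out_dir, "diversity.tsv"))
  log_stage("stage diversity: ", nrow(windows), " windows")

  # --- fst ----------------------------------------------------------------
  fst_rec <- replicate_pair_fst(snps, sheet)
  wfst <- window_fst(fst_rec, windows, group_col = "replicate")
  wfst_mean <- wfst[, .(fst = mean(fst, na.rm = TRUE)),
                    by = .(chrom, start, end)]
  wfst_mean[is.nan(fst), fst := NA_real_]
  fx <- bootstrap_fx(wfst, x_chroms = x_chroms, z = cfg$z,
                     n_boot = cfg$n_boot, seed = seed + 4L,
                     group_col = "replicate")
  xa <- xa_ratio(wfst_mean, "fst", x_chroms, n_boot = cfg$n_boot,
                 seed = seed + 5L)
  write_tsv(wfst, file.path(out_dir, "window_fst.tsv"))
  write_tsv(fx, file.path(out_dir, "fx.tsv"))
  log_stage("stage fst: X:A ratio ", round(xa$ratio, 3))

  # --- ld -----------------------------------------------------------------
  ld_slopes <- list()
  for (tr in c("E", "M")) {
    lds <- cfg$ld
    pos0 <- sort(sample_positions_fixed(lds$n_loci, lds$span_bp))
    hap <- simulate_haplotype_region(
      positions = pos0, p0 = 0.5, n_e = cfg$sim$n_e,
      generations = cfg$sim$generations, recomb_rate = lds$recomb_rate,
      seed = seed + 6L + (tr == "M"))
    obs <- generate_read_pairs(hap, pos0, chrom = "3",
                               n_pairs = lds$n_pairs,
                               read_len = lds$read_len,
                               insert_mean = lds$insert_mean,
                               insert_sd = lds$insert_sd,
                               seed = seed + 8L + (tr == "M"))
    cls <- bin_by_distance(pair_r2(obs))
    ld_slopes[[tr]] <- if (nrow(cls) >= 2L) fit_decay(cls, region = tr)
                       else NULL
  }
  log_stage("stage ld: slopes ",
            paste(vapply(ld_slopes, function(f)
              if (is.null(f)) NA_real_ else round(f$decay_slope, 4),
              numeric(1)), collapse = " / "))

  # --- expression integration --------------------------------------------
  expr <- NULL
  if (!is.null(genes) && nrow(top) > 0L) {
    near <- genes_near_snps(top[, .(chrom, pos)], genes)
    ovl <- if (nrow(near) > 0L)
      overlap_resampling_test(near$gene_id, genes[is_de == TRUE]$gene_id,
                              genes$gene_id, n_resample = 1000L,
                              seed = seed + 10L)
    else NULL
    gene_fst <- gene_mean_stat(wfst_mean, genes, stat_col = "fst")
    gene_fst <- merge(gene_fst,
                      genes[, .(gene_id, chrom, is_de)], by = "gene_id")
    gene_fst[, chrom_type := data.table::fifelse(chrom %in% x_chroms,
                                                 chrom, "autosome")]
    contrast <- de_contrast(gene_fst, stat_col = "mean_stat",
                            strata_cols = "chrom_type")
    expr <- list(n_near = nrow(near), overlap = ovl, contrast = contrast)
    write_tsv(contrast, file.path(out_dir, "de_contrast_fst.tsv"))
    log_stage("stage expression: ", nrow(near), " genes near top SNPs")
  }

  # --- summary ------------------------------------------------------------
  tr_mean <- function(col, trt)
    mean(div[treatment == trt][[col]], na.rm = TRUE)
  # contrasts use all clusters (any size) as the region set
  in_peak_fst <- peak_outside_means(wfst_mean, peaks)
  div_e <- div[treatment == "E", .(tajd = mean(tajd, na.rm = TRUE)),
               by = .(chrom, start, end)]
  in_peak_d_e <- peak_outside_means(div_e, peaks, stat_col = "tajd")
  summary <- list(
    n_sites = n_sites(sites),
    n_snps = n_snps(snps),
    n_top_snps = nrow(top),
    n_clusters = nrow(peaks),
    n_peaks = sum(peaks$is_peak),
    prop_top_in_peaks = if (nrow(top) > 0L)
      sum(peaks[is_peak == TRUE]$n_snps) / nrow(top) else NA_real_,
    prop_top_fixed_diff = if (length(fixed)) mean(fixed) else NA_real_,
    min_excess_p_adj = if (!is.null(excess)) min(excess$p_adj) else NA_real_,
    pi_e = tr_mean("pi", "E"), pi_m = tr_mean("pi", "M"),
    tajd_e = tr_mean("tajd", "E"), tajd_m = tr_mean("tajd", "M"),
    fst_autosome = mean(wfst_mean[!chrom %in% x_chroms]$fst, na.rm = TRUE),
    fst_x = mean(wfst_mean[chrom %in% x_chroms]$fst, na.rm = TRUE),
    fst_xa_ratio = xa$ratio,
    fst_in_peaks = in_peak_fst$mean_in,
    fst_outside_peaks = in_peak_fst$mean_out,
    tajd_e_in_peaks = in_peak_d_e$mean_in,
    tajd_e_outside_peaks = in_peak_d_e$mean_out,
    fx_expected_z1 = mean(fx[z == 1]$f_x_expected),
    fx_expected_z6 = mean(fx[z == 6]$f_x_expected),
    ld_slope_e = if (!is.null(ld_slopes$E)) ld_slopes$E$decay_slope
                 else NA_real_,
    ld_slope_m = if (!is.null(ld_slopes$M)) ld_slopes$M$decay_slope
                 else NA_real_,
    n_genes_near_top = if (!is.null(expr)) expr$n_near else NA_real_,
    overlap_p = if (!is.null(expr) && !is.null(expr$overlap))
      expr$overlap$empirical_p else NA_real_)
  sm <- data.table::data.table(quantity = names(summary),
                               value = vapply(summary, function(v)
                                 format(v, digits = 15), character(1)))
  write_tsv(sm, file.path(out_dir, "summary.tsv"))
  log_stage("done: summary written to ", file.path(out_dir, "summary.tsv"))
  invisible(list(truth = truth, sheet = sheet, sites = sites, snps = snps,
                 scan = scan, peaks = peaks, excess = excess,
                 diversity = div, window_fst = wfst,
                 window_fst_mean = wfst_mean, fx = fx, xa = xa,
                 ld = ld_slopes, expression = expr, summary = summary))
}

# Evenly spread n positions over a span (deterministic; LD loci do not need
# randomised placement).
sample_positions_fixed <- function(n, span) {
  unique(round(seq(1, span, length.out = n)))
}

# Mean of a window statistic inside vs outside peak spans.
peak_outside_means <- function(win_stats, peaks, stat_col = "fst") {
  ws <- data.table::copy(data.table::as.data.table(win_stats))
  ws[, in_peak := FALSE]
  if (nrow(peaks) > 0L) {
    p2 <- data.table::as.data.table(peaks)[, .(chrom, start, end)]
    data.table::setkey(p2, chrom, start, end)
    ov <- data.table::foverlaps(ws[, .(chrom, start, end, row = .I)], p2,
                                type = "any", nomatch = NULL)
    ws$in_peak[unique(ov$row)] <- TRUE
  }
  v <- ws[[stat_col]]
  list(mean_in = mean(v[ws$in_peak], na.rm = TRUE),
       mean_out = mean(v[!ws$in_peak], na.rm = TRUE))
}
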