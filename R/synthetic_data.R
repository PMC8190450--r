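# Forward simulator of the replicated experimental-evolution design:
# paired monogamy (M) / elevated-polyandry (E) lines evolved by
# Wright-Fisher drift + viability selection, then pool-sequenced with
# two-stage sampling noise (individuals into the pool, reads from the pool).

#' Simulation configuration
#'
#' Defaults describe the study design being emulated: 4 replicate E/M line
#' pairs, effective population size ~120 per line, 160 generations of
#' divergence, pools of 40 diploid females, and X-linked loci segregating at
#' reduced effective size (N_eX = 3/4 N_eA).
#'
#' @param n_replicates Number of replicate E/M line pairs.
#' @param n_e Effective population size per line (diploid individuals).
#' @param generations Generations of divergence.
#' @param chrom_plan `data.frame` with columns `chrom`, `length_bp`,
#'   `n_loci`, `x_linked`. Default: autosomes 2, 3, 4 and X arms XL, XR,
#'   2 Mb and 1000 loci each.
#' @param selected_fraction Fraction of loci under divergent selection.
#' @param sel_coeff_e,sel_coeff_m Signed selection coefficients applied to
#'   the focal allele at selected loci in E and M lines respectively; a
#'   negative value disfavours the focal allele. The defaults (+0.05 in E,
#'   -0.05 in M) encode divergent treatment-specific selection: the allele
#'   favoured under elevated polyandry is disfavoured under monogamy.
#' @param dominance Dominance coefficient h in `[0, 1]`.
#' @param pool_size Diploid individuals sequenced per pool.
#' @param mean_coverage Expected (Poisson) read depth per pool per site.
#' @param p0_min,p0_max Bounds of the ancestral allele-frequency
#'   distribution (shared by all lines: one ancestral population).
#' @param p0_dist `"uniform"` (default) or `"sfs"`: ancestral frequencies
#'   drawn uniformly or from a neutral site-frequency spectrum
#'   (density proportional to 1/p), both truncated to `[p0_min, p0_max]`.
#' @param selected_placement `"random"`: a `selected_fraction` of loci drawn
#'   at random genome-wide; `"clustered"`: all loci inside one
#'   `sweep_span_bp` region per `sweep_chroms` entry are selected,
#'   emulating localised divergent selection (divergence peaks).
#' @param sweep_chroms Chromosomes receiving a sweep region in clustered
#'   mode (default chromosome 3 and both X arms, where the study's largest
#'   divergent clusters sit).
#' @param sweep_span_bp Span of each sweep region (bp).
#' @param seed Integer seed used by the simulation functions.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_replicates = 4L, n_e = 120L, generations = 160L,
                       chrom_plan = default_chrom_plan(),
                       selected_fraction = 0.01,
                       sel_coeff_e = 0.05, sel_coeff_m = -0.05,
                       dominance = 0.5, pool_size = 40L,
                       mean_coverage = 50, p0_min = 0.05, p0_max = 0.95,
                       p0_dist = c("uniform", "sfs"),
                       selected_placement = c("random", "clustered"),
                       sweep_chroms = c("3", "XL", "XR"),
                       sweep_span_bp = 50000L, seed = 1L) {
  p0_dist <- match.arg(p0_dist)
  selected_placement <- match.arg(selected_placement)
  chrom_plan <- data.table::as.data.table(chrom_plan)
  stopifnot(n_e >= 2, generations >= 0,
            selected_fraction >= 0, selected_fraction <= 1,
            mean_coverage >= 0, dominance >= 0, dominance <= 1,
            all(c("chrom", "length_bp", "n_loci", "x_linked") %in%
                  names(chrom_plan)))
  structure(list(n_replicates = as.integer(n_replicates),
                 n_e = as.integer(n_e),
                 generations = as.integer(generations),
                 chrom_plan = chrom_plan,
                 selected_fraction = selected_fraction,
                 sel_coeff_e = sel_coeff_e, sel_coeff_m = sel_coeff_m,
                 dominance = dominance, pool_size = as.integer(pool_size),
                 mean_coverage = mean_coverage,
                 p0_min = p0_min, p0_max = p0_max, p0_dist = p0_dist,
                 selected_placement = selected_placement,
                 sweep_chroms = sweep_chroms,
                 sweep_span_bp = as.integer(sweep_span_bp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default chromosome plan (main chromosome arms)
#' @return A `data.table` with chroms 2, 3, 4 (autosomes) and XL, XR
#'   (X-linked), 2 Mb / 1000 loci each.
#' @export
default_chrom_plan <- function() {
  data.table::data.table(
    chrom = c("2", "3", "4", "XL", "XR"),
    length_bp = rep(2e6, 5),
    n_loci = rep(1000L, 5),
    x_linked = c(FALSE, FALSE, FALSE, TRUE, TRUE))
}

#' Sample sheet implied by a simulation configuration
#' @param config A [sim_config()].
#' @return A validated sample sheet (`E1..`, then `M1..`).
#' @export
sim_sample_sheet <- function(config) {
  r <- config$n_replicates
  validate_sample_sheet(data.table::data.table(
    pool_id = c(paste0("E", 1:r), paste0("M", 1:r)),
    treatment = rep(c("E", "M"), each = r),
    replicate = rep(1:r, 2),
    pool_size = config$pool_size), paired = TRUE)
}

# Deterministic viability-selection update: genotype fitnesses 1, 1-hs,
# 1-s for the favoured homozygote, heterozygote, unfavoured homozygote.
selection_update <- function(p, s, h) {
  if (all(s == 0)) return(p)
  wbar <- p^2 + 2 * p * (1 - p) * (1 - h * s) + (1 - p)^2 * (1 - s)
  (p^2 + p * (1 - p) * (1 - h * s)) / wbar
}

#' Simulate replicated Wright-Fisher evolution under the E/M design
#'
#' All lines start from identical ancestral frequencies (shared source
#' population). Each generation applies the deterministic selection update
#' (selected loci only; `sel_coeff_e` in E lines, `sel_coeff_m` in M lines)
#' followed by binomial drift over `2 * n_e` gene copies at autosomal loci
#' and `round(1.5 * n_e)` copies at X-linked loci (N_eX = 3/4 N_eA).
#'
#' @param config A [sim_config()].
#' @return A `truth_set`: list with `loci` (`data.table`: chrom, pos,
#'   x_linked, selected, s_e, s_m, p0), `freq` (matrix loci x lines of final
#'   focal-allele frequencies, columns named as in [sim_sample_sheet()]) and
#'   the `config`.
#' @export
simulate_wright_fisher <- function(config) {
  set.seed(config$seed)
  cp <- config$chrom_plan
  loci <- cp[, .(pos = sort(sample.int(length_bp, n_loci)),
                 x_linked = x_linked), by = chrom]
  n <- nrow(loci)
  loci[, selected := FALSE]
  if (identical(config$selected_placement, "clustered")) {
    cp2 <- config$chrom_plan
    for (ch in config$sweep_chroms) {
      len <- cp2[chrom == ch, length_bp]
      if (length(len) == 0L) next
      s0 <- sample.int(max(len - config$sweep_span_bp, 1L), 1L)
      loci[chrom == ch & pos >= s0 & pos < s0 + config$sweep_span_bp,
           selected := TRUE]
    }
  } else {
    n_sel <- round(config$selected_fraction * n)
    if (n_sel > 0) loci$selected[sample.int(n, n_sel)] <- TRUE
  }
  loci[, s_e := ifelse(selected, config$sel_coeff_e, 0)]
  loci[, s_m := ifelse(selected, config$sel_coeff_m, 0)]
  loci[, p0 := if (identical(config$p0_dist, "sfs")) {
    # inverse-CDF draw from density 1/p truncated to [p0_min, p0_max]
    config$p0_min * (config$p0_max / config$p0_min)^runif(n)
  } else {
    runif(n, config$p0_min, config$p0_max)
  }]

  sheet <- sim_sample_sheet(config)
  copies <- ifelse(loci$x_linked, round(1.5 * config$n_e), 2L * config$n_e)
  freq <- matrix(rep(loci$p0, nrow(sheet)), nrow = n,
                 dimnames = list(NULL, sheet$pool_id))
  h <- config$dominance
  for (g in seq_len(config$generations)) {
    for (j in seq_len(nrow(sheet))) {
      s <- if (sheet$treatment[j] == "E") loci$s_e else loci$s_m
      p <- selection_update(freq[, j], s, h)
      freq[, j] <- rbinom(n, copies, p) / copies
    }
  }
  structure(list(loci = loci, freq = freq, config = config),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$loci), "loci (", sum(x$loci$selected),
      "selected ),", ncol(x$freq), "lines\n")
  invisible(x)
}

#' Pool-seq sampling of simulated lines
#'
#' Two-stage sampling per site and pool: (1) `2 * pool_size` allele copies
#' drawn binomially from the line's true frequency (female-only pools carry
#' two X copies each, so the X uses the same `2 * pool_size`); (2) read
#' depth drawn Poisson(`mean_coverage`) and focal-allele reads binomially
#' from the realised pool allele fraction. Each locus is assigned a
#' reference and a distinct alternate nucleotide.
#'
#' @param truth A `truth_set` from [simulate_wright_fisher()].
#' @param config A [sim_config()]; defaults to the one inside `truth`.
#' @param seed Seed for the sampling stage (defaults to `config$seed + 1`).
#' @return A `sync_sites` object with pools in [sim_sample_sheet()] order.
#' @export
sample_pool_counts <- function(truth, config = truth$config,
                               seed = config$seed + 1L) {
  set.seed(seed)
  loci <- truth$loci
  n <- nrow(loci)
  sheet <- sim_sample_sheet(config)
  k <- nrow(sheet)
  nuc_idx <- seq_len(4)
  ref_a <- sample(nuc_idx, n, replace = TRUE)
  alt_a <- ((ref_a - 1L + sample(1:3, n, replace = TRUE)) %% 4L) + 1L
  counts <- array(0L, dim = c(n, 6L, k))
  two_n <- 2L * config$pool_size
  for (j in seq_len(k)) {
    pool_frac <- rbinom(n, two_n, truth$freq[, j]) / two_n
    depth <- rpois(n, config$mean_coverage)
    alt_reads <- rbinom(n, depth, pool_frac)
    ref_reads <- depth - alt_reads
    counts[cbind(seq_len(n), ref_a, j)] <- ref_reads
    counts[cbind(seq_len(n), alt_a, j)] <-
      counts[cbind(seq_len(n), alt_a, j)] + alt_reads
  }
  sync_sites(loci$chrom, loci$pos, NUCS[ref_a], counts, sheet$pool_id)
}

#' Simulate a linked-haplotype region forward in time
#'
#' Wright-Fisher evolution of `2 * n_e` haplotypes over a set of linked loci
#' with per-interval recombination, used to generate read pairs for LD
#' estimation. Neutral (LD statistics are compared against plug-in truth,
#' not selection).
#'
#' @param positions Sorted locus positions (bp) within the region.
#' @param p0 Initial allele frequencies (recycled); initial haplotypes are
#'   drawn in linkage equilibrium unless `init_haplotypes` is given.
#' @param n_e Diploid effective size.
#' @param generations Generations to evolve.
#' @param recomb_rate Per-generation recombination probability between
#'   adjacent loci (scalar or length `length(positions) - 1`).
#' @param init_haplotypes Optional 0/1 matrix (`2 * n_e` x loci) to start from.
#' @param seed Integer seed.
#' @return 0/1 haplotype matrix (`2 * n_e` rows) after evolution.
#' @export
simulate_haplotype_region <- function(positions, p0 = 0.5, n_e = 120L,
                                      generations = 160L, recomb_rate = 1e-4,
                                      init_haplotypes = NULL, seed = 1L) {
  set.seed(seed)
  l <- length(positions)
  nh <- 2L * n_e
  if (is.null(init_haplotypes)) {
    p0 <- rep_len(p0, l)
    H <- matrix(rbinom(nh * l, 1L, rep(p0, each = nh)), nrow = nh)
  } else {
    H <- init_haplotypes
    nh <- nrow(H)
  }
  r <- rep_len(recomb_rate, max(l - 1L, 0L))
  for (g in seq_len(generations)) {
    p1 <- H[sample.int(nh, nh, replace = TRUE), , drop = FALSE]
    p2 <- H[sample.int(nh, nh, replace = TRUE), , drop = FALSE]
    if (l > 1L) {
      sw <- matrix(rbinom(nh * (l - 1L), 1L, rep(r, each = nh)), nrow = nh)
      state <- (matrix(rbinom(nh, 1L, 0.5), nh, l) +
                  cbind(0L, t(apply(sw, 1L, cumsum)))) %% 2L
    } else {
      state <- matrix(rbinom(nh, 1L, 0.5), nh, 1L)
    }
    H <- ifelse(state == 0L, p1, p2)
  }
  H
}

#' Generate read-pair haplotype observations from a haplotype pool
#'
#' Each read pair samples one haplotype, covers two `read_len` segments
#' separated by a gap (`fragment ~ round(Normal(insert_mean, insert_sd))`,
#' gap = `max(0, fragment - 2 * read_len)`), and reports the allele and a
#' Phred-scaled base quality at every locus it covers.
#'
#' @param haplotypes 0/1 matrix, one row per haplotype in the pool.
#' @param positions Locus positions (bp), one per haplotype column.
#' @param chrom Chromosome name for the region.
#' @param n_pairs Number of read pairs to draw.
#' @param read_len Read length (bp).
#' @param insert_mean,insert_sd Mean/SD of the total fragment (insert) size.
#' @param region Length-2 vector giving the span within which fragment
#'   starts are drawn; defaults to the locus span.
#' @param qual_mean,qual_sd Mean/SD of per-base Phred quality labels.
#' @param seed Integer seed.
#' @return `data.table` with columns `pair_id`, `chrom`, `pos`, `allele`
#'   (0/1), `qual`; empty if no locus is ever covered.
#' @export
generate_read_pairs <- function(haplotypes, positions, chrom = "2",
                                n_pairs = 1000L, read_len = 100L,
                                insert_mean = 340, insert_sd = 10,
                                region = range(positions),
                                qual_mean = 37, qual_sd = 3, seed = 1L) {
  set.seed(seed)
  if (length(positions) == 0L)
    return(data.table::data.table(pair_id = integer(0), chrom = character(0),
                                  pos = integer(0), allele = integer(0),
                                  qual = integer(0)))
  hap_i <- sample.int(nrow(haplotypes), n_pairs, replace = TRUE)
  frag <- pmax(2L * read_len, round(rnorm(n_pairs, insert_mean, insert_sd)))
  lo <- region[1] - read_len + 1L
  hi <- region[2]
  start <- floor(runif(n_pairs, lo, hi + 1))
  gap <- frag - 2L * read_len
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    s1 <- start[i]; e1 <- s1 + read_len - 1L
    s2 <- e1 + gap[i] + 1L; e2 <- s2 + read_len - 1L
    cov <- which((positions >= s1 & positions <= e1) |
                   (positions >= s2 & positions <= e2))
    if (length(cov) == 0L) next
    out[[i]] <- data.table::data.table(
      pair_id = i, chrom = chrom, pos = positions[cov],
      allele = as.integer(haplotypes[hap_i[i], cov]),
      qual = pmax(2L, round(rnorm(length(cov), qual_mean, qual_sd))))
  }
  obs <- data.table::rbindlist(out)
  if (nrow(obs) == 0L)
    return(data.table::data.table(pair_id = integer(0), chrom = character(0),
                                  pos = integer(0), allele = integer(0),
                                  qual = integer(0)))
  obs[]
}

#' Generate a synthetic gene annotation with DE flags
#'
#' Non-overlapping gene intervals are tiled along each chromosome. Each
#' gene's differential-expression flag is drawn with base probability
#' `de_base_rate`, multiplied on the odds scale by
#' `de_enrichment_near_selected` when a selected locus lies within
#' `flank_bp` of the gene span. Sex-bias fold changes `log2fc_e` /
#' `log2fc_m` are drawn from a bivariate normal (sd 1, correlation 0.8).
#'
#' @param truth A `truth_set`.
#' @param n_genes Total number of genes to tile (>= 1).
#' @param de_base_rate Baseline DE probability.
#' @param de_enrichment_near_selected Odds multiplier near selected loci.
#' @param flank_bp Proximity window (bp) defining "near".
#' @param seed Integer seed.
#' @return `data.table`: gene_id, chrom, start, end, is_de, log2fc_e,
#'   log2fc_m (1-based inclusive coordinates).
#' @export
generate_gene_annotation_and_de <- function(truth, n_genes = 2000L,
                                            de_base_rate = 0.15,
                                            de_enrichment_near_selected = 1,
                                            flank_bp = 10000L, seed = 1L) {
  stopifnot(n_genes >= 1)
  set.seed(seed)
  cp <- truth$config$chrom_plan
  per <- pmax(1L, round(n_genes * cp$length_bp / sum(cp$length_bp)))
  genes <- data.table::rbindlist(lapply(seq_len(nrow(cp)), function(i) {
    m <- per[i]
    slot <- cp$length_bp[i] / m
    len <- pmin(floor(slot) - 1L, round(runif(m, 2000, 8000)))
    start <- floor((seq_len(m) - 1L) * slot) +
      floor(runif(m, 1, pmax(2, slot - len)))
    data.table::data.table(chrom = cp$chrom[i], start = as.integer(start),
                           end = as.integer(start + pmax(len, 1L) - 1L))
  }))
  genes <- genes[seq_len(min(nrow(genes), n_genes))]
  genes[, gene_id := sprintf("g%05d", .I)]
  sel <- truth$loci[selected == TRUE]
  near <- logical(nrow(genes))
  if (nrow(sel) > 0) {
    for (i in seq_len(nrow(genes))) {
      near[i] <- sel[chrom == genes$chrom[i] &
                       pos >= genes$start[i] - flank_bp &
                       pos <= genes$end[i] + flank_bp, .N] > 0
    }
  }
  odds <- de_base_rate / (1 - de_base_rate) *
    ifelse(near, de_enrichment_near_selected, 1)
  genes[, is_de := runif(.N) < odds / (1 + odds)]
  z1 <- rnorm(nrow(genes)); z2 <- rnorm(nrow(genes))
  rho <- 0.8
  genes[, log2fc_e := z1]
  genes[, log2fc_m := rho * z1 + sqrt(1 - rho^2) * z2]
  data.table::setcolorder(genes, c("gene_id", "chrom", "start", "end",
                                   "is_de", "log2fc_e", "log2fc_m"))
  genes[]
}
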