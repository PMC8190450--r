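# Short-range LD from read-pair co-observations: r^2 per SNP pair by
# direct haplotype counting (LDx-style), exact-distance class averaging
# with filters, and log-distance decay fits.

#' r^2 from two-locus haplotype counts
#'
#' `r2 = D^2 / (p1 q1 p2 q2)` with `D = f(AB) - f(A) f(B)` computed from
#' joint observations. Invariant to allele-label swaps at either locus.
#'
#' @param n_ab,n_aB,n_Ab,n_AB Haplotype counts (lower case = allele 0).
#' @return r^2 in `[0, 1]`, or `NA` if a marginal frequency is 0 or 1.
#' @export
haplotype_r2 <- function(n_ab, n_aB, n_Ab, n_AB) {
  n <- n_ab + n_aB + n_Ab + n_AB
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  d <- n_AB / n - pA * pB
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  r2[pA <= 0 | pA >= 1 | pB <= 0 | pB >= 1] <- NA_real_
  r2
}

#' Pairwise r^2 from read-pair observations
#'
#' Filters bases by Phred quality, then sites by minor allele frequency and
#' coverage (number of passing observations), then tallies two-locus
#' haplotype counts from read pairs covering both sites of a pair and
#' computes `r2 = D^2 / (p1 q1 p2 q2)`. Pairs whose joint observations are
#' monomorphic at either site are skipped.
#'
#' @param obs Long observation table from [generate_read_pairs()]:
#'   pair_id, chrom, pos, allele (0/1), qual.
#' @param min_maf Minimum site minor-allele frequency (strict, default 0.1).
#' @param min_cov,max_cov Site coverage bounds (inclusive; defaults 10, 400).
#' @param min_qual Bases with Phred quality strictly above this are used
#'   (default 20).
#' @return `data.table` (`PairLd`): chrom, pos1, pos2, distance_bp,
#'   n_joint, r2.
#' @export
pair_r2 <- function(obs, min_maf = 0.1, min_cov = 10L, max_cov = 400L,
                    min_qual = 20L) {
  o <- data.table::as.data.table(obs)[qual > min_qual]
  empty <- data.table::data.table(chrom = character(0), pos1 = integer(0),
                                  pos2 = integer(0), distance_bp = integer(0),
                                  n_joint = integer(0), r2 = numeric(0))
  if (nrow(o) == 0L) return(empty)
  site <- o[, .(cov = .N, maf = min(mean(allele), 1 - mean(allele))),
            by = .(chrom, pos)]
  keep <- site[maf > min_maf & cov >= min_cov & cov <= max_cov,
               .(chrom, pos)]
  o <- o[keep, on = c("chrom", "pos")]
  if (nrow(o) == 0L) return(empty)
  joint <- merge(o, o, by = c("pair_id", "chrom"),
                 allow.cartesian = TRUE)[pos.x < pos.y]
  if (nrow(joint) == 0L) return(empty)
  res <- joint[, .(
    n_joint = .N,
    n_AB = sum(allele.x == 1L & allele.y == 1L),
    n_Ab = sum(allele.x == 1L & allele.y == 0L),
    n_aB = sum(allele.x == 0L & allele.y == 1L),
    n_ab = sum(allele.x == 0L & allele.y == 0L)),
    by = .(chrom, pos1 = pos.x, pos2 = pos.y)]
  res[, r2 := haplotype_r2(n_ab, n_aB, n_Ab, n_AB)]
  res <- res[!is.na(r2)]
  res[, distance_bp := pos2 - pos1]
  res[, .(chrom, pos1, pos2, distance_bp, n_joint, r2)]
}

#' Mean r^2 per exact distance class
#'
#' Classes are exact bp distances; classes with fewer than
#' `min_pairs_per_class` SNP pairs are dropped. Sorted by distance.
#'
#' @param pairs `PairLd` table from [pair_r2()].
#' @param min_pairs_per_class Minimum pairs per class (default 5).
#' @return `data.table`: distance_bp, mean_r2, n.
#' @export
bin_by_distance <- function(pairs, min_pairs_per_class = 5L) {
  p <- data.table::as.data.table(pairs)
  cls <- p[, .(mean_r2 = mean(r2), n = .N), by = distance_bp]
  cls <- cls[n >= min_pairs_per_class]
  data.table::setorder(cls, distance_bp)
  cls[]
}

#' Fit the LD decay model
#'
#' Ordinary least squares of mean r^2 on the natural log of distance:
#' `r2 ~ a + log(bp)`. The slope measures the decay of linkage with
#' distance (the log base only rescales the slope).
#'
#' @param classes Distance-class table from [bin_by_distance()].
#' @param region Optional region label carried into the result.
#' @return List (`DecayFit`): region, intercept, decay_slope, slope_se,
#'   n_classes, model (the `lm` fit).
#' @export
fit_decay <- function(classes, region = NA_character_) {
  cls <- data.table::as.data.table(classes)
  if (nrow(cls) < 2L) stop("need at least 2 distance classes for a fit")
  fit <- lm(mean_r2 ~ log(distance_bp), data = cls)
  co <- summary(fit)$coefficients
  list(region = region, intercept = unname(co[1, 1]),
       decay_slope = unname(co[2, 1]), slope_se = unname(co[2, 2]),
       n_classes = nrow(cls), model = fit)
}

#' Compare LD decay across regions (and treatments)
#'
#' Tabulates per-fit slopes and tests for slope differences with a linear
#' model on the pooled class-level data: `mean_r2 ~ log(d) * region`
#' (plus `* treatment` when a treatment label is present), with the
#' sequential F table from [stats::anova()].
#'
#' @param class_tables Named list of distance-class tables (names are
#'   region labels, optionally `"region|treatment"`).
#' @return List: `slopes` (`data.table` region, intercept, decay_slope,
#'   slope_se, n_classes), `anova` (data.frame), `model`.
#' @export
compare_decay <- function(class_tables) {
  stopifnot(length(class_tables) >= 2L)
  keep <- vapply(class_tables, function(x) nrow(x) >= 2L, logical(1))
  class_tables <- class_tables[keep]
  if (length(class_tables) < 2L) stop("need at least 2 non-empty regions")
  fits <- lapply(names(class_tables), function(nm)
    fit_decay(class_tables[[nm]], region = nm))
  slopes <- data.table::rbindlist(lapply(fits, function(f)
    data.table::data.table(region = f$region, intercept = f$intercept,
                           decay_slope = f$decay_slope,
                           slope_se = f$slope_se,
                           n_classes = f$n_classes)))
  all_cls <- data.table::rbindlist(lapply(names(class_tables), function(nm) {
    dt <- data.table::as.data.table(class_tables[[nm]])
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    dt[, region := parts[1]]
    if (length(parts) > 1L) dt[, treatment := parts[2]]
    dt
  }), fill = TRUE)
  form <- if ("treatment" %in% names(all_cls) &&
              length(unique(all_cls$treatment)) > 1L)
    mean_r2 ~ log(distance_bp) * region + log(distance_bp) * treatment
  else mean_r2 ~ log(distance_bp) * region
  fit <- lm(form, data = all_cls)
  list(slopes = slopes, anova = as.data.frame(anova(fit)), model = fit)
}
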