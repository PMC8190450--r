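# Shared fixtures: small paired designs and randomised count tables built
# in code at test time.

make_sheet <- function(k = 4L, pool_size = 40L) {
  poolscan::validate_sample_sheet(data.frame(
    pool_id = c(paste0("E", 1:k), paste0("M", 1:k)),
    treatment = rep(c("E", "M"), each = k),
    replicate = rep(1:k, 2),
    pool_size = pool_size), paired = TRUE)
}

# Independently coded step-by-step Storey procedure (the reference the
# package implementation is checked against).
storey_reference <- function(p) {
  m <- length(p)
  lambda <- seq(0, 0.90, by = 0.05)
  pi0_hat <- numeric(length(lambda))
  for (i in seq_along(lambda))
    pi0_hat[i] <- sum(p > lambda[i]) / (m * (1 - lambda[i]))
  sp <- stats::smooth.spline(lambda, pi0_hat, df = 3)
  pi0 <- stats::predict(sp, x = 0.90)$y
  pi0 <- min(max(pi0, 1e-8), 1)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, pi0 * m * p[o[i]] / i)
    q[o[i]] <- min(prev, 1)
  }
  q
}

# Random biallelic snp_set with counts drawn around given frequencies.
random_snp_set <- function(n, sheet, coverage = 50, seed = 1) {
  set.seed(seed)
  k <- nrow(sheet)
  p <- matrix(runif(n * k, 0.05, 0.95), n, k)
  depth <- matrix(rpois(n * k, coverage), n, k)
  maj <- matrix(rbinom(n * k, depth, p), n, k)
  colnames(maj) <- colnames(depth) <- sheet$pool_id
  structure(list(
    info = data.table::data.table(
      chrom = sample(c("2", "3", "XL"), n, replace = TRUE),
      pos = sample.int(1e6, n), major = "A", minor = "T"),
    maj = maj, mino = depth - maj, pools = sheet$pool_id,
    n_multiallelic = 0L), class = "snp_set")
}

# Random sync_sites over `k` pools with occasional multi-allelic sites.
random_sync_sites <- function(n, k, seed = 1, lambda = 12) {
  set.seed(seed)
  counts <- array(0L, dim = c(n, 6L, k))
  for (j in seq_len(k)) {
    counts[, 1, j] <- rpois(n, lambda)
    counts[, 2, j] <- rpois(n, lambda / 2)
    counts[, 3, j] <- rbinom(n, 1, 0.3) * rpois(n, lambda / 2)
    counts[, 4, j] <- rbinom(n, 1, 0.05) * rpois(n, lambda)
    counts[, 5, j] <- rbinom(n, 1, 0.05)
    counts[, 6, j] <- rbinom(n, 1, 0.05)
  }
  poolscan::sync_sites(chrom = rep(c("2", "3"), length.out = n),
                       pos = rep(seq_len(ceiling(n / 2)) * 10, each = 2)[1:n],
                       ref = rep("A", n), counts = counts,
                       pools = paste0("p", seq_len(k)))
}
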