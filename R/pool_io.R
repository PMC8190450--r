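# Readers/writers for sync count tables, sample sheets, gene annotations and
# result tables. All coordinates are 1-based inclusive (sync convention);
# nucleotide count order within a sync field is A:T:C:G:N:del.

NUCS <- c("A", "T", "C", "G", "N", "del")

#' Read a pool sample sheet
#'
#' A sample sheet is a TSV with header columns `pool_id`, `treatment`
#' (`E` or `M`), `replicate` (integer >= 1) and `pool_size` (diploid
#' individuals sequenced per pool).
#'
#' @param path Path to the TSV file.
#' @param paired If `TRUE`, additionally require that every replicate has
#'   exactly one `E` and one `M` pool (the paired design all replicate-pair
#'   analyses assume).
#' @return A `data.table` with the four columns, validated.
#' @export
read_sample_sheet <- function(path, paired = FALSE) {
  sheet <- data.table::fread(path, sep = "\t", colClasses = list(
    character = "pool_id", character = "treatment"
  ))
  validate_sample_sheet(sheet, paired = paired)
}

#' Validate (and return) a sample sheet
#'
#' @param sheet A data.frame with columns `pool_id`, `treatment`,
#'   `replicate`, `pool_size`.
#' @inheritParams read_sample_sheet
#' @return The validated sheet as a `data.table`.
#' @export
validate_sample_sheet <- function(sheet, paired = FALSE) {
  sheet <- data.table::as.data.table(sheet)
  need <- c("pool_id", "treatment", "replicate", "pool_size")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$pool_id))
    stop("duplicate pool_id in sample sheet")
  if (!all(sheet$treatment %in% c("E", "M")))
    stop("unknown treatment code (must be 'E' or 'M'): ",
         paste(setdiff(sheet$treatment, c("E", "M")), collapse = ", "))
  if (any(sheet$replicate < 1) || any(sheet$replicate != round(sheet$replicate)))
    stop("replicate must be a positive integer")
  if (any(sheet$pool_size < 1))
    stop("pool_size must be >= 1")
  if (paired) {
    tab <- sheet[, .N, by = .(replicate, treatment)]
    reps <- unique(sheet$replicate)
    ok <- all(tab$N == 1L) && nrow(tab) == 2L * length(reps)
    if (!ok)
      stop("paired design requires exactly one E and one M pool per replicate")
  }
  sheet[]
}

#' Read a sync-format count table
#'
#' The sync format is TAB-separated: `chrom pos ref count1 ... countK` with
#' one `A:T:C:G:N:del` count field per pool, pools in sample-sheet order.
#'
#' @param path Path to the sync file.
#' @param sheet Sample sheet giving pool order and count.
#' @return A `sync_sites` object: list with `chrom`, `pos`, `ref` vectors and
#'   a `counts` array of dimension `n_sites x 6 x n_pools` (nucleotide order
#'   A, T, C, G, N, del), plus `pools` (pool ids).
#' @export
read_sync <- function(path, sheet) {
  sheet <- validate_sample_sheet(sheet)
  k <- nrow(sheet)
  if (!file.exists(path)) stop("sync file not found: ", path)
  if (file.size(path) == 0L)
    return(sync_sites(character(0), integer(0), character(0),
                      array(0L, dim = c(0L, 6L, k)), sheet$pool_id))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          colClasses = "character")
  if (ncol(dt) != 3L + k)
    stop("sync file has ", ncol(dt), " columns; expected ", 3L + k,
         " for ", k, " pools")
  counts <- array(0L, dim = c(nrow(dt), 6L, k))
  for (j in seq_len(k)) {
    parts <- data.table::tstrsplit(dt[[3L + j]], ":", fixed = TRUE)
    if (length(parts) != 6L)
      stop("malformed count field in pool column ", j)
    for (a in 1:6) {
      v <- suppressWarnings(as.integer(parts[[a]]))
      bad <- which(is.na(v))
      if (length(bad))
        stop("malformed count field at line ", bad[1L], ", pool column ", j)
      counts[, a, j] <- v
    }
  }
  pos <- suppressWarnings(as.integer(dt[[2L]]))
  if (anyNA(pos)) stop("malformed position at line ", which(is.na(pos))[1L])
  x <- sync_sites(dt[[1L]], pos, dt[[3L]], counts, sheet$pool_id)
  d <- data.table::data.table(chrom = x$chrom, pos = x$pos)
  if (any(d[, diff(pos) <= 0, by = chrom]$V1))
    stop("positions must be strictly increasing within each chromosome")
  x
}

#' Construct a sync_sites object
#'
#' @param chrom,pos,ref Per-site chromosome, 1-based position, reference base.
#' @param counts Integer array `n_sites x 6 x n_pools` (A,T,C,G,N,del).
#' @param pools Character vector of pool ids (3rd array dimension).
#' @return A `sync_sites` object.
#' @export
sync_sites <- function(chrom, pos, ref, counts, pools) {
  stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
            dim(counts)[1] == length(pos), dim(counts)[2] == 6L,
            dim(counts)[3] == length(pools))
  if (any(pos < 1L)) stop("positions must be >= 1")
  if (any(counts < 0L)) stop("counts must be >= 0")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), counts = counts,
                 pools = as.character(pools)),
            class = "sync_sites")
}

#' @export
print.sync_sites <- function(x, ...) {
  cat("sync_sites:", length(x$pos), "sites,", length(x$pools), "pools (",
      paste(head(x$pools, 8), collapse = ", "), ")\n")
  invisible(x)
}

#' Number of sites in a sync_sites object
#' @param x A `sync_sites` object.
#' @return Integer site count.
#' @export
n_sites <- function(x) length(x$pos)

#' Write a sync-format count table
#'
#' Inverse of [read_sync()]; round-trips byte-identically.
#'
#' @param x A `sync_sites` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sync <- function(x, path) {
  k <- length(x$pools)
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    m <- x$counts[, , j, drop = FALSE]
    dim(m) <- dim(x$counts)[1:2]
    cols[[j]] <- do.call(paste, c(lapply(1:6, function(a) m[, a]), sep = ":"))
  }
  dt <- data.table::data.table(chrom = x$chrom, pos = x$pos, ref = x$ref)
  for (j in seq_len(k)) data.table::set(dt, j = paste0("p", j), value = cols[[j]])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' BED-like TSV with header: `chrom`, `start`, `end` (1-based inclusive),
#' `gene_id`, optional `is_de` flag and `log2fc_e` / `log2fc_m` sex-bias
#' fold-change columns. Missing values are written as `.`.
#'
#' @param path Path to the TSV file.
#' @return A `data.table`, one row per gene, `gene_id` unique.
#' @export
read_gene_annotation <- function(path) {
  g <- data.table::fread(path, sep = "\t", na.strings = ".")
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% names(g)))
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop("duplicate gene_id in annotation")
  if (any(g$start > g$end)) stop("gene interval with start > end")
  if ("is_de" %in% names(g)) g[, is_de := as.logical(is_de)]
  g[]
}

#' Write a result or annotation table as TSV
#'
#' UTF-8, header line, `.` for missing values.
#'
#' @param x A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = ".")
  invisible(path)
}
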