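# Internal helpers shared across modules. Coordinates are 0-based, half-open
# throughout; bin k at resolution r covers [k*r, (k+1)*r).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a genome bin table
#'
#' Tiles each chromosome with fixed-width bins. The last bin of a chromosome
#' is truncated at the chromosome end.
#'
#' @param chrom_sizes data.frame with columns `chrom`, `length` (bp).
#' @param bin_size bin width in bp.
#' @return data.frame with columns `chrom`, `start`, `end`, `bin_id`
#'   (`bin_id` is 0-based and global across chromosomes, in table order).
#' @export
genome_bins <- function(chrom_sizes, bin_size) {
  stopifnot(is.data.frame(chrom_sizes), bin_size > 0)
  out <- do.call(rbind, lapply(seq_len(nrow(chrom_sizes)), function(i) {
    len <- chrom_sizes$length[i]
    starts <- seq(0L, len - 1L, by = bin_size)
    data.frame(chrom = chrom_sizes$chrom[i], start = starts,
               end = pmin(starts + bin_size, len))
  }))
  out$bin_id <- seq_len(nrow(out)) - 1L
  rownames(out) <- NULL
  out
}

# Map (chrom, pos) to 0-based global bin id; NA when outside the bin table.
bin_of <- function(bins, chrom, pos, bin_size) {
  key <- paste0(bins$chrom, ":", bins$start %/% bin_size)
  q <- paste0(chrom, ":", pos %/% bin_size)
  bins$bin_id[match(q, key)]
}

# chrom.sizes from a bin table or genome
sizes_of_bins <- function(bins) {
  agg <- stats::aggregate(end ~ chrom, data = bins, FUN = max)
  names(agg) <- c("chrom", "length")
  agg[match(unique(bins$chrom), agg$chrom), , drop = FALSE]
}

# data.frame(chrom,start,end) -> GRanges (internal; half-open input)
as_granges <- function(df, sizes = NULL) {
  GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(start = df$start + 1L, end = pmax(df$end, df$start + 1L)))
}

# Tiny polynomial string hash (hex) used to fingerprint configurations in
# reports; stays within double-exact integer range.
fnv1a_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Derive a per-stage seed from a master seed (kept below 2^31).
derive_seed <- function(seed, stage) {
  bytes <- utf8ToInt(stage)
  h <- (seed %% 100000) + 1
  for (b in bytes) h <- (h * 31 + b) %% 2147480000
  as.integer(h + 1)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}
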