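# Independent oracles and small fixture builders shared across tests.

# Exhaustive-enumeration hypergeometric upper tail: with M of N cells
# accessible for peak 1, enumerate every possible accessible-cell subset
# of size n for peak 2 and count those sharing >= x cells with the M-set.
hyper_tail_enum <- function(N, M, n, x) {
  if (n == 0L) return(as.numeric(x <= 0L))
  sets <- utils::combn(N, n, simplify = FALSE)
  mset <- seq_len(M)
  mean(vapply(sets, function(s) sum(s %in% mset) >= x, logical(1)))
}

# Exact binomial upper tail P(K >= k), K ~ Binomial(size, 1/2), by direct
# pmf summation.
binom_tail_sum <- function(k, size) {
  if (k <= 0L) return(1)
  sum(choose(size, k:size)) / 2^size
}

# Two-sided exact binomial p at p = 1/2 by summation.
binom_two_sided_sum <- function(n, m) {
  tot <- n + m
  lo <- min(n, m)
  min(1, 2 * sum(choose(tot, 0:lo)) / 2^tot)
}

# A tiny deterministic fragment table.
toy_fragments <- function() {
  fragment_table(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 300L, 700L, 100L),
    end = c(250L, 420L, 900L, 200L),
    cell_id = c("A", "A", "B", "B"),
    r1_meta = c("m01", "m02", "m01", "m03"),
    r2_meta = c("m05", "m05", "m02", "m04")
  ))
}

# GRanges helper with 0-based half-open inputs (BED convention).
gr0 <- function(chrom, start, end, strand = NULL) {
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start + 1L, end))
  if (!is.null(strand)) GenomicRanges::strand(g) <- strand
  g
}
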