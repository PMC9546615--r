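# Fragment construction, PCR deduplication, cross-cell decontamination.
#
# Coordinates are 0-based, half-open (BED convention) throughout. A
# fragment's identity for deduplication and decontamination is its
# FragmentKey: (chrom, start, end, r1_meta, r2_meta).

FRAG_COLS <- c("chrom", "start", "end", "cell_id", "read_count",
               "r1_meta", "r2_meta", "allele")
ALLELE_CODES <- c("M", "P", "I", "U")

#' Build a fragment table
#'
#' Normalises columns into the package's fragment-table layout (chrom,
#' start, end, cell_id, read_count, r1_meta, r2_meta, allele), with
#' 0-based half-open coordinates. Missing `read_count` defaults to 1,
#' missing `allele` to `"U"` (unphased).
#'
#' @param x data.frame-like with at least chrom, start, end, cell_id.
#' @return data.table with the canonical columns, sorted by
#'   (chrom, start, end, cell_id).
#' @export
fragment_table <- function(x) {
  x <- data.table::as.data.table(x)
  for (col in c("chrom", "start", "end", "cell_id"))
    if (!col %in% names(x)) stop("missing column ", col, call. = FALSE)
  if (!"read_count" %in% names(x)) x[, "read_count" := 1L]
  if (!"r1_meta" %in% names(x)) x[, "r1_meta" := NA_character_]
  if (!"r2_meta" %in% names(x)) x[, "r2_meta" := NA_character_]
  if (!"allele" %in% names(x)) x[, "allele" := "U"]
  x[, c("start", "end", "read_count") := list(
    as.integer(start), as.integer(end), as.integer(read_count))]
  if (any(x$start >= x$end))
    stop("fragment with start >= end", call. = FALSE)
  if (any(x$read_count < 1L))
    stop("fragment with read_count < 1", call. = FALSE)
  if (!all(x$allele %in% ALLELE_CODES))
    stop("allele codes must be one of M, P, I, U", call. = FALSE)
  data.table::setcolorder(x, FRAG_COLS)
  x <- x[, FRAG_COLS, with = FALSE]
  data.table::setorderv(x, c("chrom", "start", "end", "cell_id"))
  x[]
}

#' Convert aligned read pairs to Tn5-centered fragments
#'
#' Applies the mapping-quality filter, the proper-pair filter, and the Tn5
#' insertion centering correction: fragment start is the plus-strand mate's
#' start + 4 and fragment end is the minus-strand mate's end - 5 (0-based,
#' half-open). Pairs whose corrected interval is empty or inverted are
#' discarded as physically meaningless.
#'
#' @param pairs data.frame-like with columns `chrom`, `r1_strand` (`"+"` or
#'   `"-"`), `r1_start`, `r1_end`, `r2_start`, `r2_end`, `mapq` (minimum of
#'   the two mates), `is_proper`, `cell_id`, and optionally `r1_meta`,
#'   `r2_meta`.
#' @param min_mapq minimum mapping quality (default 30).
#' @return fragment table of retained pairs (read_count 1 each).
#' @export
pairs_to_fragments <- function(pairs, min_mapq = 30L) {
  p <- data.table::as.data.table(pairs)
  keep <- p$mapq >= min_mapq & p$is_proper
  p <- p[keep]
  plus_start <- ifelse(p$r1_strand == "+", p$r1_start, p$r2_start)
  minus_end <- ifelse(p$r1_strand == "+", p$r2_end, p$r1_end)
  start <- plus_start + 4L
  end <- minus_end - 5L
  ok <- start < end
  out <- data.table::data.table(
    chrom = p$chrom[ok], start = start[ok], end = end[ok],
    cell_id = p$cell_id[ok], read_count = 1L,
    r1_meta = if ("r1_meta" %in% names(p)) p$r1_meta[ok] else NA_character_,
    r2_meta = if ("r2_meta" %in% names(p)) p$r2_meta[ok] else NA_character_,
    allele = "U"
  )
  fragment_table(out)
}

#' Remove PCR duplicates within cells
#'
#' Fragments are grouped by (cell, chrom, start, end, META pair); each
#' group collapses to one representative whose `read_count` is the group's
#' total read support. Identical coordinates with different META pairs are
#' distinct molecules and are kept separate. The total read count is
#' conserved and the operation is idempotent.
#'
#' @param fragments a fragment table.
#' @return deduplicated fragment table.
#' @export
deduplicate <- function(fragments) {
  f <- fragment_table(fragments)
  out <- f[, list(read_count = sum(read_count), allele = allele[1L]),
           by = c("cell_id", "chrom", "start", "end", "r1_meta", "r2_meta")]
  fragment_table(out)
}

#' Remove cross-cell barcode contamination
#'
#' For every FragmentKey (chrom, start, end, META pair) observed in two or
#' more cells, only the copy in the cell with the strictly highest read
#' count is retained; frequency ties are removed from all cells. Each
#' surviving key therefore lives in exactly one cell.
#'
#' @param fragments a deduplicated fragment table (read_count populated).
#' @return list with `fragments` (filtered table) and `cell_stats`
#'   (data.table: cell_id, n_before, n_removed, contamination_rate, where
#'   the rate is removed unique fragments over pre-filter unique fragments).
#' @export
decontaminate <- function(fragments) {
  f <- fragment_table(fragments)
  key <- c("chrom", "start", "end", "r1_meta", "r2_meta")
  f[, c(".ncell", ".mx") := list(.N, max(read_count)), by = key]
  f[, ".nmx" := sum(read_count == .mx), by = key]
  keep <- f$.ncell == 1L | (f$read_count == f$.mx & f$.nmx == 1L)
  before <- f[, list(n_before = .N), by = "cell_id"]
  removed <- f[!keep, list(n_removed = .N), by = "cell_id"]
  stats <- merge(before, removed, by = "cell_id", all.x = TRUE)
  stats[is.na(n_removed), "n_removed" := 0L]
  stats[, "contamination_rate" := n_removed / n_before]
  out <- f[keep]
  out[, c(".ncell", ".mx", ".nmx") := NULL]
  list(fragments = fragment_table(out), cell_stats = stats[])
}

# GRanges view of a fragment table (1-based closed coordinates internally).
frag_granges <- function(fragments) {
  GenomicRanges::GRanges(
    seqnames = fragments$chrom,
    ranges = IRanges::IRanges(start = fragments$start + 1L,
                              end = fragments$end)
  )
}

# Tn5 insertion positions of fragments: both ends, 0-based positions of the
# first and last covered base.
insertion_sites <- function(fragments) {
  data.table::data.table(
    chrom = rep(fragments$chrom, 2L),
    pos = c(fragments$start, fragments$end - 1L),
    cell_id = rep(fragments$cell_id, 2L),
    allele = rep(fragments$allele, 2L)
  )
}
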