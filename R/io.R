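# Readers and writers for the plain-text formats the toolkit exchanges:
# BED intervals, the extended fragments file, sparse matrix exports, FASTQ
# and the run configuration. Readers reject malformed rows with
# line-numbered errors rather than silently skipping them.

#' Read a BED file of intervals
#'
#' Accepts 3+ column tab-delimited BED (0-based, half-open); `track`,
#' `browser` and `#` comment lines are skipped. Column 4 becomes interval
#' names, column 6 the strand, when present. Input need not be sorted.
#'
#' @param path file path (plain or gzip).
#' @return `GRanges` (1-based closed internally, as is conventional in R).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  skip <- grepl("^(track|browser|#)", lines) | lines == ""
  body <- lines[!skip]
  lineno <- which(!skip)
  if (!length(body)) return(GenomicRanges::GRanges())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED row with fewer than 3 columns at line ",
         lineno[which(nf < 3L)[1L]], call. = FALSE)
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("invalid BED interval at line ", lineno[bad[1L]], call. = FALSE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (all(nf >= 4L))
    names(gr) <- vapply(fields, `[[`, character(1), 4L)
  if (all(nf >= 6L)) {
    st <- vapply(fields, `[[`, character(1), 6L)
    GenomicRanges::strand(gr) <- ifelse(st %in% c("+", "-"), st, "*")
  }
  gr
}

#' Write a fragment table to a fragments file
#'
#' Tab-delimited, one fragment per row, columns: chrom, start, end,
#' cell_barcode, read_count, r1_meta, r2_meta, allele. Coordinates are
#' 0-based half-open; the first five columns match the common single-cell
#' fragments format, so third-party tools reading five columns stay
#' compatible. Output is sorted by (chrom, start, end, cell) and written
#' without a header; gzip output is selected by a `.gz` suffix.
#'
#' @param fragments a fragment table.
#' @param path output path.
#' @export
write_fragments <- function(fragments, path) {
  f <- fragment_table(fragments)
  data.table::setnames(f, "cell_id", "cell_barcode")
  data.table::fwrite(f, path, sep = "\t", col.names = FALSE,
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a fragments file
#'
#' Inverse of [write_fragments()]: `write_fragments()` then
#' `read_fragments()` is the identity on the table. Comment-prefixed
#' (`#`) header lines are tolerated. Malformed rows (bad coordinates,
#' read_count < 1, unknown allele code) raise an error naming the first
#' offending line.
#'
#' @param path fragments file (plain or gzip).
#' @return a fragment table.
#' @export
read_fragments <- function(path) {
  con <- gzfile(path)  # transparently handles plain and gzip input
  lines <- readLines(con)
  close(con)
  lines <- lines[!grepl("^#", lines) & lines != ""]
  if (!length(lines))
    return(fragment_table(data.table::data.table(
      chrom = character(0), start = integer(0), end = integer(0),
      cell_id = character(0))))
  dt <- data.table::fread(text = lines, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "cell_id",
                                        "read_count", "r1_meta", "r2_meta",
                                        "allele"),
                          colClasses = list(character = c(1, 4, 6, 7, 8),
                                            integer = c(2, 3, 5)))
  if (nrow(dt) == 0L)
    return(fragment_table(data.table::data.table(
      chrom = character(0), start = integer(0), end = integer(0),
      cell_id = character(0))))
  bad <- which(is.na(dt$start) | is.na(dt$end) | dt$start >= dt$end |
                 is.na(dt$read_count) | dt$read_count < 1L |
                 !dt$allele %in% ALLELE_CODES)
  if (length(bad))
    stop("malformed fragment row at line ", bad[1L], " of ", path,
         call. = FALSE)
  fragment_table(dt)
}

#' Write pair scores as a BEDPE-like table
#'
#' @param results a [score_pairs()] table.
#' @param path output TSV.
#' @export
write_pair_scores <- function(results, path) {
  cols <- c("chrom_i", "start_i", "end_i", "chrom_j", "start_j", "end_j",
            "N", "M", "n", "x", "score")
  data.table::fwrite(data.table::as.data.table(results)[, cols,
                                                        with = FALSE],
                     path, sep = "\t")
  invisible(path)
}

#' Export an accessibility matrix as MatrixMarket plus sidecars
#'
#' Writes `<prefix>.mtx` (cells x peaks pattern matrix),
#' `<prefix>.cells.tsv` and `<prefix>.peaks.tsv` (BED of the peak
#' intervals).
#'
#' @param am an `accessibility_matrix`.
#' @param prefix output path prefix.
#' @export
write_matrix <- function(am, prefix) {
  Matrix::writeMM(methods::as(am$mat, "dMatrix"), paste0(prefix, ".mtx"))
  writeLines(am$cells, paste0(prefix, ".cells.tsv"))
  peaks <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(am$peaks)),
    start = GenomicRanges::start(am$peaks) - 1L,
    end = GenomicRanges::end(am$peaks))
  data.table::fwrite(peaks, paste0(prefix, ".peaks.tsv"), sep = "\t",
                     col.names = FALSE)
  invisible(prefix)
}

#' Read an accessibility matrix written by [write_matrix()]
#'
#' @param prefix path prefix used at write time.
#' @return an `accessibility_matrix`.
#' @export
read_matrix <- function(prefix) {
  mat <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "lMatrix")
  cells <- readLines(paste0(prefix, ".cells.tsv"))
  pk <- data.table::fread(paste0(prefix, ".peaks.tsv"), header = FALSE,
                          col.names = c("chrom", "start", "end"))
  peaks <- GenomicRanges::GRanges(pk$chrom,
                                  IRanges::IRanges(pk$start + 1L, pk$end))
  rownames(mat) <- cells
  accessibility_matrix(mat, peaks, cells)
}

#' Write read pairs as FASTQ
#'
#' @param reads data.table with `read_id`, `r1_seq`, `r2_seq` and optional
#'   quality columns (`r1_qual`, `r2_qual`; constant high quality is
#'   written when absent).
#' @param r1_path,r2_path output FASTQ paths (gzip by suffix).
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  wr <- function(seqs, quals, ids, path) {
    if (is.null(quals)) quals <- strrep("I", nchar(seqs))
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  wr(reads$r1_seq, reads$r1_qual, reads$read_id, r1_path)
  wr(reads$r2_seq, reads$r2_qual, reads$read_id, r2_path)
  invisible(NULL)
}

#' Read paired FASTQ files into a read table
#'
#' @param r1_path,r2_path FASTQ paths (mates in matching order).
#' @return data.table: read_id, r1_seq, r1_qual, r2_seq, r2_qual.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # Biostrings warns (harmlessly) about dropping its own metadata columns
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(r1) != length(r2))
    stop("mate files differ in read count", call. = FALSE)
  data.table::data.table(
    read_id = sub(" .*", "", names(r1)),
    r1_seq = as.character(r1),
    r1_qual = as.character(Biostrings::quality(r1)),
    r2_seq = as.character(r2),
    r2_qual = as.character(Biostrings::quality(r2)))
}

RUN_CONFIG_KEYS <- c("scheme", "min_mapq", "max_bc_mismatch",
                     "max_meta_mismatch", "species_human_cutoff",
                     "species_mouse_cutoff", "xci_lower", "xci_upper",
                     "xci_min_informative", "fdr_alpha", "seed",
                     "output_dir")

#' Load a run configuration file
#'
#' YAML key-value file; unknown keys are hard errors (typo protection for
#' thresholds), and referenced files must exist at load time.
#'
#' @param path YAML file.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$scheme) && !file.exists(cfg$scheme))
    stop("scheme file does not exist: ", cfg$scheme, call. = FALSE)
  cfg
}
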