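# RNA-side read filters and UMI collapsing for the joint ATAC-RNA assay.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Count mismatches of a sequence against an IUPAC template
#'
#' @param sequence character vector of observed sequences.
#' @param pattern a single IUPAC-style template of the same length.
#' @return integer vector: positions whose base is not within the
#'   template's allowed set.
#' @export
pattern_mismatches <- function(sequence, pattern) {
  pat <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  if (any(nchar(sequence) != length(pat)))
    stop("sequence length must match pattern length", call. = FALSE)
  sets <- IUPAC_SETS[pat]
  if (anyNA(names(sets))) stop("invalid IUPAC code in pattern", call. = FALSE)
  vapply(strsplit(toupper(sequence), "", fixed = TRUE), function(ch) {
    sum(!mapply(function(b, s) b %in% s, ch, sets))
  }, integer(1))
}

#' Filter UMI-bearing reads on pattern fidelity and the downstream T run
#'
#' A read is discarded when its UMI has more than `max_pattern_mismatch`
#' bases inconsistent with the designed UMI pattern, or when the 5 bp
#' immediately downstream of the UMI contain fewer than `min_T` T bases
#' (the designed oligo places a T-rich stretch there). Reads with missing
#' downstream bases are discarded with a reason.
#'
#' @param umi character vector of observed UMI sequences.
#' @param downstream_5bp character vector of the 5 bases 3' of each UMI.
#' @param pattern designed UMI pattern (IUPAC template); if supplied, the
#'   mismatch counts are computed from it, otherwise provide
#'   `pattern_mismatch` directly.
#' @param pattern_mismatch optional precomputed mismatch counts.
#' @param max_pattern_mismatch strict upper bound (default 3: discard at
#'   more than three mismatches).
#' @param min_T strict lower bound on T count (default 4: discard below
#'   four).
#' @return data.table: keep (logical), reason (`NA` when kept).
#' @export
filter_umi_read <- function(umi, downstream_5bp, pattern = NULL,
                            pattern_mismatch = NULL,
                            max_pattern_mismatch = 3L, min_T = 4L) {
  if (is.null(pattern_mismatch)) {
    if (is.null(pattern))
      stop("supply pattern or pattern_mismatch", call. = FALSE)
    pattern_mismatch <- pattern_mismatches(umi, pattern)
  }
  n <- length(umi)
  reason <- rep(NA_character_, n)
  missing_ds <- is.na(downstream_5bp) | nchar(downstream_5bp) < 5L
  n_t <- integer(n)
  n_t[!missing_ds] <- vapply(strsplit(downstream_5bp[!missing_ds], "",
                                      fixed = TRUE),
                             function(ch) sum(ch == "T"), integer(1))
  reason[pattern_mismatch > max_pattern_mismatch] <- "UMI_PATTERN"
  bad_t <- is.na(reason) & !missing_ds & n_t < min_T
  reason[bad_t] <- "DOWNSTREAM_T"
  reason[is.na(reason) & missing_ds] <- "MISSING_DOWNSTREAM"
  data.table::data.table(keep = is.na(reason), reason = reason)
}

#' Quality filter for cDNA-bearing R1 reads
#'
#' PolyA tails are trimmed first (a 3'-terminal run of >= `polya_min` A
#' bases is removed); the read is then kept iff (1) its length is at
#' least `min_len`, (2) strictly more than half of its bases have
#' quality greater than `q_threshold`, and (3) strictly less than
#' `max_N_frac` of its bases are N.
#'
#' @param sequence character vector of read sequences.
#' @param qualities list of numeric Phred vectors, or character vector of
#'   Phred+33 quality strings.
#' @param min_len minimum post-trim length (default 40).
#' @param q_threshold quality cutoff (default 38, strict).
#' @param max_N_frac maximum N fraction (default 0.10, strict).
#' @param polya_min minimum polyA run length to trim (default 6).
#' @return logical vector: TRUE = keep.
#' @export
filter_r1_quality <- function(sequence, qualities, min_len = 40L,
                              q_threshold = 38, max_N_frac = 0.10,
                              polya_min = 6L) {
  if (is.character(qualities))
    qualities <- lapply(qualities, function(q) utf8ToInt(q) - 33L)
  stopifnot(length(sequence) == length(qualities))
  keep <- logical(length(sequence))
  for (i in seq_along(sequence)) {
    s <- sequence[[i]]
    q <- qualities[[i]]
    tail_a <- regmatches(s, regexpr("A+$", s))
    if (length(tail_a) && nchar(tail_a) >= polya_min) {
      newlen <- nchar(s) - nchar(tail_a)
      s <- substr(s, 1L, newlen)
      q <- q[seq_len(newlen)]
    }
    len <- nchar(s)
    if (len < min_len) next
    if (sum(q > q_threshold) <= len / 2) next
    n_N <- sum(strsplit(s, "", fixed = TRUE)[[1L]] == "N")
    if (n_N / len >= max_N_frac) next
    keep[i] <- TRUE
  }
  keep
}

#' Collapse UMIs at Hamming distance <= 1
#'
#' Builds the graph whose vertices are the observed UMI sequences of one
#' gene in one cell, with edges between UMIs differing by at most one
#' substitution, and counts connected components: each component is one
#' inferred original molecule. Collapsing is transitive (chains merge)
#' and permutation-invariant.
#'
#' @param umis character vector of equal-length UMI sequences.
#' @return integer molecule count.
#' @export
collapse_umis <- function(umis) {
  umis <- unique(umis)
  k <- length(umis)
  if (k == 0L) return(0L)
  if (length(unique(nchar(umis))) != 1L)
    stop("UMIs must have uniform length", call. = FALSE)
  len <- nchar(umis[1L])
  chars <- matrix(unlist(strsplit(umis, "", fixed = TRUE)),
                  nrow = k, ncol = len, byrow = TRUE)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (a in seq_len(k - 1L)) {
    d <- rowSums(chars[(a + 1L):k, , drop = FALSE] !=
                   rep(chars[a, ], each = k - a))
    for (b in (a + which(d <= 1L))) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1))))
}

#' Count molecules per cell and gene by UMI collapsing
#'
#' @param reads data.frame-like with columns `cell_id`, `gene_id`, `umi`
#'   (post-filter reads).
#' @return data.table: cell_id, gene_id, umi_count.
#' @export
count_umis <- function(reads) {
  r <- data.table::as.data.table(reads)
  if (nrow(r) == 0L)
    return(data.table::data.table(cell_id = character(0),
                                  gene_id = character(0),
                                  umi_count = integer(0)))
  r[, list(umi_count = collapse_umis(umi)), by = c("cell_id", "gene_id")]
}
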