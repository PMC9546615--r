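# Barcode / META-tag scheme and sequence matching.

#' The 19-bp Tn5 mosaic end sequence
#'
#' The Tn5 recognition sequence that appears as adapter read-through at the
#' 3' end of short inserts (and in reverse-complement orientation on the
#' opposite strand).
#' @export
TN5_MOSAIC_END <- "AGATGTGTATAAGAGACAG"

#' Construct a demultiplexing scheme
#'
#' A scheme bundles the per-plate cell barcodes carried on each mate, the
#' set of META tags (transposon end tags used for duplicate discrimination
#' and contamination tracing), the barcode-pair-to-cell table, and the
#' mismatch tolerances used during demultiplexing.
#'
#' Barcode and META sequences are fixed-length within a scheme (barcodes
#' 4-7 nt, META tags 11-13 nt); reads are parsed at the declared lengths.
#'
#' @param r1_barcodes,r2_barcodes named character vectors of cell-barcode
#'   sequences carried on read 1 / read 2 (names are barcode ids).
#' @param meta_tags named character vector of META tag sequences.
#' @param pairs data.frame with columns `cell_id`, `r1_bc`, `r2_bc` mapping
#'   whitelisted barcode-id pairs to cells.
#' @param mosaic_end the 19-nt mosaic end sequence.
#' @param max_bc_mismatch,max_meta_mismatch Hamming-distance tolerances for
#'   barcode and META assignment (defaults 1 and 2).
#' @return an object of class `barcode_scheme`.
#' @export
barcode_scheme <- function(r1_barcodes, r2_barcodes, meta_tags, pairs,
                           mosaic_end = TN5_MOSAIC_END,
                           max_bc_mismatch = 1L, max_meta_mismatch = 2L) {
  check_set <- function(x, what, lo, hi) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
      stop(what, " must be a named character vector", call. = FALSE)
    if (anyDuplicated(x)) stop("duplicate ", what, " sequences", call. = FALSE)
    if (anyDuplicated(names(x))) stop("duplicate ", what, " ids", call. = FALSE)
    len <- unique(nchar(x))
    if (length(len) != 1L)
      stop(what, " must all have the same length", call. = FALSE)
    if (len < lo || len > hi)
      stop(what, " length must be in [", lo, ", ", hi, "]", call. = FALSE)
    len
  }
  bl1 <- check_set(r1_barcodes, "r1_barcodes", 4L, 7L)
  bl2 <- check_set(r2_barcodes, "r2_barcodes", 4L, 7L)
  ml <- check_set(meta_tags, "meta_tags", 11L, 13L)
  if (nchar(mosaic_end) != 19L)
    stop("mosaic_end must be 19 nt", call. = FALSE)
  pairs <- as.data.frame(pairs)
  if (!all(c("cell_id", "r1_bc", "r2_bc") %in% names(pairs)))
    stop("pairs must have columns cell_id, r1_bc, r2_bc", call. = FALSE)
  if (!all(pairs$r1_bc %in% names(r1_barcodes)) ||
      !all(pairs$r2_bc %in% names(r2_barcodes)))
    stop("pairs reference unknown barcode ids", call. = FALSE)
  if (anyDuplicated(pairs$cell_id) ||
      anyDuplicated(paste(pairs$r1_bc, pairs$r2_bc)))
    stop("pairs must map barcode pairs and cells one-to-one", call. = FALSE)
  structure(list(
    r1_barcodes = r1_barcodes, r2_barcodes = r2_barcodes,
    meta_tags = meta_tags, pairs = pairs, mosaic_end = mosaic_end,
    bc_len = c(r1 = bl1, r2 = bl2), meta_len = ml,
    max_bc_mismatch = as.integer(max_bc_mismatch),
    max_meta_mismatch = as.integer(max_meta_mismatch)
  ), class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat("barcode_scheme:", nrow(x$pairs), "cells;",
      length(x$r1_barcodes), "x", length(x$r2_barcodes), "barcodes;",
      length(x$meta_tags), "META tags\n")
  invisible(x)
}

# Draw n codes of given length with pairwise Hamming distance >= min_dist.
# Greedy rejection sampling; deterministic under the surrounding RNG state.
.spaced_codes <- function(n, len, min_dist) {
  bases <- c("A", "C", "G", "T")
  codes <- character(0)
  mats <- NULL
  tries <- 0L
  while (length(codes) < n) {
    tries <- tries + 1L
    if (tries > 50000L) stop("unable to generate spaced codes")
    cand <- sample(bases, len, replace = TRUE)
    ok <- TRUE
    if (!is.null(mats)) {
      d <- colSums(matrix(cand != mats, nrow = len))
      ok <- all(d >= min_dist)
    }
    if (ok) {
      codes <- c(codes, paste(cand, collapse = ""))
      mats <- cbind(mats, cand)
    }
  }
  codes
}

#' Generate an example demultiplexing scheme
#'
#' Builds a deterministic scheme with well-separated barcodes (pairwise
#' Hamming distance >= 3, so a single substitution is always uniquely
#' correctable) and 16 META tags (pairwise distance >= 5, uniquely
#' correctable at two substitutions). Cells are laid out on an
#' r1-barcode x r2-barcode grid, mimicking a plate layout.
#'
#' @param n_cells number of cells to whitelist.
#' @param bc_len,meta_len barcode and META tag lengths.
#' @param n_meta number of META tags (16 by default).
#' @param seed RNG seed controlling code generation.
#' @return a [barcode_scheme()].
#' @export
example_scheme <- function(n_cells = 96L, bc_len = 6L, meta_len = 12L,
                           n_meta = 16L, seed = 1L) {
  withr::with_seed(seed, {
    n_side <- max(2L, ceiling(sqrt(n_cells)))
    b1 <- .spaced_codes(n_side, bc_len, 3L)
    b2 <- .spaced_codes(n_side, bc_len, 3L)
    names(b1) <- sprintf("bc1_%02d", seq_along(b1))
    names(b2) <- sprintf("bc2_%02d", seq_along(b2))
    mt <- .spaced_codes(n_meta, meta_len, 5L)
    names(mt) <- sprintf("m%02d", seq_along(mt))
    grid <- expand.grid(r1_bc = names(b1), r2_bc = names(b2),
                        stringsAsFactors = FALSE)[seq_len(n_cells), ]
    pairs <- data.frame(cell_id = sprintf("cell_%04d", seq_len(n_cells)),
                        r1_bc = grid$r1_bc, r2_bc = grid$r2_bc)
    barcode_scheme(b1, b2, mt, pairs)
  })
}

#' Match sequences against a whitelist with mismatch tolerance
#'
#' Assigns each observed sequence to the unique whitelist entry within
#' `max_mismatch` substitutions (Hamming distance). Observations with no
#' candidate in range, or with two or more candidates tied at the minimum
#' distance, are left unassigned (`NA`): misassignment is treated as worse
#' than loss.
#'
#' @param observed character vector of observed sequences.
#' @param candidates named character vector of whitelist sequences, all the
#'   same length as the observations.
#' @param max_mismatch maximum Hamming distance for assignment.
#' @return character vector of candidate ids, `NA` where unassigned.
#' @export
match_with_mismatch <- function(observed, candidates, max_mismatch) {
  if (length(observed) == 0L) return(character(0))
  len <- unique(nchar(candidates))
  if (length(len) != 1L)
    stop("candidates must all have the same length", call. = FALSE)
  if (any(nchar(observed) != len))
    stop("observed sequences must match candidate length", call. = FALSE)
  obs <- matrix(unlist(strsplit(observed, "", fixed = TRUE),
                       use.names = FALSE),
                nrow = length(observed), ncol = len, byrow = TRUE)
  d <- matrix(0L, nrow = length(observed), ncol = length(candidates))
  for (j in seq_along(candidates)) {
    cc <- strsplit(candidates[[j]], "", fixed = TRUE)[[1L]]
    d[, j] <- rowSums(obs != rep(cc, each = nrow(obs)))
  }
  best <- max.col(-d, ties.method = "first")
  dmin <- d[cbind(seq_len(nrow(d)), best)]
  nmin <- rowSums(d == dmin)
  out <- names(candidates)[best]
  out[dmin > max_mismatch | nmin > 1L] <- NA_character_
  out
}

#' Parse the barcode + META read structure of read pairs
#'
#' Each mate starts with a cell barcode followed by a META tag; both are
#' matched against the scheme with the scheme's mismatch tolerances and the
#' prefixes are removed from the insert. A cell is assigned only when both
#' mates' barcodes resolve and the (r1, r2) barcode pair is whitelisted.
#' META ids are recorded per mate independently of cell assignment.
#'
#' @param reads data.frame / data.table with columns `read_id`, `r1_seq`,
#'   `r2_seq` and optionally `r1_qual`, `r2_qual`.
#' @param scheme a [barcode_scheme()].
#' @return data.table with columns `read_id`, `cell_id`, `r1_meta`,
#'   `r2_meta`, `r1_insert`, `r2_insert` (plus insert qualities when
#'   supplied) and `reason` (`NA` when fully assigned, otherwise
#'   `"TOO_SHORT"`, `"BARCODE_UNASSIGNED"`, `"BARCODE_PAIR_UNKNOWN"`).
#' @export
parse_read_structure <- function(reads, scheme) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  reads <- data.table::as.data.table(reads)
  for (col in c("read_id", "r1_seq", "r2_seq"))
    if (!col %in% names(reads)) stop("reads lacks column ", col, call. = FALSE)
  n <- nrow(reads)
  pre1 <- scheme$bc_len[["r1"]] + scheme$meta_len
  pre2 <- scheme$bc_len[["r2"]] + scheme$meta_len
  too_short <- nchar(reads$r1_seq) < pre1 | nchar(reads$r2_seq) < pre2
  ok <- which(!too_short)

  cell <- rep(NA_character_, n)
  m1 <- rep(NA_character_, n)
  m2 <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  reason[too_short] <- "TOO_SHORT"

  if (length(ok)) {
    bc1 <- substr(reads$r1_seq[ok], 1L, scheme$bc_len[["r1"]])
    bc2 <- substr(reads$r2_seq[ok], 1L, scheme$bc_len[["r2"]])
    mt1 <- substr(reads$r1_seq[ok], scheme$bc_len[["r1"]] + 1L, pre1)
    mt2 <- substr(reads$r2_seq[ok], scheme$bc_len[["r2"]] + 1L, pre2)
    id1 <- match_with_mismatch(bc1, scheme$r1_barcodes, scheme$max_bc_mismatch)
    id2 <- match_with_mismatch(bc2, scheme$r2_barcodes, scheme$max_bc_mismatch)
    m1[ok] <- match_with_mismatch(mt1, scheme$meta_tags,
                                  scheme$max_meta_mismatch)
    m2[ok] <- match_with_mismatch(mt2, scheme$meta_tags,
                                  scheme$max_meta_mismatch)
    pair_key <- paste(id1, id2, sep = "\r")
    tab_key <- paste(scheme$pairs$r1_bc, scheme$pairs$r2_bc, sep = "\r")
    hit <- match(pair_key, tab_key)
    cell[ok] <- scheme$pairs$cell_id[hit]
    bad_bc <- is.na(id1) | is.na(id2)
    reason[ok][bad_bc] <- "BARCODE_UNASSIGNED"
    reason[ok][!bad_bc & is.na(hit)] <- "BARCODE_PAIR_UNKNOWN"
  }

  out <- data.table::data.table(
    read_id = reads$read_id, cell_id = cell,
    r1_meta = m1, r2_meta = m2,
    r1_insert = substr(reads$r1_seq, pre1 + 1L, nchar(reads$r1_seq)),
    r2_insert = substr(reads$r2_seq, pre2 + 1L, nchar(reads$r2_seq)),
    reason = reason
  )
  out[too_short, c("r1_insert", "r2_insert") := ""]
  if ("r1_qual" %in% names(reads))
    out[, "r1_insert_qual" := ifelse(too_short, "",
        substr(reads$r1_qual, pre1 + 1L, nchar(reads$r1_qual)))]
  if ("r2_qual" %in% names(reads))
    out[, "r2_insert_qual" := ifelse(too_short, "",
        substr(reads$r2_qual, pre2 + 1L, nchar(reads$r2_qual)))]
  out[]
}

.revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

# Score adapter occurrences in one read; returns trim window or NULL.
# Semiglobal matching: full internal occurrences, plus terminal partial
# matches of length >= min_overlap at the indicated end.
.best_adapter_hit <- function(seq_chars, ad_chars, end, max_error_rate,
                              min_overlap) {
  n <- length(seq_chars)
  alen <- length(ad_chars)
  best <- NULL
  best_score <- -Inf
  consider <- function(start, L, score_pos) {
    mm <- sum(seq_chars[start:(start + L - 1L)] != ad_chars[score_pos])
    if (mm / L <= max_error_rate) {
      sc <- (L - mm) - mm
      if (sc > best_score) {
        best_score <<- sc
        best <<- c(start = start, len = L)
      }
    }
  }
  if (end == 3L) {
    # adapter begins at position i; truncated only when it runs off the 3' end
    for (i in seq_len(n)) {
      L <- min(alen, n - i + 1L)
      if (L < alen && (i + L - 1L) != n) next
      if (L < min_overlap) next
      consider(i, L, seq_len(L))
    }
  } else {
    # full occurrence anywhere (trim through its end), or adapter suffix
    # overhanging the 5' end (read prefix matches adapter tail)
    if (n >= alen) {
      for (i in seq_len(n - alen + 1L)) consider(i, alen, seq_len(alen))
    }
    for (L in seq(from = min(alen - 1L, n), to = min_overlap, by = -1L)) {
      if (L < min_overlap) break
      consider(1L, L, (alen - L + 1L):alen)
    }
  }
  best
}

#' Trim mosaic-end adapter sequence from an insert
#'
#' Removes Tn5 mosaic-end adapter read-through: the reverse complement of
#' the mosaic end as a 3' adapter (including partial 3'-terminal matches of
#' length >= `min_overlap`), and the mosaic end itself at the 5' end. A
#' match is eligible when its per-base error rate is at most
#' `max_error_rate`; the best-scoring occurrence (matches minus mismatches)
#' is removed. Qualities, when given, are trimmed in lockstep. Reads with
#' no eligible match are returned unchanged.
#'
#' @param sequence character vector of insert sequences.
#' @param quality optional character vector of quality strings.
#' @param mosaic_end the 19-nt mosaic end.
#' @param max_error_rate maximum per-match error rate (default 0.22).
#' @param min_overlap minimum terminal partial-match length (default 3).
#' @return list with elements `sequence` and `quality` (NULL if no
#'   qualities were given).
#' @export
trim_mosaic_end <- function(sequence, quality = NULL,
                            mosaic_end = TN5_MOSAIC_END,
                            max_error_rate = 0.22, min_overlap = 3L) {
  ad3 <- strsplit(.revcomp(mosaic_end), "", fixed = TRUE)[[1L]]
  ad5 <- strsplit(mosaic_end, "", fixed = TRUE)[[1L]]
  seq_out <- sequence
  qual_out <- quality
  for (i in seq_along(sequence)) {
    s <- strsplit(sequence[[i]], "", fixed = TRUE)[[1L]]
    lo <- 1L
    hi <- length(s)
    if (hi == 0L) next
    hit5 <- .best_adapter_hit(s, ad5, 5L, max_error_rate, min_overlap)
    if (!is.null(hit5)) lo <- hit5[["start"]] + hit5[["len"]]
    if (lo <= hi) {
      hit3 <- .best_adapter_hit(s[lo:hi], ad3, 3L, max_error_rate,
                                min_overlap)
      if (!is.null(hit3)) hi <- lo + hit3[["start"]] - 2L
    }
    if (lo > 1L || hi < length(s)) {
      seq_out[[i]] <- if (lo <= hi) substr(sequence[[i]], lo, hi) else ""
      if (!is.null(quality))
        qual_out[[i]] <- if (lo <= hi) substr(quality[[i]], lo, hi) else ""
    }
  }
  list(sequence = seq_out, quality = qual_out)
}
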