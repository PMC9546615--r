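# Hypergeometric peak-pair coaccessibility.
#
# With N cells, a peak accessible in M cells, a second peak accessible in
# n cells and both accessible in x cells, the coaccessibility score is
# -log10 P(X >= x) for X hypergeometric: the upper-tail probability of the
# observed co-occurrence under independence, conditioned on both marginals
# and the full cell universe N.

#' Build a binary cells-by-peaks accessibility matrix
#'
#' A peak is accessible in a cell when at least one fragment of that cell
#' overlaps the peak by >= 1 bp. Cells with no fragments keep an all-zero
#' row and still count toward the cell universe N: the hypergeometric
#' model conditions on all cells passing QC, not only cells with signal.
#'
#' @param fragments a fragment table.
#' @param peaks `GRanges` of peak intervals (typically fixed-width).
#' @param cells optional character vector fixing the cell universe and row
#'   order; defaults to the sorted cells present in `fragments`.
#' @return an `accessibility_matrix` object: sparse logical cells x peaks
#'   matrix plus peak intervals and cached marginals.
#' @export
binarize <- function(fragments, peaks, cells = NULL) {
  if (length(peaks) == 0L) stop("empty peak set", call. = FALSE)
  f <- data.table::as.data.table(fragments)
  if (is.null(cells)) cells <- sort(unique(f$cell_id))
  hits <- GenomicRanges::findOverlaps(frag_granges(f), peaks,
                                      ignore.strand = TRUE)
  ci <- match(f$cell_id[S4Vectors::queryHits(hits)], cells)
  pj <- S4Vectors::subjectHits(hits)
  keep <- !is.na(ci)
  mat <- Matrix::sparseMatrix(i = ci[keep], j = pj[keep], x = TRUE,
                              dims = c(length(cells), length(peaks)),
                              dimnames = list(cells, NULL))
  mat <- methods::as(mat, "lMatrix")
  accessibility_matrix(mat, peaks, cells)
}

#' Construct an accessibility matrix object
#'
#' @param mat sparse logical cells x peaks matrix.
#' @param peaks `GRanges` of the peak intervals (columns).
#' @param cells character vector of cell ids (rows).
#' @return object of class `accessibility_matrix` with fields `mat`,
#'   `peaks`, `cells`, `N` and cached per-peak marginals.
#' @export
accessibility_matrix <- function(mat, peaks, cells = rownames(mat)) {
  stopifnot(nrow(mat) == length(cells), ncol(mat) == length(peaks))
  structure(list(mat = mat, peaks = peaks, cells = cells,
                 N = length(cells),
                 marginals = Matrix::colSums(mat)),
            class = "accessibility_matrix")
}

#' @export
print.accessibility_matrix <- function(x, ...) {
  cat("accessibility_matrix:", x$N, "cells x", length(x$peaks), "peaks;",
      sprintf("%.1f%% occupancy\n",
              100 * sum(x$marginals) / (x$N * length(x$peaks))))
  invisible(x)
}

#' Hypergeometric coaccessibility score
#'
#' Computes `-log10 P(X >= x)` where X follows the hypergeometric
#' distribution of the co-occurrence count of two peaks with marginals M
#' and n among N cells. The tail is evaluated in log space (survival
#' function), so scores well beyond 300 are exact to double precision.
#' The score is 0 when the tail probability is 1 (e.g. when `M = N` or
#' `x` is at the lower feasible bound).
#'
#' @param N number of cells.
#' @param M,n accessible-cell counts of the two peaks.
#' @param x number of cells with both peaks accessible; must lie in
#'   `[max(0, M + n - N), min(M, n)]`.
#' @return nonnegative score(s); vectorised over its arguments.
#' @export
coaccess_score <- function(N, M, n, x) {
  if (any(M < 0 | M > N | n < 0 | n > N))
    stop("marginals must lie in [0, N]", call. = FALSE)
  if (any(x < pmax(0, M + n - N) | x > pmin(M, n)))
    stop("x outside the feasible hypergeometric support", call. = FALSE)
  logp <- stats::phyper(x - 1, M, N - M, n, lower.tail = FALSE,
                        log.p = TRUE)
  score <- -logp / log(10)
  pmax(score, 0)
}

#' Score a set of peak pairs
#'
#' For each pair (i, j), x is the size of the intersection of the two
#' peaks' accessible-cell sets; the score is the hypergeometric tail.
#' Pairs may be long-range or interchromosomal; output order equals input
#' order.
#'
#' @param am an `accessibility_matrix`.
#' @param pairs data.frame-like with integer columns `i`, `j` (peak
#'   indices, i != j).
#' @return data.table with peak coordinates, N, M, n, x, `distance`
#'   (midpoint-to-midpoint; NA across chromosomes) and `score`.
#' @export
score_pairs <- function(am, pairs) {
  p <- data.table::as.data.table(pairs)
  stopifnot(all(c("i", "j") %in% names(p)))
  if (any(p$i == p$j)) stop("pairs must have i != j", call. = FALSE)
  np <- length(am$peaks)
  if (any(p$i < 1L | p$i > np | p$j < 1L | p$j > np))
    stop("pair indices out of range", call. = FALSE)
  x <- unname(Matrix::colSums(am$mat[, p$i, drop = FALSE] &
                                am$mat[, p$j, drop = FALSE]))
  M <- unname(am$marginals[p$i])
  n <- unname(am$marginals[p$j])
  chrom <- as.character(GenomicRanges::seqnames(am$peaks))
  st <- GenomicRanges::start(am$peaks) - 1L  # back to 0-based half-open
  en <- GenomicRanges::end(am$peaks)
  mid <- (st + en) / 2
  data.table::data.table(
    peak_i = p$i, peak_j = p$j,
    chrom_i = chrom[p$i], start_i = st[p$i], end_i = en[p$i],
    chrom_j = chrom[p$j], start_j = st[p$j], end_j = en[p$j],
    N = am$N, M = M, n = n, x = x,
    distance = ifelse(chrom[p$i] == chrom[p$j],
                      abs(mid[p$j] - mid[p$i]), NA_real_),
    score = coaccess_score(am$N, M, n, x)
  )
}

#' Enumerate neighboring peak pairs
#'
#' All same-chromosome pairs whose midpoint-to-midpoint distance is at
#' most `max_distance` (closed bound).
#'
#' @param peaks `GRanges`, any order.
#' @param max_distance maximum center-to-center distance in bp.
#' @return data.table with columns `i`, `j` (i < j) and `distance`.
#' @export
neighbor_pairs <- function(peaks, max_distance) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  mid <- (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    ord <- idx[order(mid[idx])]
    m <- mid[ord]
    hi <- findInterval(m + max_distance, m)
    for (a in seq_along(ord)) {
      if (hi[a] > a) {
        b <- (a + 1L):hi[a]
        out[[length(out) + 1L]] <- data.table::data.table(
          i = pmin(ord[a], ord[b]), j = pmax(ord[a], ord[b]),
          distance = m[b] - m[a])
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(i = integer(0), j = integer(0),
                                  distance = numeric(0)))
  data.table::rbindlist(out)
}

#' Summarise coaccessibility scores by pair distance
#'
#' Bins same-chromosome pairs by midpoint distance and reports mean and
#' median score with pair counts per bin. Empty bins are omitted.
#'
#' @param results a [score_pairs()] table (must contain `distance`).
#' @param bin_edges strictly increasing numeric bin edges.
#' @return data.table: bin_lo, bin_hi, n_pairs, mean_score, median_score.
#' @export
distance_profile <- function(results, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing", call. = FALSE)
  r <- data.table::as.data.table(results)
  r <- r[!is.na(distance)]
  if (nrow(r) == 0L)
    return(data.table::data.table(bin_lo = numeric(0), bin_hi = numeric(0),
                                  n_pairs = integer(0),
                                  mean_score = numeric(0),
                                  median_score = numeric(0)))
  b <- cut(r$distance, bin_edges, right = FALSE, labels = FALSE)
  r <- r[!is.na(b)]
  b <- b[!is.na(b)]
  out <- r[, list(n_pairs = .N, mean_score = mean(score),
                  median_score = stats::median(score)),
           by = list(bin = b)]
  out[, c("bin_lo", "bin_hi") := list(bin_edges[bin], bin_edges[bin + 1L])]
  data.table::setorderv(out, "bin_lo")
  out[, c("bin_lo", "bin_hi", "n_pairs", "mean_score", "median_score"),
      with = FALSE]
}

#' Compare loop-anchor coaccessibility against flanking controls
#'
#' For each loop, the two anchors are mapped to their nearest peaks
#' (skipped, and counted, when no peak lies within `flank_offset`); the
#' control pair takes the peaks nearest to positions offset outward by
#' `flank_offset` from each anchor. Scores are grouped by loop span bins.
#'
#' @param am an `accessibility_matrix`.
#' @param loops data.frame-like with columns `chrom`, `start1`, `end1`,
#'   `start2`, `end2` (0-based half-open anchor intervals, anchor 1
#'   upstream of anchor 2).
#' @param flank_offset control offset in bp (default 10000).
#' @param span_breaks bin edges for loop span grouping.
#' @return data.table with one row per loop and group (`TRUE` anchors /
#'   `FALSE` flanks): loop id, span, span bin, peak indices and score.
#'   The number of skipped loops is in attribute `n_skipped`.
#' @export
anchor_vs_flank <- function(am, loops, flank_offset = 10000,
                            span_breaks = c(0, 1e5, 5e5, Inf)) {
  l <- data.table::as.data.table(loops)
  mid <- (GenomicRanges::start(am$peaks) + GenomicRanges::end(am$peaks)) / 2
  chrom <- as.character(GenomicRanges::seqnames(am$peaks))
  nearest_peak <- function(ch, pos, max_d = Inf) {
    idx <- which(chrom == ch)
    if (!length(idx)) return(NA_integer_)
    d <- abs(mid[idx] - pos)
    k <- which.min(d)
    if (d[k] > max_d) NA_integer_ else idx[k]
  }
  rows <- list()
  n_skipped <- 0L
  for (r in seq_len(nrow(l))) {
    a1 <- (l$start1[r] + l$end1[r]) / 2
    a2 <- (l$start2[r] + l$end2[r]) / 2
    p1 <- nearest_peak(l$chrom[r], a1, flank_offset)
    p2 <- nearest_peak(l$chrom[r], a2, flank_offset)
    f1 <- nearest_peak(l$chrom[r], a1 - flank_offset)
    f2 <- nearest_peak(l$chrom[r], a2 + flank_offset)
    if (is.na(p1) || is.na(p2) || is.na(f1) || is.na(f2) ||
        p1 == p2 || f1 == f2) {
      n_skipped <- n_skipped + 1L
      next
    }
    span <- abs(a2 - a1)
    sc_t <- score_pairs(am, data.frame(i = p1, j = p2))$score
    sc_f <- score_pairs(am, data.frame(i = f1, j = f2))$score
    rows[[length(rows) + 1L]] <- data.table::data.table(
      loop = r, group = c(TRUE, FALSE), span = span,
      span_bin = cut(span, span_breaks, right = FALSE),
      peak_a = c(p1, f1), peak_b = c(p2, f2), score = c(sc_t, sc_f))
  }
  out <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(loop = integer(0), group = logical(0),
                           span = numeric(0), span_bin = factor(),
                           peak_a = integer(0), peak_b = integer(0),
                           score = numeric(0))
  data.table::setattr(out, "n_skipped", n_skipped)
  out
}

#' Precision-recall evaluation of pair scores
#'
#' Ranks labeled pairs by score (descending) and reports precision and
#' recall at every distinct score threshold, plus the area under the PR
#' curve by trapezoid integration over recall. Labeled pairs without a
#' score are treated as score 0.
#'
#' @param scores data.frame-like with columns `pair_id`, `score`.
#' @param labels data.frame-like with columns `pair_id`, `label`
#'   (logical; TRUE = validated).
#' @return list with `curve` (data.table: threshold, precision, recall)
#'   and `auprc`.
#' @export
precision_recall <- function(scores, labels) {
  s <- data.table::as.data.table(scores)
  l <- data.table::as.data.table(labels)
  if (!any(l$label)) stop("no positive labels", call. = FALSE)
  m <- merge(l, s, by = "pair_id", all.x = TRUE)
  m[is.na(score), "score" := 0]
  data.table::setorderv(m, "score", order = -1L)
  tp <- cumsum(m$label)
  fp <- cumsum(!m$label)
  npos <- sum(m$label)
  # collapse tied scores: evaluate at the last index of each distinct score
  last <- rev(!duplicated(rev(m$score)))
  curve <- data.table::data.table(
    threshold = m$score[last],
    precision = (tp / (tp + fp))[last],
    recall = (tp / npos)[last])
  rec <- c(0, curve$recall)
  prec <- c(curve$precision[1L], curve$precision)
  auprc <- sum(diff(rec) * (utils::head(prec, -1L) + prec[-1L]) / 2)
  list(curve = curve, auprc = auprc)
}

#' Cluster items by pairwise coaccessibility
#'
#' Average-linkage hierarchical clustering on the distance
#' `max(score) - score`, cut into `k` groups; the group with the higher
#' mean within-group score is labeled `HIGH` (the rest `LOW`).
#'
#' @param score_matrix symmetric nonnegative matrix of pairwise scores.
#' @param k number of groups (default 2).
#' @return data.table: item, group (integer), label.
#' @export
cluster_by_coaccessibility <- function(score_matrix, k = 2L) {
  m <- as.matrix(score_matrix)
  if (nrow(m) < 2L) stop("need at least 2 items", call. = FALSE)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("score matrix must be symmetric", call. = FALSE)
  d <- max(m) - m
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, k = k)
  within_mean <- vapply(seq_len(k), function(g) {
    idx <- which(grp == g)
    if (length(idx) < 2L) return(-Inf)
    mean(m[idx, idx][upper.tri(m[idx, idx])])
  }, numeric(1))
  high <- which.max(within_mean)
  items <- if (!is.null(rownames(m))) rownames(m) else
    as.character(seq_len(nrow(m)))
  data.table::data.table(
    item = items, group = unname(grp),
    label = ifelse(grp == high & k > 1L, "HIGH",
                   ifelse(k == 1L, "ALL", "LOW")))
}
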