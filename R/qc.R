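# Per-cell and per-dataset quality metrics.

#' Count fragments overlapping peaks (FRiP)
#'
#' A fragment is in peaks when it overlaps at least one peak by >= 1 bp;
#' each fragment is counted at most once. FRiP is the fraction of fragments
#' in peaks; with zero fragments it is undefined and reported as `NA`.
#'
#' @param fragments a fragment table.
#' @param peaks a `GRanges` of peak intervals.
#' @return list with `count` and `frip`.
#' @export
count_in_peaks <- function(fragments, peaks) {
  if (nrow(fragments) == 0L) return(list(count = 0L, frip = NA_real_))
  hits <- GenomicRanges::countOverlaps(frag_granges(fragments), peaks)
  cnt <- sum(hits > 0L)
  list(count = cnt, frip = cnt / nrow(fragments))
}

#' Estimate library complexity with the Lander-Waterman model
#'
#' Solves `U = L * (1 - exp(-T / L))` for the library size `L` given total
#' read count `T` and observed unique fragments `U`, by monotone
#' root-finding to relative tolerance 1e-6. `U = T` (no duplication
#' observed) has no finite solution and returns `Inf`.
#'
#' @param total_reads total reads `T`.
#' @param unique_fragments observed unique fragments `U`, `0 < U <= T`.
#' @return estimated library size (possibly `Inf`).
#' @export
lander_waterman_size <- function(total_reads, unique_fragments) {
  T <- as.numeric(total_reads)
  U <- as.numeric(unique_fragments)
  if (length(T) > 1L || length(U) > 1L)
    return(mapply(lander_waterman_size, T, U))
  if (U <= 0 || T <= 0) stop("counts must be positive", call. = FALSE)
  if (U > T) stop("unique fragments cannot exceed total reads",
                  call. = FALSE)
  if (U == T) return(Inf)
  f <- function(L) L * (1 - exp(-T / L)) - U
  # U(L) increases from U(->0)=0 toward T as L grows; bracket and bisect
  lo <- U
  hi <- max(2 * U, T)
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = .Machine$double.eps^0.5,
                 check.conv = TRUE)$root
}

#' TSS enrichment score
#'
#' Aggregates Tn5 insertion events (both fragment ends) in a strand-aware
#' window of +/- `window` bp around each TSS and reports the mean
#' insertions per bp in the central `center_width` bp divided by the mean
#' insertions per bp in the two outermost `flank_width` bp. With zero
#' flank insertions the score is undefined and reported as `NA`.
#'
#' @param fragments a fragment table.
#' @param tss `GRanges` of TSS positions (width-1 ranges; strand used to
#'   orient the window).
#' @param window half-width of the profile window (default 2000).
#' @param center_width width of the central bin (default 101).
#' @param flank_width width of each outermost flank bin (default 100).
#' @return enrichment score (numeric scalar, possibly `NA`).
#' @export
tss_enrichment <- function(fragments, tss, window = 2000L,
                           center_width = 101L, flank_width = 100L) {
  if (length(tss) == 0L) stop("empty TSS set", call. = FALSE)
  ins <- insertion_sites(fragments)
  ins_gr <- GenomicRanges::GRanges(ins$chrom,
                                   IRanges::IRanges(ins$pos + 1L, ins$pos + 1L))
  win <- GenomicRanges::resize(tss, width = 2L * window + 1L, fix = "center")
  hits <- GenomicRanges::findOverlaps(ins_gr, win, ignore.strand = TRUE)
  if (length(hits) == 0L) return(NA_real_)
  pos <- ins$pos[S4Vectors::queryHits(hits)]
  t_idx <- S4Vectors::subjectHits(hits)
  tss_pos <- GenomicRanges::start(tss)[t_idx] - 1L
  rel <- pos - tss_pos
  minus <- as.character(GenomicRanges::strand(tss))[t_idx] == "-"
  rel[minus] <- -rel[minus]
  half <- (center_width - 1L) %/% 2L
  n_center <- sum(abs(rel) <= half)
  n_flank <- sum(abs(rel) > window - flank_width)
  if (n_flank == 0L) return(NA_real_)
  (n_center / center_width) / (n_flank / (2 * flank_width))
}

#' Classify cells by species in a mixing experiment
#'
#' Computes, per cell, the fraction of fragments aligned to chromosomes of
#' the human genome and applies the strict rule: fraction > 0.9 is a human
#' cell, fraction < 0.1 is a mouse cell, anything else (boundaries
#' included) is a doublet. Cells with zero fragments are UNCLASSIFIED.
#'
#' @param fragments a fragment table covering one or more cells.
#' @param genome_map named character vector mapping chromosome names to
#'   `"HUMAN"` or `"MOUSE"`; every chromosome present must be mapped.
#' @param human_cutoff,mouse_cutoff classification thresholds.
#' @return data.table: cell_id, n_fragments, fraction_human, label.
#' @export
classify_species <- function(fragments, genome_map,
                             human_cutoff = 0.9, mouse_cutoff = 0.1) {
  f <- data.table::as.data.table(fragments)
  unknown <- setdiff(unique(f$chrom), names(genome_map))
  if (length(unknown))
    stop("chromosomes not in genome_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  f[, ".is_human" := genome_map[chrom] == "HUMAN"]
  out <- f[, list(n_fragments = .N, fraction_human = mean(.is_human)),
           by = "cell_id"]
  out[, "label" := data.table::fifelse(
    fraction_human > human_cutoff, "HUMAN",
    data.table::fifelse(fraction_human < mouse_cutoff, "MOUSE", "DOUBLET"))]
  out[n_fragments == 0L, c("fraction_human", "label") :=
        list(NA_real_, "UNCLASSIFIED")]
  out[]
}

#' Count reference DHSs detected by a peak set
#'
#' A DHS is detected when it overlaps at least one called peak by >= 1 bp;
#' each DHS counts once regardless of how many peaks overlap it.
#'
#' @param called_peaks,dhs_reference `GRanges` on the same genome build.
#' @return integer count of detected DHSs.
#' @export
dhs_detected <- function(called_peaks, dhs_reference) {
  sum(GenomicRanges::countOverlaps(dhs_reference, called_peaks,
                                   ignore.strand = TRUE) > 0L)
}

#' Toy coverage-threshold peak caller
#'
#' Calls a peak wherever the aggregated fragment coverage reaches
#' `min_coverage`, merging runs and dropping intervals narrower than
#' `min_width`. This is a deliberately simple caller bundled for
#' saturation analyses and tests; production peak calling is consumed from
#' external callers.
#'
#' @param fragments a fragment table (aggregated across cells).
#' @param min_coverage minimum fragment coverage (default 2).
#' @param min_width minimum peak width in bp (default 50).
#' @return `GRanges` of called peaks.
#' @export
call_peaks_threshold <- function(fragments, min_coverage = 2L,
                                 min_width = 50L) {
  if (nrow(fragments) == 0L) return(GenomicRanges::GRanges())
  cov <- GenomicRanges::coverage(frag_granges(fragments))
  sl <- IRanges::slice(cov, lower = min_coverage, rangesOnly = TRUE)
  gr <- GenomicRanges::GRanges(sl)
  gr[GenomicRanges::width(gr) >= min_width]
}

#' DHS saturation curve by cell down-sampling
#'
#' For each requested cell number, draws `n_replicates` random cell
#' subsets without replacement, aggregates their fragments, calls peaks
#' with the injected `peak_caller`, and records how many reference DHSs
#' the called peaks detect.
#'
#' @param fragments a fragment table.
#' @param cell_numbers integer vector of subset sizes.
#' @param n_replicates independent down-sample replicates per size
#'   (default 10).
#' @param peak_caller function from a fragment table to a `GRanges` of
#'   peaks (default [call_peaks_threshold()]).
#' @param dhs_reference `GRanges` of reference DHSs.
#' @param seed RNG seed for the down-sampling.
#' @return data.table: n_cells, replicate_index, n_dhs_detected.
#' @export
saturation_curve <- function(fragments, cell_numbers, n_replicates = 10L,
                             peak_caller = call_peaks_threshold,
                             dhs_reference, seed = 1L) {
  f <- data.table::as.data.table(fragments)
  cells <- unique(f$cell_id)
  if (any(cell_numbers > length(cells)))
    stop("cell number exceeds available cells", call. = FALSE)
  withr::with_seed(seed, {
    res <- list()
    for (nc in cell_numbers) {
      for (r in seq_len(n_replicates)) {
        sub <- sample(cells, nc, replace = FALSE)
        peaks <- peak_caller(f[f$cell_id %in% sub])
        res[[length(res) + 1L]] <- data.table::data.table(
          n_cells = nc, replicate_index = r,
          n_dhs_detected = dhs_detected(peaks, dhs_reference))
      }
    }
    data.table::rbindlist(res)
  })
}

#' Filter cells on configured QC thresholds
#'
#' Each threshold names a QC metric and supplies an optional `min` and/or
#' `max`. A cell passes when every configured criterion is met; failing
#' cells carry all failure reasons. No configured thresholds means all
#' cells pass: there are no hidden defaults.
#'
#' @param cells data.frame-like per-cell QC table with a `cell_id` column
#'   and one column per metric.
#' @param thresholds named list; each element a list with optional `min`
#'   and `max`. Names must be columns of `cells`.
#' @return data.table: cell_id, pass, reasons (semicolon-joined).
#' @export
qc_filter <- function(cells, thresholds = list()) {
  cells <- data.table::as.data.table(cells)
  unknown <- setdiff(names(thresholds), names(cells))
  if (length(unknown))
    stop("unknown QC metric in thresholds: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  reasons <- vector("list", nrow(cells))
  for (metric in names(thresholds)) {
    th <- thresholds[[metric]]
    v <- cells[[metric]]
    if (!is.null(th$min)) {
      bad <- which(is.na(v) | v < th$min)
      for (i in bad) reasons[[i]] <- c(reasons[[i]],
                                       sprintf("%s < %g", metric, th$min))
    }
    if (!is.null(th$max)) {
      bad <- which(is.na(v) | v > th$max)
      for (i in bad) reasons[[i]] <- c(reasons[[i]],
                                       sprintf("%s > %g", metric, th$max))
    }
  }
  data.table::data.table(
    cell_id = cells$cell_id,
    pass = lengths(reasons) == 0L,
    reasons = vapply(reasons, function(r)
      if (length(r)) paste(r, collapse = "; ") else "", character(1))
  )
}

#' Per-cell QC metric table
#'
#' Computes the per-cell metrics used for cell filtering: fragment counts,
#' mitochondrial fraction, FRiP, promoter ratio (fraction of fragments in
#' TSS +/- 2 kb), TSS enrichment, fraction in reference DHSs, and the
#' Lander-Waterman library-size estimate from read support.
#'
#' @param fragments a fragment table.
#' @param peaks,tss,dhs optional `GRanges`; metrics needing an absent
#'   annotation are reported `NA`.
#' @param contamination optional data.table from [decontaminate()]
#'   (`cell_stats`) supplying contamination_rate.
#' @param mito_chroms chromosome names treated as mitochondrial.
#' @param promoter_window promoter half-width around the TSS (default
#'   2000 bp).
#' @return data.table of per-cell metrics.
#' @export
compute_cell_qc <- function(fragments, peaks = NULL, tss = NULL, dhs = NULL,
                            contamination = NULL,
                            mito_chroms = c("chrM", "MT"),
                            promoter_window = 2000L) {
  f <- fragment_table(fragments)
  out <- f[, list(n_reads = sum(read_count), n_unique_fragments = .N,
                  mito_fraction = mean(chrom %in% mito_chroms)),
           by = "cell_id"]
  out[, "estimated_library_size" :=
        mapply(lander_waterman_size, n_reads, n_unique_fragments)]
  split_cells <- split(seq_len(nrow(f)), f$cell_id)
  ov_frac <- function(gr) {
    hit <- GenomicRanges::countOverlaps(frag_granges(f), gr) > 0L
    vapply(split_cells[out$cell_id], function(i) mean(hit[i]), numeric(1))
  }
  out[, "frip" := if (is.null(peaks)) NA_real_ else ov_frac(peaks)]
  if (is.null(tss)) {
    out[, c("promoter_ratio", "tss_enrichment") := list(NA_real_, NA_real_)]
  } else {
    prom <- GenomicRanges::resize(tss, width = 2L * promoter_window + 1L,
                                  fix = "center")
    out[, "promoter_ratio" := ov_frac(prom)]
    out[, "tss_enrichment" := vapply(split_cells[out$cell_id], function(i)
      tss_enrichment(f[i], tss), numeric(1))]
  }
  out[, "fraction_in_dhs" := if (is.null(dhs)) NA_real_ else ov_frac(dhs)]
  if (!is.null(contamination)) {
    out[, "contamination_rate" :=
          contamination$contamination_rate[
            match(out$cell_id, contamination$cell_id)]]
  } else {
    out[, "contamination_rate" := NA_real_]
  }
  out[]
}
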