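# Seeded synthetic-data generator with ground-truth ledgers.
#
# The generator emulates the statistical structure the analysis modules
# assume -- binary peak accessibility with optional co-accessible modules,
# fragment positions with META pairs, PCR duplicates, cross-cell
# contamination, allele labels with X-inactivation skew -- on a toy genome
# of named ~1 Mb contigs. It makes no attempt at sequence-content realism
# (no GC or insertion-site bias). All randomness flows from a single seed;
# identical (config, seed) give identical outputs.

#' Simulation configuration
#'
#' Defaults describe a mid-sized plate experiment: 600 cells, 200
#' fixed-width (501 bp) peaks across three 1-Mb autosomes plus chrX and a
#' mitochondrial contig, per-peak baseline accessibility drawn uniformly
#' from \[0.05, 0.5\], a 10% PCR duplication rate, 2% cross-cell
#' contamination, and X inactivation with a 0.98 skew toward the active
#' allele.
#'
#' @param n_cells number of cells.
#' @param n_peaks number of autosomal peaks.
#' @param peak_width fixed peak width in bp (default 501).
#' @param baseline_prob per-peak accessibility probability: scalar, vector
#'   of length `n_peaks`, or `NULL` to draw uniformly from
#'   `baseline_range`.
#' @param baseline_range range for drawn baseline probabilities.
#' @param modules list of co-accessible modules, each a list with `peaks`
#'   (peak indices), `latent_prob`, `activation`, `leak`; module peak sets
#'   must be disjoint.
#' @param contigs named numeric vector of contig lengths.
#' @param frag_len_range fragment length range in bp.
#' @param max_frags_per_open maximum fragments emitted per accessible
#'   (cell, peak) entry.
#' @param background_per_cell fragments scattered per cell outside the
#'   peak-generating process.
#' @param mito_per_cell mitochondrial fragments per cell.
#' @param duplication_rate probability a fragment carries PCR duplicates.
#' @param max_extra_dups maximum extra read copies per duplicated fragment.
#' @param contamination_rate fraction of fragments copied into another
#'   cell (always with strictly lower read support).
#' @param barcode_error_rate per-base substitution rate in barcode and
#'   META prefixes of simulated reads.
#' @param x_frags_per_cell chrX fragments per cell.
#' @param x_informative_frac fraction of chrX fragments carrying a SNP
#'   label.
#' @param xci_skew fraction of informative chrX fragments from the active
#'   allele.
#' @param allelic_regions optional data.frame with columns `peak` (index)
#'   and `maternal_frac`: peaks whose fragments carry planted allelic
#'   imbalance.
#' @param meta_ids META tag ids used to draw tag pairs.
#' @param x_chrom,mito_chrom contig names for chrX / mitochondria.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cells = 600L, n_peaks = 200L, peak_width = 501L,
                       baseline_prob = NULL, baseline_range = c(0.05, 0.5),
                       modules = list(),
                       contigs = c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6,
                                   chrX = 1e6, chrM = 16299),
                       frag_len_range = c(50L, 400L),
                       max_frags_per_open = 3L,
                       background_per_cell = 20L, mito_per_cell = 2L,
                       duplication_rate = 0.1, max_extra_dups = 3L,
                       contamination_rate = 0.02,
                       barcode_error_rate = 0.01,
                       x_frags_per_cell = 30L, x_informative_frac = 0.9,
                       xci_skew = 0.98,
                       allelic_regions = NULL,
                       meta_ids = sprintf("m%02d", 1:16),
                       x_chrom = "chrX", mito_chrom = "chrM") {
  cfg <- as.list(environment())
  probs <- c(baseline_range, duplication_rate, contamination_rate,
             barcode_error_rate, x_informative_frac, xci_skew)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  mod_peaks <- unlist(lapply(modules, `[[`, "peaks"))
  if (anyDuplicated(mod_peaks))
    stop("module peak sets must be disjoint", call. = FALSE)
  if (length(mod_peaks) && any(mod_peaks > n_peaks))
    stop("module peak index out of range", call. = FALSE)
  for (m in modules) {
    pr <- c(m$latent_prob, m$activation, m$leak)
    if (length(pr) != 3L || any(pr < 0 | pr > 1))
      stop("each module needs latent_prob, activation, leak in [0, 1]",
           call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Peak layout of a simulation configuration
#'
#' Evenly spaced fixed-width peaks on the autosomal contigs of the toy
#' genome; the deterministic layout used by [simulate_accessibility()].
#'
#' @param config a [sim_config()].
#' @return `GRanges` of peak intervals.
#' @export
sim_peaks <- function(config) {
  autos <- setdiff(names(config$contigs),
                   c(config$x_chrom, config$mito_chrom))
  per <- diff(round(seq(0, config$n_peaks, length.out = length(autos) + 1)))
  chrom <- character(0)
  start0 <- numeric(0)
  for (k in seq_along(autos)) {
    np <- per[k]
    if (np == 0L) next
    len <- config$contigs[[autos[k]]]
    starts <- round(seq(2000, len - config$peak_width - 2000,
                        length.out = np))
    chrom <- c(chrom, rep(autos[k], np))
    start0 <- c(start0, starts)
  }
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start0 + 1L,
                                          start0 + config$peak_width))
}

.sim_access_core <- function(config) {
  nc <- config$n_cells
  np <- config$n_peaks
  cells <- sprintf("cell_%04d", seq_len(nc))
  p <- config$baseline_prob
  if (is.null(p)) {
    p <- stats::runif(np, config$baseline_range[1], config$baseline_range[2])
  } else {
    p <- rep_len(p, np)
  }
  prob <- matrix(p, nrow = nc, ncol = np, byrow = TRUE)
  latents <- NULL
  module_of_peak <- rep(NA_integer_, np)
  if (length(config$modules)) {
    latents <- matrix(FALSE, nrow = nc, ncol = length(config$modules))
    for (j in seq_along(config$modules)) {
      m <- config$modules[[j]]
      latents[, j] <- stats::runif(nc) < m$latent_prob
      module_of_peak[m$peaks] <- j
      prob[, m$peaks] <- ifelse(latents[, j], m$activation, m$leak)
    }
  }
  open <- matrix(stats::runif(nc * np), nc, np) < prob
  mat <- methods::as(Matrix::Matrix(open, sparse = TRUE), "lMatrix")
  rownames(mat) <- cells
  peaks <- sim_peaks(config)
  list(am = accessibility_matrix(mat, peaks, cells),
       truth = list(peak_probs = p, latents = latents,
                    module_of_peak = module_of_peak))
}

#' Simulate a binary accessibility matrix
#'
#' Peaks outside any module are independent Bernoulli draws at their
#' baseline probability; peaks of a co-accessible module share a per-cell
#' latent on/off state and are drawn at the module's activation
#' probability when the latent is on, its leak probability otherwise.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `am` (an `accessibility_matrix`) and `truth`
#'   (per-peak probabilities, per-cell module latents, peak-to-module
#'   map).
#' @export
simulate_accessibility <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, .sim_access_core(config))
}

# Substitute bases at the given per-base rate. Substitutions draw from all
# four bases, so the realised change rate is 3/4 of `rate`.
.inject_subs <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  len <- nchar(seqs[1L])
  nerr <- stats::rbinom(length(seqs), len, rate)
  bases <- c("A", "C", "G", "T")
  idx <- which(nerr > 0L)
  for (i in idx) {
    pos <- sample.int(len, nerr[i])
    for (p in pos) substr(seqs[i], p, p) <- sample(bases, 1L)
  }
  seqs
}

.sim_fragments_core <- function(config, acc) {
  nc <- config$n_cells
  cells <- acc$am$cells
  peaks <- acc$am$peaks
  fl <- config$frag_len_range
  rand_len <- function(n) sample(seq(fl[1], fl[2]), n, replace = TRUE)
  meta_pair <- function(n) list(
    r1 = sample(config$meta_ids, n, replace = TRUE),
    r2 = sample(config$meta_ids, n, replace = TRUE))

  parts <- list()

  # fragments inside accessible peaks
  tm <- methods::as(acc$am$mat, "TsparseMatrix")
  on <- if (length(tm@x)) which(tm@x) else seq_along(tm@i)
  ei <- tm@i[on] + 1L
  ej <- tm@j[on] + 1L
  if (length(ei)) {
    k <- sample.int(config$max_frags_per_open, length(ei), replace = TRUE)
    ci <- rep(ei, k)
    pj <- rep(ej, k)
    n <- length(ci)
    len <- rand_len(n)
    pstart <- GenomicRanges::start(peaks)[pj] - 1L
    pwidth <- GenomicRanges::width(peaks)[pj]
    off <- floor(stats::runif(n) * pmax(1L, pwidth - len))
    start <- pstart + off
    mp <- meta_pair(n)
    allele <- rep("U", n)
    if (!is.null(config$allelic_regions)) {
      ar <- data.table::as.data.table(config$allelic_regions)
      hit <- match(pj, ar$peak)
      lab <- which(!is.na(hit))
      frac <- ar$maternal_frac[hit[lab]]
      allele[lab] <- ifelse(stats::runif(length(lab)) < frac, "M", "P")
    }
    parts$peak <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(peaks))[pj],
      start = start, end = start + len, cell_id = cells[ci],
      r1_meta = mp$r1, r2_meta = mp$r2, allele = allele, peak = pj)
  }

  autos <- setdiff(names(config$contigs),
                   c(config$x_chrom, config$mito_chrom))
  scatter <- function(n_per_cell, chroms) {
    n <- n_per_cell * nc
    if (n == 0L) return(NULL)
    ch <- sample(chroms, n, replace = TRUE)
    len <- rand_len(n)
    start <- floor(stats::runif(n) * (config$contigs[ch] - len - 10))
    mp <- meta_pair(n)
    data.table::data.table(
      chrom = ch, start = start, end = start + len,
      cell_id = rep(cells, each = n_per_cell),
      r1_meta = mp$r1, r2_meta = mp$r2, allele = "U", peak = NA_integer_)
  }
  parts$background <- scatter(config$background_per_cell, autos)
  parts$mito <- scatter(config$mito_per_cell, config$mito_chrom)

  # chrX fragments with allele labels per the cell's XCI state
  xci <- data.table::data.table(
    cell_id = cells,
    inactive_parent = sample(c("XM", "XP"), nc, replace = TRUE))
  if (config$x_frags_per_cell > 0L) {
    xf <- scatter(config$x_frags_per_cell, config$x_chrom)
    inact <- rep(xci$inactive_parent, each = config$x_frags_per_cell)
    informative <- stats::runif(nrow(xf)) < config$x_informative_frac
    from_active <- stats::runif(nrow(xf)) < config$xci_skew
    # active allele is maternal when the paternal X is inactive
    active_is_m <- inact == "XP"
    lab <- ifelse(from_active == active_is_m, "M", "P")
    xf[, "allele" := ifelse(informative, lab, "U")]
    parts$x <- xf
  }

  f <- data.table::rbindlist(parts, use.names = TRUE)
  f[, "peak" := NULL]

  # enforce key uniqueness among true fragments so that duplication and
  # contamination events are exactly the injected ones
  key <- c("chrom", "start", "end", "r1_meta", "r2_meta")
  for (pass in 1:20) {
    dup <- duplicated(f, by = key)
    if (!any(dup)) break
    f[dup, "end" := end + 1L]
  }

  # PCR duplicates: extra read copies of the same FragmentKey in-cell
  n <- nrow(f)
  dup_extra <- ifelse(stats::runif(n) < config$duplication_rate,
                      sample.int(config$max_extra_dups, n, replace = TRUE),
                      0L)
  f[, "read_count" := 1L + dup_extra]

  truth_frag <- fragment_table(f)

  # contamination: copy keys into another cell at strictly lower counts
  n_cont <- round(config$contamination_rate * n)
  cont <- NULL
  observed <- data.table::copy(f)
  if (n_cont > 0L && nc > 1L) {
    pick <- sample.int(n, n_cont)
    observed[pick, "read_count" := pmax(read_count, 2L)]
    src <- observed[pick]
    recipient <- cells[(match(src$cell_id, cells) - 1L +
                          sample.int(nc - 1L, n_cont, replace = TRUE)) %%
                         nc + 1L]
    cont_rows <- data.table::copy(src)
    cont_rows[, "cell_id" := recipient]
    cont_rows[, "read_count" :=
                1L + as.integer(floor(stats::runif(n_cont) *
                                        (src$read_count - 1L)))]
    cont <- data.table::data.table(
      chrom = src$chrom, start = src$start, end = src$end,
      r1_meta = src$r1_meta, r2_meta = src$r2_meta,
      owner = src$cell_id, recipient = recipient,
      owner_count = src$read_count, recipient_count = cont_rows$read_count)
    observed <- rbind(observed, cont_rows)
  }

  list(fragments = fragment_table(observed),
       records = NULL,
       truth = list(
         owner_fragments = fragment_table(observed[
           !cont_key(observed, cont)]),
         contamination = cont,
         xci = xci,
         accessibility = acc$truth,
         peaks = peaks))
}

# rows of `f` that are injected contamination copies
cont_key <- function(f, cont) {
  if (is.null(cont)) return(rep(FALSE, nrow(f)))
  a <- paste(f$chrom, f$start, f$end, f$r1_meta, f$r2_meta, f$cell_id)
  b <- paste(cont$chrom, cont$start, cont$end, cont$r1_meta, cont$r2_meta,
             cont$recipient)
  a %in% b
}

#' Simulate a fragment table with ground truth
#'
#' Draws an accessibility matrix (unless one is supplied), emits 1-3
#' fragments inside each accessible (cell, peak) entry with random META
#' pairs, scatters background, mitochondrial and chrX fragments, injects
#' PCR duplicates as extra read support and cross-cell contamination as
#' key copies with strictly lower read counts, and labels chrX (and
#' optionally planted-imbalance) fragments with parental alleles.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param accessibility optional result of [simulate_accessibility()]; by
#'   default one is drawn inside the same seeded stream.
#' @return list with `fragments` (the observed, deduplicated table,
#'   contamination included) and `truth` (owner fragments, contamination
#'   events, per-cell XCI states, accessibility truth, peak intervals).
#' @export
simulate_fragments <- function(config, seed = 1L, accessibility = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(seed, {
    acc <- if (is.null(accessibility)) .sim_access_core(config) else
      accessibility
    .sim_fragments_core(config, acc)
  })
}

#' Simulate raw read pairs from a fragment table
#'
#' Expands each fragment into `read_count` read pairs. Each mate carries
#' its cell barcode and META tag prefix (substitution errors injected at
#' `barcode_error_rate` per base) followed by a fixed insert stub; the
#' matching alignment table carries the un-corrected genomic coordinates
#' (plus-strand start 4 bp before the fragment start, minus-strand end
#' 5 bp after the fragment end) so that Tn5-centered fragment
#' construction recovers the original interval.
#'
#' @param fragments a fragment table (e.g. from [simulate_fragments()]).
#' @param scheme a [barcode_scheme()] whose whitelist covers all cells in
#'   `fragments`.
#' @param config a [sim_config()] (for the error rate).
#' @param seed RNG seed.
#' @return list with `reads` (read_id, r1_seq, r2_seq), `alignments`
#'   (SAM-like pair table for [pairs_to_fragments()]) and `truth`
#'   (read_id to true cell and META pair).
#' @export
simulate_reads <- function(fragments, scheme, config, seed = 1L) {
  stopifnot(inherits(scheme, "barcode_scheme"),
            inherits(config, "sim_config"))
  f <- fragment_table(fragments)
  miss <- setdiff(unique(f$cell_id), scheme$pairs$cell_id)
  if (length(miss))
    stop("scheme does not whitelist cells: ", miss[1L], ", ...",
         call. = FALSE)
  withr::with_seed(seed, {
    rows <- rep(seq_len(nrow(f)), f$read_count)
    n <- length(rows)
    read_id <- sprintf("read_%08d", seq_len(n))
    cell <- f$cell_id[rows]
    hit <- match(cell, scheme$pairs$cell_id)
    bc1 <- scheme$r1_barcodes[scheme$pairs$r1_bc[hit]]
    bc2 <- scheme$r2_barcodes[scheme$pairs$r2_bc[hit]]
    mt1 <- scheme$meta_tags[f$r1_meta[rows]]
    mt2 <- scheme$meta_tags[f$r2_meta[rows]]
    insert <- strrep("ACGT", 8L)
    rate <- config$barcode_error_rate
    reads <- data.table::data.table(
      read_id = read_id,
      r1_seq = paste0(.inject_subs(unname(bc1), rate),
                      .inject_subs(unname(mt1), rate), insert),
      r2_seq = paste0(.inject_subs(unname(bc2), rate),
                      .inject_subs(unname(mt2), rate), insert))
    read_len <- 50L
    aln <- data.table::data.table(
      read_id = read_id,
      chrom = f$chrom[rows],
      r1_strand = "+",
      r1_start = f$start[rows] - 4L,
      r1_end = pmin(f$start[rows] - 4L + read_len, f$end[rows] + 5L),
      r2_start = pmax(f$end[rows] + 5L - read_len, f$start[rows] - 4L),
      r2_end = f$end[rows] + 5L,
      mapq = 60L,
      is_proper = TRUE)
    truth <- data.table::data.table(
      read_id = read_id, cell_id = cell,
      r1_meta = f$r1_meta[rows], r2_meta = f$r2_meta[rows],
      chrom = f$chrom[rows], start = f$start[rows], end = f$end[rows])
    list(reads = reads, alignments = aln, truth = truth)
  })
}

#' Simulate per-region parental allele counts
#'
#' Draws region depths uniformly from `depth_range` and splits each
#' depth binomially with the region's maternal fraction; used for
#' calibration and power checks of the allele-specificity statistic.
#'
#' @param n_regions number of regions.
#' @param depth_range range of total informative counts `n + m`.
#' @param maternal_frac true maternal fraction (scalar or per-region).
#' @param seed RNG seed.
#' @return data.table: region, n (paternal), m (maternal),
#'   true_maternal_frac.
#' @export
simulate_allele_counts <- function(n_regions, depth_range = c(10L, 100L),
                                   maternal_frac = 0.5, seed = 1L) {
  withr::with_seed(seed, {
    depth <- sample(seq(depth_range[1], depth_range[2]), n_regions,
                    replace = TRUE)
    frac <- rep_len(maternal_frac, n_regions)
    m <- stats::rbinom(n_regions, depth, frac)
    data.table::data.table(region = seq_len(n_regions),
                           n = depth - m, m = m,
                           true_maternal_frac = frac)
  })
}

#' Run the read-processing pipeline on raw reads plus alignments
#'
#' Convenience wrapper chaining demultiplexing, fragment construction,
#' deduplication and decontamination: parses read structure, joins cell
#' and META assignments onto the alignment table, keeps fully assigned
#' pairs, applies the Tn5-centered conversion and the MAPQ/proper-pair
#' filters, and removes duplicates and cross-cell contamination.
#'
#' @param reads data.table of read pairs (`read_id`, `r1_seq`, `r2_seq`).
#' @param alignments SAM-like pair table (see [pairs_to_fragments()]),
#'   keyed by `read_id`.
#' @param scheme a [barcode_scheme()].
#' @param min_mapq minimum mapping quality.
#' @return list with `fragments`, `cell_stats`, `tagged` (the per-read
#'   assignment table).
#' @export
demux_to_fragments <- function(reads, alignments, scheme, min_mapq = 30L) {
  tagged <- parse_read_structure(reads, scheme)
  ok <- tagged[!is.na(cell_id) & !is.na(r1_meta) & !is.na(r2_meta)]
  aln <- data.table::as.data.table(alignments)
  pairs <- merge(aln, ok[, c("read_id", "cell_id", "r1_meta", "r2_meta"),
                         with = FALSE], by = "read_id")
  frags <- pairs_to_fragments(pairs, min_mapq = min_mapq)
  dedup <- deduplicate(frags)
  dec <- decontaminate(dedup)
  list(fragments = dec$fragments, cell_stats = dec$cell_stats,
       tagged = tagged)
}
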