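# Allele-specific accessibility: fragment labeling, the specificity
# statistic S, monoallelic peak calling, promoter specificity, and
# X-inactivation assignment.
#
# Allele codes on fragments: "M" maternal, "P" paternal, "I" inconclusive,
# "U" unphased (no SNP observation).

#' Label a fragment's allele of origin from its SNP observations
#'
#' A fragment with no SNP observation is unphased (`"U"`). If every
#' observed base matches one parent's genotype, the fragment is labeled
#' with that parent (`"M"`/`"P"`). Observations supporting both parents,
#' or any base matching neither parent, make the fragment inconclusive
#' (`"I"`); inconclusive fragments are excluded from allele-specific
#' analysis downstream.
#'
#' @param observed_base,maternal_base,paternal_base character vectors of
#'   equal length: the base seen in the read and the two parental
#'   genotypes at each covered SNP site of one fragment.
#' @return one of `"M"`, `"P"`, `"I"`, `"U"`.
#' @export
label_fragment_allele <- function(observed_base, maternal_base,
                                  paternal_base) {
  if (length(observed_base) == 0L) return("U")
  is_m <- observed_base == maternal_base
  is_p <- observed_base == paternal_base
  if (any(!is_m & !is_p)) return("I")
  if (any(is_m) && any(is_p)) return("I")
  if (all(is_m)) "M" else "P"
}

#' Attach allele labels to a fragment table
#'
#' Applies [label_fragment_allele()] per fragment given a per-observation
#' SNP table keyed by fragment index.
#'
#' @param fragments a fragment table.
#' @param observations data.frame-like with columns `fragment` (row index
#'   into `fragments`), `observed_base`, `maternal_base`, `paternal_base`.
#' @return the fragment table with its `allele` column filled in
#'   (fragments without observations become `"U"`).
#' @export
assign_alleles <- function(fragments, observations) {
  f <- fragment_table(fragments)
  obs <- data.table::as.data.table(observations)
  f[, "allele" := "U"]
  if (nrow(obs)) {
    lab <- obs[, list(allele = label_fragment_allele(
      observed_base, maternal_base, paternal_base)), by = "fragment"]
    f[lab$fragment, "allele" := lab$allele]
  }
  f[]
}

#' Parental accessibility counts per region
#'
#' Accumulates paternal (`n`) and maternal (`m`) accessibility in each
#' region from allele-labeled fragments; unphased and inconclusive
#' fragments contribute nothing. In `"insertions"` mode (default) each
#' fragment contributes its Tn5 insertion ends that fall inside the
#' region (up to 2); in `"fragments"` mode each overlapping fragment
#' contributes 1.
#'
#' @param fragments an allele-labeled fragment table.
#' @param regions `GRanges` of regions.
#' @param count_mode `"insertions"` or `"fragments"`.
#' @return data.table: region (index into `regions`), n (paternal),
#'   m (maternal), one row per region.
#' @export
region_allele_counts <- function(fragments, regions,
                                 count_mode = c("insertions", "fragments")) {
  count_mode <- match.arg(count_mode)
  f <- data.table::as.data.table(fragments)
  f <- f[f$allele %in% c("M", "P")]
  n_reg <- length(regions)
  tally <- data.table::data.table(region = seq_len(n_reg), n = 0L, m = 0L)
  if (nrow(f)) {
    if (count_mode == "insertions") {
      ins <- insertion_sites(f)
      gr <- GenomicRanges::GRanges(ins$chrom,
                                   IRanges::IRanges(ins$pos + 1L,
                                                    ins$pos + 1L))
      allele <- ins$allele
    } else {
      gr <- frag_granges(f)
      allele <- f$allele
    }
    hits <- GenomicRanges::findOverlaps(gr, regions, ignore.strand = TRUE)
    if (length(hits)) {
      dt <- data.table::data.table(
        region = S4Vectors::subjectHits(hits),
        allele = allele[S4Vectors::queryHits(hits)])
      cnt <- dt[, list(n = sum(allele == "P"), m = sum(allele == "M")),
                by = "region"]
      tally[cnt$region, c("n", "m") := list(cnt$n, cnt$m)]
    }
  }
  tally[]
}

#' Allele-specificity statistic S
#'
#' For paternal count `n` and maternal count `m`, with
#' `K ~ Binomial(n + m, 1/2)`,
#' `S = log10 P(K >= n) - log10 P(K >= m)`. Positive S indicates the
#' maternal allele is more accessible; negative S the paternal allele.
#' S is antisymmetric (`S(n, m) = -S(m, n)`) and `S(n, n) = 0`. Tails are
#' the normalised binomial survival function, evaluated in log space.
#' `n + m = 0` is undefined and returns `NA`.
#'
#' @param n,m nonnegative integer counts (vectorised).
#' @return signed specificity score(s).
#' @export
allele_specificity <- function(n, m) {
  tot <- n + m
  lt_n <- stats::pbinom(n - 1, tot, 0.5, lower.tail = FALSE, log.p = TRUE)
  lt_m <- stats::pbinom(m - 1, tot, 0.5, lower.tail = FALSE, log.p = TRUE)
  out <- (lt_n - lt_m) / log(10)
  out[tot == 0] <- NA_real_
  out
}

# Exact two-sided binomial p-value at p = 1/2 (symmetric distribution):
# twice the smaller tail, capped at 1.
binom_p_two_sided <- function(n, m) {
  tot <- n + m
  p <- 2 * stats::pbinom(pmin(n, m), tot, 0.5)
  out <- pmin(p, 1)
  out[tot == 0] <- NA_real_
  out
}

#' Call monoallelically accessible regions
#'
#' Per region, an exact two-sided binomial test of the paternal count
#' against `p = 1/2`, with Benjamini-Hochberg adjustment across the tested
#' regions (regions with zero informative counts are not tested).
#' Significant regions are flagged MATERNAL when `m > n`, PATERNAL when
#' `n > m`.
#'
#' @param counts data.frame-like with columns `region`, `n`, `m`.
#' @param alpha FDR level (default 0.05).
#' @param fdr_method multiple-testing method passed to [stats::p.adjust()].
#' @return data.table: region, n, m, S, p, q, direction, significant.
#' @export
call_monoallelic <- function(counts, alpha = 0.05, fdr_method = "BH") {
  cc <- data.table::as.data.table(counts)
  if (nrow(cc) == 0L)
    return(data.table::data.table(
      region = integer(0), n = integer(0), m = integer(0), S = numeric(0),
      p = numeric(0), q = numeric(0), direction = character(0),
      significant = logical(0)))
  stopifnot(alpha > 0, alpha < 1)
  out <- cc[, c("region", "n", "m"), with = FALSE]
  out[, "S" := allele_specificity(n, m)]
  out[, "p" := binom_p_two_sided(n, m)]
  out[, "q" := NA_real_]
  tested <- which(!is.na(out$p))
  out[tested, "q" := stats::p.adjust(out$p[tested], method = fdr_method)]
  out[, "direction" := data.table::fifelse(
    m > n, "MATERNAL", data.table::fifelse(n > m, "PATERNAL", "NONE"))]
  out[, "significant" := !is.na(q) & q < alpha & direction != "NONE"]
  out[]
}

#' Promoter allele specificity per gene
#'
#' Defines a promoter as TSS +/- `promoter_window` (strand-aware TSS
#' position) and computes allele counts, S and the two-sided binomial p
#' per promoter. Isoforms with distinct TSSs yield separate rows. Genes
#' with no informative counts get `NA` statistics. Fed allele-resolved
#' transcript counts instead of fragments, the same statistic quantifies
#' expression specificity.
#'
#' @param genes data.frame-like with columns `gene`, `chrom`, `tss`
#'   (0-based position), `strand`.
#' @param fragments an allele-labeled fragment table.
#' @param promoter_window half-width in bp (default 2000).
#' @param count_mode passed to [region_allele_counts()].
#' @return data.table: gene, chrom, tss, n, m, S, p.
#' @export
promoter_specificity <- function(genes, fragments, promoter_window = 2000L,
                                 count_mode = "insertions") {
  g <- data.table::as.data.table(genes)
  prom <- GenomicRanges::GRanges(
    g$chrom,
    IRanges::IRanges(pmax(1L, g$tss + 1L - promoter_window),
                     g$tss + 1L + promoter_window),
    strand = g$strand)
  cnt <- region_allele_counts(fragments, prom, count_mode = count_mode)
  out <- data.table::data.table(
    gene = g$gene, chrom = g$chrom, tss = g$tss,
    n = cnt$n, m = cnt$m)
  out[, "S" := allele_specificity(n, m)]
  out[, "p" := binom_p_two_sided(n, m)]
  out[]
}

#' Assign X-inactivation state per cell
#'
#' For each cell, the maternal fragment ratio among SNP-informative
#' (maternal- or paternal-labeled) chrX fragments. In crosses the ratio is
#' bimodal near 0 and 1: a ratio at or below `lower` means the maternal X
#' is inactive (XM_INACTIVE), at or above `upper` the paternal X
#' (XP_INACTIVE). Cells between the thresholds, or with fewer than
#' `min_informative` informative fragments, are UNASSIGNED.
#'
#' @param fragments an allele-labeled fragment table (any chromosomes;
#'   only `x_chrom` is used).
#' @param lower,upper ratio thresholds (defaults 0.2 / 0.8).
#' @param min_informative minimum informative chrX fragments (default 10).
#' @param x_chrom name of the X chromosome contig.
#' @return data.table: cell_id, n_informative_x_fragments, maternal_ratio,
#'   state.
#' @export
xci_assign <- function(fragments, lower = 0.2, upper = 0.8,
                       min_informative = 10L, x_chrom = "chrX") {
  f <- data.table::as.data.table(fragments)
  cells <- sort(unique(f$cell_id))
  fx <- f[f$chrom == x_chrom & f$allele %in% c("M", "P")]
  tab <- fx[, list(n_informative_x_fragments = .N,
                   maternal_ratio = mean(allele == "M")), by = "cell_id"]
  out <- data.table::data.table(cell_id = cells)
  out <- merge(out, tab, by = "cell_id", all.x = TRUE)
  out[is.na(n_informative_x_fragments),
      "n_informative_x_fragments" := 0L]
  out[, "state" := "UNASSIGNED"]
  ok <- out$n_informative_x_fragments >= min_informative
  out[ok & maternal_ratio <= lower, "state" := "XM_INACTIVE"]
  out[ok & maternal_ratio >= upper, "state" := "XP_INACTIVE"]
  out[]
}

#' Pool chrX fragments into active / inactive haplotypes
#'
#' Using per-cell XCI assignments, maternal and paternal chrX fragments
#' are routed to the active-X (Xa) and inactive-X (Xi) pools: in an
#' XP_INACTIVE cell the maternal X is active, so maternal fragments join
#' Xa and paternal fragments join Xi; mirrored for XM_INACTIVE cells.
#' UNASSIGNED cells and non-informative fragments are excluded.
#'
#' @param fragments an allele-labeled fragment table.
#' @param assignments output of [xci_assign()].
#' @param x_chrom name of the X chromosome contig.
#' @return list with fragment tables `Xa` and `Xi`.
#' @export
haplotype_aggregate_x <- function(fragments, assignments,
                                  x_chrom = "chrX") {
  f <- data.table::as.data.table(fragments)
  a <- data.table::as.data.table(assignments)
  f <- f[f$chrom == x_chrom & f$allele %in% c("M", "P")]
  f[, ".state" := a$state[match(cell_id, a$cell_id)]]
  f <- f[.state %in% c("XM_INACTIVE", "XP_INACTIVE")]
  active_is_m <- f$.state == "XP_INACTIVE"
  xa <- f[(active_is_m & f$allele == "M") | (!active_is_m & f$allele == "P")]
  xi <- f[(active_is_m & f$allele == "P") | (!active_is_m & f$allele == "M")]
  xa[, ".state" := NULL]
  xi[, ".state" := NULL]
  empty <- fragment_table(data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    cell_id = character(0)))
  list(Xa = if (nrow(xa)) fragment_table(xa) else empty,
       Xi = if (nrow(xi)) fragment_table(xi) else empty)
}
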