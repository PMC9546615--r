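# Allele labeling, the specificity statistic S, monoallelic calling,
# promoter specificity and X-inactivation assignment.

test_that("fragment allele labels follow the genotype-consistency rules", {
  expect_equal(label_fragment_allele(character(0), character(0),
                                     character(0)), "U")
  expect_equal(label_fragment_allele(c("A", "G"), c("A", "G"),
                                     c("C", "T")), "M")
  expect_equal(label_fragment_allele("C", "A", "C"), "P")
  # observations supporting both parents are inconclusive
  expect_equal(label_fragment_allele(c("A", "C"), c("A", "G"),
                                     c("T", "C")), "I")
  # a base matching neither parent is inconclusive
  expect_equal(label_fragment_allele(c("A", "T"), c("A", "G"),
                                     c("C", "C")), "I")
  frags <- toy_fragments()
  obs <- data.frame(fragment = c(1L, 1L, 2L, 3L),
                    observed_base = c("A", "G", "C", "T"),
                    maternal_base = c("A", "G", "A", "G"),
                    paternal_base = c("C", "T", "C", "A"))
  lab <- assign_alleles(frags, obs)
  expect_equal(lab$allele, c("M", "P", "I", "U"))
})

test_that("region counts accumulate insertions or fragments from labeled alleles", {
  frags <- fragment_table(data.frame(
    chrom = "chr1", start = c(100L, 150L, 120L, 130L),
    end = c(200L, 260L, 180L, 170L), cell_id = "A",
    allele = c("M", "P", "I", "U")))
  region <- gr0("chr1", 90L, 250L)
  ins <- region_allele_counts(frags, region, "insertions")
  # maternal fragment fully inside contributes both ends; the paternal
  # fragment's right end (259) falls outside the region
  expect_equal(ins$m, 2L)
  expect_equal(ins$n, 1L)
  fr <- region_allele_counts(frags, region, "fragments")
  expect_equal(fr$m, 1L)
  expect_equal(fr$n, 1L)
  # inconclusive and unphased fragments contribute nothing
  none <- region_allele_counts(frags[frags$allele %in% c("I", "U")],
                               region)
  expect_equal(none$n + none$m, 0L)
})

test_that("S matches exact binomial tails, antisymmetry and the zero law", {
  expect_equal(allele_specificity(3, 0), log10(1 / 8), tolerance = 1e-9)
  expect_equal(allele_specificity(0, 3), -log10(1 / 8), tolerance = 1e-9)
  for (tot in c(1L, 5L, 12L, 25L)) {
    for (n in 0:tot) {
      m <- tot - n
      expect_equal(allele_specificity(n, m),
                   log10(binom_tail_sum(n, tot)) -
                     log10(binom_tail_sum(m, tot)),
                   tolerance = 1e-9,
                   label = sprintf("S(%d,%d)", n, m))
      expect_equal(allele_specificity(n, m), -allele_specificity(m, n),
                   tolerance = 1e-12)
    }
  }
  expect_identical(allele_specificity(7, 7), 0)
  expect_true(is.na(allele_specificity(0, 0)))
  # positive S means maternal-biased
  expect_true(allele_specificity(2, 20) > 0)
})

test_that("monoallelic calling applies the exact two-sided test with BH", {
  counts <- data.frame(region = 1:3, n = c(30L, 5L, 0L), m = c(2L, 5L, 40L))
  res <- call_monoallelic(counts, alpha = 0.05)
  expect_equal(res$p[1L], binom_two_sided_sum(30L, 2L), tolerance = 1e-9)
  expect_true(res$p[1L] < 1e-5)
  expect_equal(res$direction, c("PATERNAL", "NONE", "MATERNAL"))
  expect_equal(res$significant, c(TRUE, FALSE, TRUE))
  # balanced counts cap at p = 1
  expect_equal(res$p[2L], 1)
  expect_equal(nrow(call_monoallelic(counts[0, ])), 0L)
})

test_that("flagging is calibrated under the balanced null and powered under skew", {
  null <- simulate_allele_counts(2000L, c(10L, 100L), 0.5, seed = 31L)
  res0 <- call_monoallelic(null, alpha = 0.05)
  expect_lte(mean(res0$significant), 0.07)
  skew <- simulate_allele_counts(400L, c(30L, 100L), 0.9, seed = 32L)
  res1 <- call_monoallelic(skew, alpha = 0.05)
  expect_gte(mean(res1$significant & res1$direction == "MATERNAL"), 0.95)
})

test_that("promoter specificity reports per-TSS signed statistics", {
  genes <- data.frame(gene = c("g1", "g1", "g2"),
                      chrom = "chr1", tss = c(10000L, 15000L, 50000L),
                      strand = c("+", "+", "-"))
  pos <- c(rep(9500L, 20L), rep(15100L, 4L), rep(15200L, 4L))
  frags <- fragment_table(data.frame(
    chrom = "chr1", start = pos, end = pos + 100L,
    cell_id = "A", allele = c(rep("M", 20L), rep("P", 8L))))
  res <- promoter_specificity(genes, frags, promoter_window = 2000L,
                              count_mode = "fragments")
  # isoform TSSs produce separate rows
  expect_equal(nrow(res), 3L)
  expect_true(res$S[1L] > 0)       # strongly maternal promoter
  expect_true(res$S[2L] < 0)       # paternal at the second isoform
  expect_true(is.na(res$S[3L]))    # no informative counts -> missing
})

test_that("XCI assignment uses ratio thresholds and the informative minimum", {
  mk <- function(cell, n_m, n_p, chrom = "chrX") data.frame(
    chrom = chrom, start = seq_len(n_m + n_p) * 1000L,
    end = seq_len(n_m + n_p) * 1000L + 100L, cell_id = cell,
    allele = c(rep("M", n_m), rep("P", n_p)))
  f <- fragment_table(rbind(mk("xp_off", 25L, 0L), mk("xm_off", 0L, 25L),
                            mk("sparse", 5L, 0L), mk("mixed", 10L, 10L),
                            mk("autosome", 30L, 0L, chrom = "chr1")))
  res <- xci_assign(f)
  get <- function(cell) res$state[res$cell_id == cell]
  # all-maternal chrX signal means the paternal X is the silent one
  expect_equal(get("xp_off"), "XP_INACTIVE")
  expect_equal(get("xm_off"), "XM_INACTIVE")
  expect_equal(get("sparse"), "UNASSIGNED")
  expect_equal(get("mixed"), "UNASSIGNED")
  # autosomal fragments are never informative for XCI
  expect_equal(get("autosome"), "UNASSIGNED")
  expect_equal(res$n_informative_x_fragments[res$cell_id == "autosome"], 0L)
})

test_that("haplotype pooling routes alleles by each cell's inactive X", {
  f <- fragment_table(data.frame(
    chrom = "chrX", start = c(1:10, 11L, 21:30, 31L) * 1000L,
    end = c(1:10, 11L, 21:30, 31L) * 1000L + 100L,
    cell_id = rep(c("a", "b"), c(11L, 11L)),
    allele = c(rep("M", 10L), "P", rep("P", 10L), "M")))
  asg <- xci_assign(f, min_informative = 5L)
  pools <- haplotype_aggregate_x(f, asg)
  # cell a is XP_INACTIVE: 10 maternal to Xa, 1 paternal to Xi;
  # cell b mirrors with paternal active
  expect_equal(nrow(pools$Xa), 20L)
  expect_equal(nrow(pools$Xi), 2L)
  expect_equal(sort(unique(pools$Xa$allele)), c("M", "P"))
  none <- haplotype_aggregate_x(f, data.table::data.table(
    cell_id = c("a", "b"), state = "UNASSIGNED"))
  expect_equal(nrow(none$Xa) + nrow(none$Xi), 0L)
})

test_that("XCI calls are exact on strongly skewed synthetic cells", {
  cfg <- sim_config(n_cells = 150L, n_peaks = 20L,
                    background_per_cell = 0L, mito_per_cell = 0L,
                    baseline_prob = 0.05, duplication_rate = 0,
                    contamination_rate = 0,
                    x_frags_per_cell = 30L, x_informative_frac = 1,
                    xci_skew = 0.98)
  sim <- simulate_fragments(cfg, seed = 17L)
  res <- xci_assign(sim$fragments)
  truth <- sim$truth$xci
  m <- merge(res, truth, by = "cell_id")
  eligible <- m$n_informative_x_fragments >= 20L
  assigned <- m$state != "UNASSIGNED"
  expected <- ifelse(m$inactive_parent == "XM", "XM_INACTIVE",
                     "XP_INACTIVE")
  # every assigned call is correct; no wrong-direction assignments at all
  expect_equal(mean(m$state[assigned & eligible] ==
                      expected[assigned & eligible]), 1)
  expect_equal(sum(assigned & m$state != expected), 0L)
})
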