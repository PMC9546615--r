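# Demultiplexing, adapter trimming, fragment construction, deduplication
# and decontamination.

test_that("whitelist matching assigns unique in-range hits and rejects ties", {
  cands <- c(a = "ACGTAC", b = "TTTTTT", c = "ACGTTT")
  expect_equal(match_with_mismatch("ACGTAC", cands, 1L), "a")
  expect_equal(match_with_mismatch("ACGTAG", cands, 1L), "a")
  # distance 2 from everything at tolerance 1 -> unassigned
  expect_true(is.na(match_with_mismatch("ACGGGC", cands, 1L)))
  # equidistant from a and c (1 mismatch each) -> ambiguity, unassigned
  expect_true(is.na(match_with_mismatch("ACGTTC", cands, 1L)))
  # but resolvable when one candidate is strictly closer
  expect_equal(match_with_mismatch("ACGTTT", cands, 1L), "c")
  expect_error(match_with_mismatch("ACGT", cands, 1L), "length")
  expect_equal(match_with_mismatch(character(0), cands, 1L), character(0))
})

test_that("read-structure parsing assigns cells and META tags with tolerance", {
  sch <- example_scheme(12L, seed = 3L)
  p1 <- sch$pairs[7L, ]
  bc1 <- sch$r1_barcodes[[p1$r1_bc]]
  bc2 <- sch$r2_barcodes[[p1$r2_bc]]
  flip <- function(s, i) {
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, i, i))[1L]
    s
  }
  reads <- data.table::data.table(
    read_id = c("exact", "bc_err", "meta_err", "r2_bad", "short"),
    r1_seq = c(
      paste0(bc1, sch$meta_tags[["m03"]], "ACGTACGT"),
      paste0(flip(bc1, 2L), sch$meta_tags[["m03"]], "ACGTACGT"),
      paste0(bc1, flip(flip(sch$meta_tags[["m03"]], 1L), 5L), "ACGTACGT"),
      paste0(bc1, sch$meta_tags[["m03"]], "ACGTACGT"),
      "ACGT"),
    r2_seq = c(
      paste0(bc2, sch$meta_tags[["m09"]], "ACGTACGT"),
      paste0(bc2, sch$meta_tags[["m09"]], "ACGTACGT"),
      paste0(bc2, sch$meta_tags[["m09"]], "ACGTACGT"),
      paste0("NNNNNN", sch$meta_tags[["m09"]], "ACGTACGT"),
      paste0(bc2, sch$meta_tags[["m09"]], "ACGTACGT")))
  tg <- parse_read_structure(reads, sch)
  expect_equal(tg$cell_id[1:3], rep(p1$cell_id, 3L))
  expect_equal(tg$r1_meta[1:3], rep("m03", 3L))
  expect_equal(tg$r2_meta[1L], "m09")
  expect_equal(tg$r1_insert[1L], "ACGTACGT")
  expect_true(is.na(tg$cell_id[4L]))
  expect_equal(tg$reason[4L], "BARCODE_UNASSIGNED")
  expect_equal(tg$reason[5L], "TOO_SHORT")
})

test_that("mosaic-end trimming removes read-through and leaves clean reads", {
  me <- TN5_MOSAIC_END
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(me, "")[[1L]]), collapse = ""))
  insert <- "TTAACCGGTTAACCGGTTAACCGG"
  # full 19-nt 3' adapter read-through
  tr <- trim_mosaic_end(paste0(insert, rc))
  expect_equal(tr$sequence, insert)
  # no adapter-like content -> unchanged
  expect_equal(trim_mosaic_end(insert)$sequence, insert)
  # 4 mismatches in 19 (error rate 0.21 <= 0.22) still trimmed
  rc4 <- rc
  for (i in c(3L, 7L, 11L, 15L))
    substr(rc4, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(rc4, i, i))[1L]
  expect_equal(trim_mosaic_end(paste0(insert, rc4))$sequence, insert)
  # 5 mismatches exceeds the error budget -> untouched
  rc5 <- rc4
  substr(rc5, 18L, 18L) <- setdiff(c("A", "C", "G", "T"),
                                   substr(rc5, 18L, 18L))[1L]
  expect_equal(trim_mosaic_end(paste0(insert, rc5))$sequence,
               paste0(insert, rc5))
  # partial 3'-terminal match (>= 3 nt) and 5' adapter, with qualities
  partial <- substr(rc, 1L, 5L)
  tr2 <- trim_mosaic_end(paste0(me, insert, partial),
                         quality = strrep("I", 19L + 24L + 5L))
  expect_equal(tr2$sequence, insert)
  expect_equal(nchar(tr2$quality), nchar(insert))
})

test_that("Tn5 centering applies +4/-5 and discards bad pairs", {
  pairs <- data.frame(
    chrom = "chr1", r1_strand = c("+", "+", "+", "-"),
    r1_start = c(100L, 100L, 100L, 160L), r1_end = c(150L, 150L, 150L, 200L),
    r2_start = c(150L, 150L, 104L, 100L), r2_end = c(200L, 200L, 108L, 140L),
    mapq = c(60L, 29L, 60L, 60L), is_proper = TRUE,
    cell_id = "A", r1_meta = "m01", r2_meta = "m02")
  fr <- pairs_to_fragments(pairs)
  # mapq 29 dropped; corrected [104,103) dropped; minus-strand R1 uses R2 start
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$start, c(104L, 104L))
  expect_equal(fr$end, c(195L, 195L))
  improper <- pairs[1L, ]
  improper$is_proper <- FALSE
  expect_equal(nrow(pairs_to_fragments(improper)), 0L)
})

test_that("deduplication collapses identical keys, keeps distinct META pairs", {
  f <- data.frame(
    chrom = "chr1", start = 100L, end = 200L, cell_id = "A",
    r1_meta = c("m01", "m01", "m01", "m02"),
    r2_meta = c("m05", "m05", "m05", "m05"))
  dd <- deduplicate(f)
  expect_equal(nrow(dd), 2L)
  expect_equal(sort(dd$read_count), c(1L, 3L))
  # total read support conserved, and dedup is idempotent
  expect_equal(sum(dd$read_count), 4L)
  expect_identical(deduplicate(dd), dd)
  expect_equal(nrow(deduplicate(toy_fragments()[0L])), 0L)
})

test_that("decontamination keeps the highest-frequency cell and drops ties", {
  base <- data.frame(chrom = "chr1", start = 100L, end = 200L,
                     r1_meta = "m01", r2_meta = "m05")
  f <- rbind(
    cbind(base, cell_id = "A", read_count = 5L),
    cbind(base, cell_id = "B", read_count = 2L),
    data.frame(chrom = "chr1", start = 500L, end = 600L, r1_meta = "m02",
               r2_meta = "m05", cell_id = "A", read_count = 3L),
    data.frame(chrom = "chr1", start = 500L, end = 600L, r1_meta = "m02",
               r2_meta = "m05", cell_id = "C", read_count = 3L),
    data.frame(chrom = "chr2", start = 10L, end = 90L, r1_meta = "m03",
               r2_meta = "m06", cell_id = "B", read_count = 1L))
  dec <- decontaminate(f)
  # shared key kept only in A; tied key removed everywhere; singleton kept
  expect_equal(nrow(dec$fragments), 2L)
  expect_setequal(dec$fragments$cell_id, c("A", "B"))
  expect_false(any(dec$fragments$start == 500L))
  st <- dec$cell_stats[order(cell_id)]
  expect_equal(st$contamination_rate, c(1 / 2, 1 / 2, 1))
  # idempotent, and each surviving key lives in exactly one cell
  again <- decontaminate(dec$fragments)
  expect_identical(again$fragments, dec$fragments)
  key <- paste(dec$fragments$chrom, dec$fragments$start,
               dec$fragments$end, dec$fragments$r1_meta,
               dec$fragments$r2_meta)
  expect_false(anyDuplicated(key) > 0L)
})

test_that("reads with at most one barcode error are never assigned to a wrong cell", {
  sch <- example_scheme(25L, seed = 11L)
  cfg <- sim_config(n_cells = 25L, n_peaks = 30L, background_per_cell = 10L,
                    x_frags_per_cell = 5L, duplication_rate = 0,
                    contamination_rate = 0, barcode_error_rate = 0)
  sim <- simulate_fragments(cfg, seed = 5L)
  rd <- simulate_reads(sim$fragments, sch, cfg, seed = 5L)
  # inject exactly one substitution into every r1 barcode
  r1 <- rd$reads$r1_seq
  flip_at <- rep(c(1L, 3L, 6L), length.out = length(r1))
  for (i in seq_along(r1)) {
    p <- flip_at[i]
    substr(r1[i], p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r1[i], p, p))[1L]
  }
  rd$reads$r1_seq <- r1
  tg <- parse_read_structure(rd$reads, sch)
  m <- merge(tg, rd$truth, by = "read_id")
  assigned <- !is.na(m$cell_id.x)
  expect_gte(mean(assigned & m$cell_id.x == m$cell_id.y), 0.99)
  expect_equal(sum(assigned & m$cell_id.x != m$cell_id.y), 0L)
})
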