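# Hypergeometric coaccessibility scoring and its downstream summaries.

test_that("score matches the exhaustive-enumeration tail on small N", {
  expect_equal(coaccess_score(4, 2, 2, 2), -log10(1 / 6), tolerance = 1e-9)
  expect_equal(coaccess_score(6, 3, 3, 3), -log10(1 / 20), tolerance = 1e-9)
  for (N in c(3L, 5L, 7L)) {
    for (n in 0:N) {
      for (M in 0:N) {
        for (x in max(0L, M + n - N):min(M, n)) {
          expect_equal(coaccess_score(N, M, n, x),
                       -log10(hyper_tail_enum(N, M, n, x)),
                       tolerance = 1e-9,
                       label = sprintf("N=%d M=%d n=%d x=%d", N, M, n, x))
        }
      }
    }
  }
})

test_that("score obeys symmetry, monotonicity and degenerate-marginal laws", {
  withr::with_seed(7L, {
    N <- sample(2:400, 2000L, replace = TRUE)
    M <- vapply(N, function(k) sample(0:k, 1L), integer(1))
    n <- vapply(N, function(k) sample(0:k, 1L), integer(1))
    lo <- pmax(0L, M + n - N)
    hi <- pmin(M, n)
    x <- lo + floor(stats::runif(2000L) * (hi - lo + 1L))
  })
  s <- coaccess_score(N, M, n, x)
  expect_true(all(s >= 0))
  # marginal exchange
  expect_equal(s, coaccess_score(N, n, M, x), tolerance = 1e-12)
  # nondecreasing in x
  up <- which(x < hi)
  expect_true(all(coaccess_score(N[up], M[up], n[up], x[up] + 1L) >=
                    s[up] - 1e-12))
  # score 0 at the lower feasible bound and when a peak is ubiquitous
  expect_equal(coaccess_score(N, M, n, lo), rep(0, length(N)))
  expect_equal(coaccess_score(N, N, n, n), rep(0, length(N)))
  expect_error(coaccess_score(10, 4, 4, 5), "feasible")
  expect_error(coaccess_score(10, 12, 4, 2), "marginals")
})

test_that("binarization marks >=1 bp overlaps and keeps empty cells in N", {
  frags <- fragment_table(data.frame(
    chrom = "chr1", start = c(100L, 120L, 140L, 480L),
    end = c(110L, 130L, 150L, 520L),
    cell_id = c("A", "A", "A", "B")))
  peaks <- gr0("chr1", c(90L, 500L), c(200L, 700L))
  am <- binarize(frags, peaks, cells = c("A", "B", "C"))
  expect_equal(am$N, 3L)
  # three fragments in one peak still give a single binary entry
  expect_equal(as.vector(am$mat["A", ]), c(TRUE, FALSE))
  # fragment spanning both peaks lights up both
  expect_equal(as.vector(am$mat["B", ]), c(FALSE, TRUE))
  expect_equal(unname(am$marginals), c(1, 1))
  expect_equal(as.vector(am$mat["C", ]), c(FALSE, FALSE))
  expect_error(binarize(frags, GenomicRanges::GRanges()), "empty")
})

test_that("pair scoring computes intersections in input order", {
  mat <- Matrix::Matrix(rbind(c(TRUE, TRUE, FALSE, TRUE),
                              c(TRUE, TRUE, FALSE, FALSE),
                              c(FALSE, FALSE, TRUE, TRUE),
                              c(TRUE, TRUE, FALSE, FALSE),
                              c(FALSE, FALSE, TRUE, FALSE)), sparse = TRUE)
  rownames(mat) <- paste0("c", 1:5)
  peaks <- gr0(c("chr1", "chr1", "chr1", "chr2"),
               c(0L, 1000L, 2000L, 0L), c(501L, 1501L, 2501L, 501L))
  am <- accessibility_matrix(mat, peaks)
  res <- score_pairs(am, data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 4L)))
  expect_equal(res$x, c(3L, 0L, 1L))
  expect_equal(res$M, c(3, 3, 3))
  expect_equal(res$n, c(3, 2, 2))
  # identical accessible-cell sets reach the maximal score for the marginals
  expect_equal(res$score[1L], coaccess_score(5, 3, 3, 3))
  # disjoint sets sit at the lower feasible bound
  expect_equal(res$score[2L], 0)
  # interchromosomal pairs are scored like any others, with NA distance
  expect_true(is.na(res$distance[3L]))
  expect_equal(res$score[3L],
               coaccess_score(5, 3, 2, 1))
})

test_that("neighbor pairs respect chromosome and the closed distance bound", {
  peaks <- gr0(c("chr1", "chr1", "chr1", "chr2"),
               c(0L, 400L, 5000L, 0L), c(100L, 500L, 5100L, 100L))
  np <- neighbor_pairs(peaks, 400)
  # centers at 50, 450, 5050 (chr1) and 50 (chr2); 450-50 = 400 included
  expect_equal(nrow(np), 1L)
  expect_equal(np$i, 1L)
  expect_equal(np$j, 2L)
  expect_equal(np$distance, 400)
  expect_equal(nrow(neighbor_pairs(peaks, 10)), 0L)
  expect_equal(nrow(neighbor_pairs(peaks, 6000)), 3L)
})

test_that("distance profile summarises scores per bin and drops empty bins", {
  res <- data.table::data.table(
    distance = c(100, 200, 900, NA),
    score = c(2, 4, 1, 100))
  prof <- distance_profile(res, c(0, 500, 1000, 2000))
  expect_equal(nrow(prof), 2L)
  expect_equal(prof$n_pairs, c(2L, 1L))
  expect_equal(prof$mean_score, c(3, 1))
  expect_equal(nrow(distance_profile(res[0L], c(0, 1))), 0L)
  expect_error(distance_profile(res, c(10, 5)), "increasing")
})

test_that("planted co-accessible modules give anchor > flank behaviour", {
  cfg <- sim_config(
    n_cells = 300L, n_peaks = 60L, baseline_prob = 0.2,
    modules = list(list(peaks = c(2L, 5L, 12L, 15L), latent_prob = 0.5,
                        activation = 0.6, leak = 0.05)))
  acc <- simulate_accessibility(cfg, seed = 21L)
  am <- acc$am
  pk <- am$peaks
  st <- GenomicRanges::start(pk) - 1L
  en <- GenomicRanges::end(pk)
  ch <- as.character(GenomicRanges::seqnames(pk))
  # loops anchored on correlated module peaks; flanks fall on baseline peaks
  loops <- data.frame(chrom = ch[c(2, 12)],
                      start1 = st[c(2, 12)], end1 = en[c(2, 12)],
                      start2 = st[c(5, 15)], end2 = en[c(5, 15)])
  gap <- st[2] - st[1]
  tab <- anchor_vs_flank(am, loops, flank_offset = gap)
  expect_equal(nrow(tab), 4L)
  expect_true(mean(tab$score[tab$group]) > mean(tab$score[!tab$group]))
  empty <- anchor_vs_flank(am, loops[0, ], flank_offset = gap)
  expect_equal(nrow(empty), 0L)
})

test_that("precision-recall handles perfect, random and singleton cases", {
  # perfect separation
  pr <- precision_recall(
    data.frame(pair_id = 1:10, score = 10:1),
    data.frame(pair_id = 1:10, label = rep(c(TRUE, FALSE), each = 5)))
  expect_equal(pr$auprc, 1)
  # single positive ranked first: precision 1 at recall 1
  pr1 <- precision_recall(
    data.frame(pair_id = 1:10, score = 10:1),
    data.frame(pair_id = 1:10, label = c(TRUE, rep(FALSE, 9))))
  expect_equal(pr1$curve$precision[pr1$curve$recall == 1][1L], 1)
  # scores independent of labels: AUPRC near prevalence (permutation null)
  withr::with_seed(3L, {
    sc <- data.frame(pair_id = 1:4000, score = stats::runif(4000))
    lb <- data.frame(pair_id = 1:4000,
                     label = sample(c(TRUE, FALSE), 4000, replace = TRUE,
                                    prob = c(0.3, 0.7)))
  })
  prn <- precision_recall(sc, lb)
  expect_equal(prn$auprc, 0.3, tolerance = 0.05)
  # missing scores default to 0; no positives is an error
  expect_error(precision_recall(sc, data.frame(pair_id = 1:10,
                                               label = FALSE)),
               "positive")
})

test_that("coaccessibility clustering recovers planted blocks", {
  m <- matrix(0.2, 10, 10)
  m[1:5, 1:5] <- 5
  m[6:10, 6:10] <- 1
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("p", 1:10)
  cl <- cluster_by_coaccessibility(m, k = 2L)
  expect_equal(length(unique(cl$group[1:5])), 1L)
  expect_equal(length(unique(cl$group[6:10])), 1L)
  expect_true(cl$group[1L] != cl$group[6L])
  # the block with the higher within-group score is the HIGH group
  expect_equal(unique(cl$label[1:5]), "HIGH")
  expect_equal(unique(cl$label[6:10]), "LOW")
  one <- cluster_by_coaccessibility(m, k = 1L)
  expect_equal(unique(one$group), 1L)
  expect_error(cluster_by_coaccessibility(m[1, , drop = FALSE]), "2 items")
})
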