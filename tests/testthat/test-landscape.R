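make_cov_track <- function(v, bin_size = 1000L, ctg = "chrA") {
  structure(list(bin_size = as.integer(bin_size),
                 seqlengths = setNames(length(v) * bin_size, ctg),
                 counts = setNames(list(as.integer(v)), ctg)),
            class = "ecc_coverage")
}

test_that("autocorrelation is one at lag zero and at an exact period", {
  set.seed(61)
  v <- rpois(1000, 8)
  ac <- scecc:::autocorr_track(make_cov_track(v), max_lag = 10000L)
  expect_equal(ac$r[ac$distance == 0], 1)
  expect_true(all(ac$r >= -1 - 1e-12 & ac$r <= 1 + 1e-12))

  periodic <- rep(c(5, 1, 2, 9), 250)
  acp <- scecc:::autocorr_track(make_cov_track(periodic), max_lag = 8000L)
  expect_equal(acp$r[acp$distance == 4000], 1)
  expect_equal(acp$r[acp$distance == 8000], 1)
})

test_that("iid Poisson coverage decorrelates beyond lag zero", {
  set.seed(62)
  v <- rpois(100000, 5)
  ac <- scecc:::autocorr_track(make_cov_track(v, bin_size = 100L),
                               max_lag = 2000L)
  expect_true(all(abs(ac$r[ac$distance > 0]) < 0.05))
})

test_that("degenerate coverage signals are rejected", {
  expect_error(scecc:::autocorr_track(make_cov_track(rep(3, 500)), 5000L),
               "zero-variance")
  expect_error(scecc:::autocorr_track(make_cov_track(c(1, 5), 1000L), 5e6),
               "too short")
})

test_that("read shuffling keeps counts and destroys clustering", {
  si <- GenomeInfoDb::Seqinfo("chrA", 2000000L)
  set.seed(63)
  # heavily clustered reads
  centers <- sample(10000:1890000, 40)
  reads <- GRanges("chrA", IRanges(
    rep(centers, each = 50) + sample(-4000:4000, 2000, replace = TRUE),
    width = 150L))
  ac <- coverage_autocorrelation(reads, si, bin_size = 1000L,
                                 max_lag = 20000L, n_shuffles = 2L,
                                 seed = 7L)
  expect_equal(ac$r[1], 1)
  expect_true("r_shuffle" %in% names(ac))
  # observed short-range correlation exceeds the shuffled baseline
  expect_gt(ac$r[2], ac$r_shuffle[2] + 0.2)
  # shuffling is deterministic under the seed
  ac2 <- coverage_autocorrelation(reads, si, bin_size = 1000L,
                                  max_lag = 20000L, n_shuffles = 2L,
                                  seed = 7L)
  expect_identical(ac, ac2)
})

test_that("GC comparison computes exact fractions and bounds", {
  genome <- Biostrings::DNAStringSet(c(
    gcC = strrep("GC", 5000),
    atC = strrep("AT", 5000)))
  cprs <- GRanges("gcC", IRanges(c(101L, 2001L), width = 500L))
  res <- gc_content_compare(cprs, genome, seed = 3L)
  expect_identical(res$gc_in, c(1, 1))
  expect_true(all(res$gc_out == 1))  # matched background on the same contig
  cprs_at <- GRanges("atC", IRanges(101L, width = 500L))
  expect_identical(gc_content_compare(cprs_at, genome)$gc_in, 0)
  bad <- GRanges("gcC", IRanges(9900L, width = 500L))
  expect_error(gc_content_compare(bad, genome), "bounds")
})

test_that("metagene profiles conserve mass and respect strand", {
  genes <- GRanges("chrA", IRanges(c(10000L, 50000L), width = 5000L),
                   strand = c("+", "-"))
  # reads only in the upstream flank of the + gene and, symmetric by
  # strand, downstream of the - gene's end coordinate
  reads <- GRanges("chrA", IRanges(c(9000L, 56000L), width = 100L))
  prof <- metagene_profile(reads, genes, body_bins = 50L,
                           flank_bp = 2000L, flank_bins = 20L)
  expect_identical(dim(prof$matrix), c(2L, 90L))
  body_cols <- which(prof$columns == "body")
  expect_true(all(prof$matrix[, body_cols] == 0))
  # both land in "upstream" after strand reversal
  up_cols <- which(prof$columns == "upstream")
  expect_identical(sum(prof$matrix[, up_cols]), 2)
  expect_identical(sum(prof$matrix), 2)

  # mass conservation against a direct window count
  set.seed(64)
  many <- GRanges("chrA", IRanges(sample.int(100000L, 300), width = 100L))
  prof2 <- metagene_profile(many, genes)
  win <- suppressWarnings(trim(genes + 2000L))
  expected <- sum(countOverlaps(scecc:::midpoints(many), win))
  expect_identical(sum(prof2$matrix), as.numeric(expected))
})

test_that("short genes are skipped with a message", {
  genes <- GRanges("chrA", IRanges(c(1000L, 5000L), width = c(30L, 5000L)),
                   strand = "+")
  expect_message(
    prof <- metagene_profile(GRanges("chrA", IRanges(6000L, 6100L)), genes),
    "skipping 1")
  expect_identical(nrow(prof$matrix), 1L)
})

test_that("feature overlap statistics follow the definitions", {
  cprs <- GRanges("chrA", IRanges(c(1000L, 20000L), width = 1000L))
  cprs$n_circle_reads <- c(30L, 10L)
  everything <- GRanges("chrA", IRanges(1L, 100000L))
  res <- feature_overlap_stats(cprs, everything)
  expect_identical(res$overlaps, c(TRUE, TRUE))
  expect_identical(res$feature_fraction, 1)
  none <- GRanges("chrA", IRanges(90000L, 95000L))
  expect_identical(feature_overlap_stats(cprs, none)$feature_fraction, 0)
  expect_error(feature_overlap_stats(cprs, GRanges()), "empty")
  # fraction is circle-read weighted
  first_only <- GRanges("chrA", IRanges(1200L, 1300L))
  expect_identical(feature_overlap_stats(cprs, first_only)$feature_fraction,
                   30 / 40)
})

test_that("co-occurrence correlation matches hand-built columns", {
  set.seed(65)
  anchor_vec <- rep(c(0, 1), 25)
  mat <- cbind(anchor = anchor_vec, same = anchor_vec,
               opposite = 1 - anchor_vec,
               matrix(rbinom(50 * 40, 1, 0.5), nrow = 50))
  catalog <- GRanges("chrA", IRanges(seq(1000, by = 5000,
                                         length.out = ncol(mat)),
                                     width = 1000L))
  res <- cooccurrence(mat, catalog, catalog[1])
  pcc <- setNames(res$pcc, colnames(mat)[res$cpr])
  expect_equal(unname(pcc["anchor"]), 1)
  expect_equal(unname(pcc["same"]), 1)
  expect_equal(unname(pcc["opposite"]), -1)
  random_pcc <- res$pcc[-(1:3)]
  expect_gte(mean(abs(random_pcc) < 0.5), 0.95)
  expect_error(
    cooccurrence(mat, catalog, GRanges("chrA", IRanges(900000L, 900100L))),
    "anchor")
})

test_that("expression correlation flags proportional genes only", {
  cells <- sprintf("c%02d", 1:10)
  set.seed(66)
  ecc <- matrix(rpois(30, 20), nrow = 10,
                dimnames = list(cells, c("g1", "g2", "g3")))
  expression <- ecc * 3
  expression[, "g2"] <- rev(expression[, "g2"])   # decouple
  expression[, "g3"] <- 7                          # constant
  res <- expression_correlation(ecc, expression)
  expect_gt(res$pcc[res$gene == "g1"], 0.9)
  expect_false("g3" %in% res$gene)
  expect_true(res$flagged[res$gene == "g1"])
  expect_error(expression_correlation(ecc[1:2, ], expression), "shared")
})

test_that("copy-number density is a ratio per 100 kb and split-stable", {
  cn <- GRanges("chrA", IRanges(1L, 1000000L))
  cn$cn <- 5L
  cell <- GRanges("chrA", IRanges(seq(1000, by = 90000,
                                      length.out = 10), width = 200L))
  res <- cn_density(list(cellA = cell), cn)
  expect_identical(unname(res$density[1, "CN5"]), 1)
  # splitting the segment into adjacent same-class pieces changes nothing
  cn_split <- GRanges("chrA", IRanges(c(1L, 400001L), c(400000L, 1000000L)))
  cn_split$cn <- 5L
  res2 <- cn_density(list(cellA = cell), cn_split)
  expect_identical(res$density, res2$density)
})

test_that("daughter distances are Euclidean on the labeled class", {
  vec <- rbind(a = c(0, 3, 4, 9), b = c(0, 0, 0, 9), c = c(0, 3, 4, 9))
  labels <- c("HFHU", "HFHU", "HFHU", "LFLU")
  res <- daughter_distance(vec, labels, "HFHU",
                           pairs = rbind(c("a", "b"), c("a", "c")))
  expect_equal(res$pair_dist, c(5, 0))
  expect_error(daughter_distance(vec, labels, "HFHU",
                                 pairs = rbind(c("a", "zz"))), "mismatch")
})

test_that("rank-sum p-values equal an exact permutation oracle", {
  xa <- c(0.31, 0.12, 0.55, 0.42)
  xb <- c(0.71, 0.68, 0.93, 0.61)
  theta <- cbind(topic1 = c(xa, xb), topic2 = runif(8, 0.2, 0.3))
  groups <- rep(c("a", "b"), each = 4)
  res <- differential_topics(theta, groups)
  expect_equal(res$p[1], oracle_ranksum_p(xa, xb))
  expect_equal(res$p[2],
               oracle_ranksum_p(theta[1:4, 2], theta[5:8, 2]))
})
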