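test_that("SAM writing and re-reading round-trips every field", {
  si <- toy_seqinfo()
  pair <- toy_pair("rt1", "chrA", 1000L, 1200L)
  pair$seq <- strrep("A", 100)
  split_primary <- alignments(
    read_id = "rt2", flag = 0L, chrom = "chrA", pos = 5000L, mapq = 60L,
    cigar = "80M20S", seq = paste0(strrep("C", 80), strrep("G", 20)),
    sa = "chrB,300,+,80S20M,60,0;")
  split_supp <- alignments(
    read_id = "rt2", flag = 2048L, chrom = "chrB", pos = 300L, mapq = 60L,
    cigar = "80S20M", seq = paste0(strrep("C", 80), strrep("G", 20)),
    sa = "chrA,5000,+,80M20S,60,0;")
  unpaired <- alignments(
    read_id = "rt3", flag = 16L, chrom = "chrB", pos = 777L, mapq = 31L,
    cigar = "100M", seq = strrep("T", 100))
  aln <- rbind(pair, split_primary, split_supp, unpaired)

  path <- tempfile(fileext = ".sam")
  write_sam(aln, path, si)
  back <- read_alignments(path, keep_seq = TRUE)

  key <- function(a) order(a$chrom, a$pos, a$flag, a$read_id)
  a1 <- aln[key(aln), , drop = FALSE]
  a2 <- back[key(back), , drop = FALSE]
  rownames(a1) <- rownames(a2) <- NULL
  for (col in c("read_id", "flag", "chrom", "pos", "mapq", "cigar",
                "mate_chrom", "mate_pos", "isize", "seq", "sa")) {
    expect_identical(a2[[col]], a1[[col]], label = paste("column", col))
  }
})

test_that("SA tag grammar parses positions, strands and CIGARs", {
  sa <- parse_sa_tag("chr1,5001,+,50S50M,60,2;chr2,10,-,50M50S,13,0;")
  expect_identical(sa$chrom, c("chr1", "chr2"))
  expect_identical(sa$pos, c(5001L, 10L))
  expect_identical(sa$pos0, c(5000L, 9L))
  expect_identical(sa$strand, c("+", "-"))
  expect_identical(sa$cigar, c("50S50M", "50M50S"))
  expect_identical(sa$mapq, c(60L, 13L))
  expect_identical(sa$nm, c(2L, 0L))
  expect_identical(nrow(parse_sa_tag(NA_character_)), 0L)
})

test_that("duplicate pairs collapse to the best-quality pair", {
  dup <- do.call(rbind, lapply(1:5, function(i) {
    toy_pair(sprintf("dup%d", i), "chrA", 1000L, 1300L,
             mapq = c(60L, 50L, 40L, 60L, 30L)[i])
  }))
  other <- toy_pair("solo", "chrA", 9000L, 9300L)
  out <- deduplicate(rbind(dup, other))
  expect_identical(sort(unique(out$read_id)), c("dup1", "solo"))
  expect_identical(nrow(out), 4L)
})

test_that("deduplication is idempotent and never grows the input", {
  set.seed(5)
  aln <- do.call(rbind, lapply(1:40, function(i) {
    toy_pair(sprintf("r%02d", i), "chrA",
             sample(c(1000L, 2000L, 3000L), 1), 5000L)
  }))
  once <- deduplicate(aln)
  expect_lte(nrow(once), nrow(aln))
  expect_identical(deduplicate(once), once)
})

test_that("duplicate keys are clip-aware at the unclipped 5' end", {
  # same leftmost pos but different unclipped starts: not duplicates
  a <- toy_pair("clip0", "chrA", 1000L, 1300L, cigar1 = "100M")
  b <- toy_pair("clip1", "chrA", 1000L, 1300L, cigar1 = "10S90M")
  out <- deduplicate(rbind(a, b))
  expect_identical(sort(unique(out$read_id)), c("clip0", "clip1"))
})

test_that("mapping rate counts mapped primaries over all reads", {
  aln <- rbind(toy_pair("m1", "chrA", 100L, 400L),
               toy_pair("m2", "chrA", 900L, 1200L))
  expect_identical(mapping_rate(aln), 1)
  expect_identical(mapping_rate(aln, n_total_reads = 5L), 4 / 5)
  expect_error(mapping_rate(aln[0, ]), "zero")
  expect_error(mapping_rate(aln, n_total_reads = 2L), "smaller")
})

test_that("chimeric extraction separates split and discordant reads", {
  concordant <- toy_pair("ok", "chrA", 1000L, 1200L)
  inter <- toy_pair("inter", "chrA", 1000L, 500L, chrom2 = "chrB",
                    flags = c(1L + 32L + 64L, 1L + 16L + 128L))
  split_lo <- alignments(read_id = "weak", flag = 0L, chrom = "chrA",
                         pos = 2000L, mapq = 15L, cigar = "80M20S",
                         sa = "chrA,9000,+,80S20M,15,0;")
  split_hi <- alignments(read_id = "strong", flag = 0L, chrom = "chrA",
                         pos = 3000L, mapq = 60L, cigar = "80M20S",
                         sa = "chrA,9000,+,80S20M,60,0;")
  aln <- rbind(concordant, inter, split_lo, split_hi)
  chim <- extract_chimeric(aln)
  expect_identical(chim$split$read_id, "strong")
  expect_identical(sort(unique(chim$discordant$read_id)), "inter")
  expect_false("ok" %in% chim$discordant$read_id)
})

test_that("everted and long-insert pairs are discordant", {
  # everted: leftmost read is reverse (short span, so not long-insert)
  everted <- toy_pair("ev", "chrA", 1000L, 1600L,
                      flags = c(1L + 16L + 64L, 1L + 32L + 128L))
  long <- toy_pair("long", "chrA", 1000L, 9000L)
  chim <- extract_chimeric(rbind(everted, long))
  expect_setequal(unique(chim$discordant$read_id), c("ev", "long"))
})

test_that("R2R1 artifact pairs are removed by default only", {
  # tandem (FF) pair with read 2 starting upstream of read 1
  r2r1 <- toy_pair("art", "chrA", 5000L, 1000L,
                   flags = c(1L + 64L, 1L + 128L))
  with_drop <- extract_chimeric(r2r1)
  without_drop <- extract_chimeric(r2r1, drop_r2r1 = FALSE)
  expect_identical(nrow(with_drop$discordant), 0L)
  expect_identical(sort(unique(without_drop$discordant$read_id)), "art")
})

test_that("lowering the mapq cutoff never shrinks the chimeric sets", {
  set.seed(9)
  parts <- lapply(1:30, function(i) {
    mq <- sample(0:60, 1)
    if (i %% 2 == 0) {
      alignments(read_id = sprintf("s%02d", i), flag = 0L, chrom = "chrA",
                 pos = 1000L * i, mapq = mq, cigar = "80M20S",
                 sa = "chrB,500,+,80S20M,60,0;")
    } else {
      toy_pair(sprintf("d%02d", i), "chrA", 1000L * i, 500L,
               chrom2 = "chrB", mapq = mq,
               flags = c(1L + 32L + 64L, 1L + 16L + 128L))
    }
  })
  aln <- do.call(rbind, parts)
  strict <- extract_chimeric(aln, min_mapq = 30L)
  loose <- extract_chimeric(aln, min_mapq = 10L)
  expect_true(all(strict$split$read_id %in% loose$split$read_id))
  expect_true(all(strict$discordant$read_id %in% loose$discordant$read_id))
  expect_gte(nrow(loose$split), nrow(strict$split))
  expect_gte(nrow(loose$discordant), nrow(strict$discordant))
})

test_that("binned coverage equals a per-base brute-force recount", {
  si <- toy_seqinfo()
  # read fully inside one bin
  one <- toy_pair("c1", "chrA", 150L, 450L)
  cov1 <- compute_coverage(one, si, bin_size = 1000L)
  expect_identical(cov1$counts$chrA[1], 2L)
  expect_true(all(cov1$counts$chrA[-1] == 0L))
  # read spanning a bin boundary increments both bins
  spanning <- alignments(read_id = "c2", flag = 0L, chrom = "chrA",
                         pos = 950L, mapq = 60L, cigar = "100M")
  cov2 <- compute_coverage(spanning, si, bin_size = 1000L)
  expect_identical(cov2$counts$chrA[1:2], c(1L, 1L))

  set.seed(21)
  n <- 100L
  chrom <- sample(c("chrA", "chrB"), n, replace = TRUE)
  pos <- ifelse(chrom == "chrA", sample.int(599000L, n),
                sample.int(399000L, n))
  aln <- alignments(read_id = sprintf("r%03d", 1:n), flag = 0L,
                    chrom = chrom, pos = pos, mapq = 60L, cigar = "150M")
  cov <- compute_coverage(aln, si, bin_size = 100L)
  oracle <- oracle_coverage(chrom, pos, rep(150L, n),
                            c(chrA = 600000L, chrB = 400000L), 100L)
  expect_identical(cov$counts$chrA, oracle$chrA)
  expect_identical(cov$counts$chrB, oracle$chrB)
})

test_that("secondary and duplicate records never count in coverage", {
  si <- toy_seqinfo()
  aln <- rbind(
    alignments("p", 0L, "chrA", 100L, 60L, "100M"),
    alignments("p", 256L, "chrA", 5000L, 0L, "100M"),
    alignments("q", 1024L, "chrA", 9000L, 60L, "100M"))
  cov <- compute_coverage(aln, si, bin_size = 1000L)
  expect_identical(sum(cov$counts$chrA), 1L)
})
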