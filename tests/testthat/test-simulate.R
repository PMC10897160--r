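tiny_design <- function(...) {
  sim_design(n_cells = 1L, chrom_sizes = c(chrA = 60000L),
             singletons_per_cell = 3L, ...)
}

test_that("the genome is deterministic and hits the designed GC", {
  d <- sim_design(chrom_sizes = c(chrA = 100000L))
  g1 <- make_genome(d, seed = 3L)
  g2 <- make_genome(d, seed = 3L)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- make_genome(d, seed = 4L)
  expect_false(identical(as.character(g1), as.character(g3)))
  gc <- sum(Biostrings::letterFrequency(g1["chrA"], c("G", "C"))) / 100000
  expect_lt(abs(gc - 0.5), 0.01)
  d7 <- sim_design(chrom_sizes = c(chrA = 100000L), gc = 0.7)
  gc7 <- sum(Biostrings::letterFrequency(
    make_genome(d7, 3L)["chrA"], c("G", "C"))) / 100000
  expect_lt(abs(gc7 - 0.7), 0.01)
  expect_identical(sort(names(g1)),
                   sort(c("chrA", "chrMsim", "spikeC", "spikeL")))
})

test_that("planted circles stay in bounds and never overlap within a cell", {
  d <- sim_design(n_cells = 4L, singletons_per_cell = 30L)
  truth <- plant_circles(d, seed = 21L)
  expect_identical(length(truth), 4L * 30L)
  segs <- do.call(rbind, lapply(truth, `[[`, "segments"))
  expect_true(all(segs$start >= 1))
  expect_true(all(segs$end <= d$chrom_sizes[segs$chrom]))
  expect_true(all(segs$end > segs$start))
  for (cell in unique(vapply(truth, `[[`, "", "cell"))) {
    cs <- do.call(rbind, lapply(Filter(function(x) x$cell == cell, truth),
                                `[[`, "segments"))
    ir <- split(IRanges(cs$start, cs$end), cs$chrom)
    red <- vapply(ir, function(x) sum(width(IRanges::reduce(x))),
                  numeric(1))
    expect_identical(sum(red), sum(cs$end - cs$start + 1))
  }
  expect_identical(plant_circles(d, seed = 21L), truth)
})

test_that("the recurrent circle is carried by the designed cell fraction", {
  d <- sim_design(n_cells = 20L, singletons_per_cell = 0L,
                  recurrent_fraction = 0.9)
  truth <- plant_circles(d, seed = 22L)
  rec <- Filter(function(x) x$kind == "recurrent", truth)
  expect_identical(length(rec), 18L)
  segs <- unique(do.call(rbind, lapply(rec, `[[`, "segments")))
  expect_identical(nrow(segs), 1L)  # identical borders without jitter
  dj <- sim_design(n_cells = 20L, singletons_per_cell = 0L,
                   recurrent_fraction = 0.9, recurrent_jitter = 0.4)
  segj <- do.call(rbind, lapply(
    Filter(function(x) x$kind == "recurrent", plant_circles(dj, 22L)),
    `[[`, "segments"))
  expect_gt(nrow(unique(segj)), 1L)
})

test_that("circle-coordinate decomposition wraps across the closure", {
  segs <- data.frame(chrom = "chrA", start = 100L, end = 199L,
                     strand = "+")
  b <- scecc:::circle_blocks(90L, 20L, segs)
  expect_identical(b$gstart, c(190L, 100L))
  expect_identical(b$len, c(10L, 10L))
  two <- data.frame(chrom = c("chrA", "chrB"), start = c(1L, 501L),
                    end = c(50L, 550L), strand = "+")
  b2 <- scecc:::circle_blocks(95L, 10L, two)
  expect_identical(b2$chrom, c("chrB", "chrA"))
  expect_identical(b2$gstart, c(546L, 1L))
  expect_identical(b2$len, c(5L, 5L))
  expect_identical(scecc:::circle_substr("ABCDEFGH", 6L, 4L), "GHAB")
})

test_that("read sequences are faithful to the reference", {
  pop <- small_population()
  aln <- pop$sim$alignments$cell001
  genome <- pop$sim$genome
  set.seed(23)
  idx <- sample(which(!is.na(aln$seq) & aln$mapq == 60L), 200L)
  for (i in idx) {
    cig <- aln$cigar[i]
    m <- as.integer(sub("^.*?(\\d+)M.*$", "\\1", cig))
    left <- if (grepl("^\\d+S", cig)) {
      as.integer(sub("^(\\d+)S.*$", "\\1", cig))
    } else 0L
    ref <- as.character(Biostrings::subseq(
      genome[[aln$chrom[i]]], aln$pos[i], aln$pos[i] + m - 1L))
    # SEQ is stored in reference orientation, so the matched block sits
    # right after the left soft clip for both strands
    expect_identical(substr(aln$seq[i], left + 1L, left + m), ref)
  }
})

test_that("circle reads live on the doubled circular template", {
  pop <- small_population()
  aln <- pop$sim$alignments$cell001
  circ <- pop$sim$truth[[1]]
  expect_identical(circ$cell, "cell001")
  seqstr <- scecc:::circle_sequence(circ$segments, pop$sim$genome)
  doubled <- paste0(seqstr, seqstr)
  mine <- aln[grepl(paste0("^", circ$circle_id, "_p"), aln$read_id) &
                !is.na(aln$seq), , drop = FALSE]
  primaries <- mine[bitwAnd(mine$flag, 2048L) == 0L, , drop = FALSE]
  expect_gt(nrow(primaries), 0L)
  for (i in seq_len(nrow(primaries))) {
    expect_true(grepl(primaries$seq[i], doubled, fixed = TRUE))
  }
})

test_that("per-circle amplification multipliers are attached and positive", {
  pop <- small_population()
  dm <- attr(pop$sim$alignments, "depth_mult")
  ids <- vapply(pop$sim$truth, `[[`, "", "circle_id")
  expect_setequal(names(dm), ids)
  expect_true(all(dm > 0))
})

test_that("disabling the background removes all background reads", {
  d <- tiny_design(background_depth = 0)
  genome <- make_genome(d, seed = 24L)
  truth <- plant_circles(d, seed = 25L)
  alns <- generate_alignments(truth, genome, d, seed = 26L)
  expect_false(any(grepl("_bg_", alns$cell001$read_id)))
  d2 <- tiny_design()
  alns2 <- generate_alignments(plant_circles(d2, 25L),
                               make_genome(d2, 24L), d2, seed = 26L)
  expect_true(any(grepl("_bg_", alns2$cell001$read_id)))
})

test_that("a population written twice is byte-identical", {
  d <- tiny_design()
  dir1 <- file.path(tempdir(), "scecc-sim-rep1")
  dir2 <- file.path(tempdir(), "scecc-sim-rep2")
  unlink(c(dir1, dir2), recursive = TRUE)
  sim1 <- simulate_population(d, seed = 31L, out_dir = dir1)
  sim2 <- simulate_population(d, seed = 31L, out_dir = dir2)
  m1 <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                            simplifyVector = TRUE)
  m2 <- jsonlite::read_json(file.path(dir2, "manifest.json"),
                            simplifyVector = TRUE)
  expect_identical(m1$file, m2$file)
  expect_identical(m1$md5, m2$md5)
  expect_true(all(file.exists(
    file.path(dir1, c("genome.fa", "genome.fa.fai", "cell001.sam",
                      "truth.json", "design.json", "manifest.json")))))
  # refusing to clobber an existing population
  expect_error(simulate_population(d, seed = 31L, out_dir = dir1),
               "not empty")
  # the on-disk SAM parses back to the in-memory record count
  back <- read_alignments(file.path(dir1, "cell001.sam"))
  expect_identical(nrow(back), nrow(sim1$alignments$cell001))
  expect_identical(m1$n_records[m1$file == "cell001.sam"],
                   nrow(sim1$alignments$cell001))
  # truth is serialized 0-based half-open
  tj <- jsonlite::read_json(file.path(dir1, "truth.json"),
                            simplifyVector = FALSE)
  s1 <- tj[[1]]$segments[[1]]
  expect_identical(s1$start, sim1$truth[[1]]$segments$start[1] - 1L)
  expect_identical(s1$end, sim1$truth[[1]]$segments$end[1])
})
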