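suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Seqinfo used by hand-built alignment fixtures
toy_seqinfo <- function() {
  GenomeInfoDb::Seqinfo(c("chrA", "chrB", "chrMsim", "spikeC", "spikeL"),
                        c(600000L, 400000L, 16000L, 2000L, 2000L))
}

# one proper FR pair at the given positions (both mates returned)
toy_pair <- function(id, chrom, s, e, mapq = 60L, rl = 100L,
                     cigar1 = paste0(rl, "M"), cigar2 = paste0(rl, "M"),
                     chrom2 = chrom, flags = NULL, sa1 = NA, sa2 = NA) {
  isize <- if (chrom == chrom2) e + rl - s else 0L
  f <- flags %||% c(1L + 2L + 32L + 64L, 1L + 2L + 16L + 128L)
  scecc::alignments(
    read_id = c(id, id), flag = f,
    chrom = c(chrom, chrom2), pos = c(s, e), mapq = mapq,
    cigar = c(cigar1, cigar2),
    mate_chrom = c(chrom2, chrom), mate_pos = c(e, s),
    isize = c(isize, -isize), sa = c(sa1, sa2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# memoized simulations shared across test files
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- maker()
  .sim_cache[[key]]
}

# small 3-cell population for module-level checks
small_population <- function() {
  cached_sim("small", function() {
    design <- sim_design(n_cells = 3L,
                         chrom_sizes = c(chrA = 200000L, chrB = 100000L),
                         singletons_per_cell = 8L)
    dir <- file.path(tempdir(), "scecc-sim-small")
    sim <- simulate_population(design, seed = 11L, out_dir = dir,
                               force = TRUE)
    list(design = design, sim = sim, dir = dir,
         params = design_cpr_params(design))
  })
}

# the default-design study population (20 cells, 1 Mb, 50 circles/cell)
default_population <- function() {
  cached_sim("default", function() {
    design <- sim_design()
    dir <- file.path(tempdir(), "scecc-sim-default")
    sim <- simulate_population(design, seed = 101L, out_dir = dir,
                               force = TRUE)
    params <- design_cpr_params(design)
    profiles <- lapply(names(sim$alignments), function(cell) {
      scecc:::profile_from_alignments(
        deduplicate(sim$alignments[[cell]]), sim$seqinfo, params,
        spike_contigs = c("spikeC", "spikeL"), cell_id = cell)
    })
    names(profiles) <- names(sim$alignments)
    list(design = design, sim = sim, params = params, profiles = profiles)
  })
}

# truth circles of one cell as GRanges (single-segment circles only)
truth_granges <- function(truth, cell) {
  circ <- Filter(function(x) x$cell == cell, truth)
  segs <- do.call(rbind, lapply(circ, `[[`, "segments"))
  gr <- if (is.null(segs)) GRanges() else
    GRanges(segs$chrom, IRanges(segs$start, segs$end))
  list(circles = circ, gr = gr)
}

# random toy population in plain interval form, for oracle comparison
random_toy <- function(mito_len = 1000L) {
  glen <- 2000L
  riv <- function() {
    s <- sample.int(glen - 100L, 1)
    c(s, min(glen, s + sample.int(300L, 1) + 19L))
  }
  n_cells <- sample(1:10, 1)
  cells <- lapply(seq_len(n_cells), function(i) {
    lapply(seq_len(sample(0:3, 1)), function(k) riv())
  })
  mito_cells <- lapply(seq_len(n_cells), function(i) {
    s <- sample.int(mito_len %/% 2L, 1)
    list(c(s, s + sample(seq(mito_len %/% 4L, mito_len %/% 2L), 1)))
  })
  list(pseudo = riv(), cells = cells, mito_cells = mito_cells,
       n_cells = n_cells, mito_len = mito_len)
}

toy_to_granges <- function(ivs, chrom) {
  if (length(ivs) == 0) return(GRanges())
  m <- do.call(rbind, ivs)
  GRanges(chrom, IRanges(m[, 1], m[, 2]))
}

run_toy <- function(toy) {
  si <- GenomeInfoDb::Seqinfo(c("chrT", "chrM"),
                              c(2000L, toy$mito_len))
  pseudo <- GRanges("chrT", IRanges(toy$pseudo[1], toy$pseudo[2]))
  pseudo$cpr_id <- "CPR_toy"
  classify_population(
    pseudo,
    cell_cprs = lapply(toy$cells, toy_to_granges, chrom = "chrT"),
    cell_mito = lapply(toy$mito_cells, toy_to_granges, chrom = "chrM"),
    mito_contig = "chrM", seqinfo = si)
}
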