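## Alignment-level simulator of circular-DNA sequencing data.
##
## Reads are drawn directly from the circular template (positions
## uniform modulo the circle length) and written as SAM records with
## exact CIGARs, SA descriptors, mate fields and flags - no aligner is
## involved, which keeps the test bed deterministic. A read whose
## fragment spans the circle closure point comes out as a soft-clipped
## primary plus a supplementary record (a split read); a pair straddling
## it comes out everted. The mitochondrial surrogate and the circular
## spike-in contig are covered as circles, the linear spike-in and the
## nuclear background as linear fragments.

#' Simulation design
#'
#' Defaults describe the desk-scale study population used throughout the
#' test suite: 20 cells over a 1-Mb nuclear genome, 50 singleton circles
#' per cell at 30x circle depth over a 0.1x linear background.
#'
#' @param n_cells number of cells.
#' @param chrom_sizes named vector of nuclear contig lengths.
#' @param mito_size,mito_contig mitochondrial surrogate contig.
#' @param spike_size lengths of the circular (`spikeC`) and linear
#'   (`spikeL`) spike-in contigs.
#' @param gc genome GC fraction.
#' @param singletons_per_cell private (cell-unique) circles per cell.
#' @param circle_len_meanlog,circle_len_sdlog,circle_len_min lognormal
#'   circle length model (bp).
#' @param recurrent_fraction fraction of cells carrying the recurrent
#'   circle (0 disables it).
#' @param recurrent_length recurrent circle length (bp).
#' @param recurrent_jitter border jitter of the recurrent circle as a
#'   fraction of its length (0 = identical borders in every carrier).
#' @param complex_per_cell multi-segment circles per cell.
#' @param complex_segments segment-count choices for complex circles.
#' @param circle_depth mean sequencing depth over a circle (x).
#' @param rca_sigma lognormal sigma of the per-circle amplification
#'   multiplier (uneven rolling-circle amplification).
#' @param background_depth linear nuclear background depth (x).
#' @param mito_depth,spike_circ_depth,spike_lin_depth auxiliary contig
#'   depths (x); the defaults give a circular spike-in read fraction of
#'   about 99.5%.
#' @param read_length,insert_mean,insert_sd paired-end read model (bp).
#' @param error_rate per-base substitution error rate.
#' @param min_clip minimum aligned length for emitting a supplementary
#'   record (shorter overhangs stay as soft clip only).
#' @return design list.
#' @export
sim_design <- function(n_cells = 20L,
                       chrom_sizes = c(chrA = 600000L, chrB = 400000L),
                       mito_size = 16000L, mito_contig = "chrMsim",
                       spike_size = c(spikeC = 2000L, spikeL = 2000L),
                       gc = 0.5,
                       singletons_per_cell = 50L,
                       circle_len_meanlog = log(3000),
                       circle_len_sdlog = 0.4,
                       circle_len_min = 600L,
                       recurrent_fraction = 0,
                       recurrent_length = 20000L,
                       recurrent_jitter = 0,
                       complex_per_cell = 0L,
                       complex_segments = 2:3,
                       circle_depth = 30,
                       rca_sigma = 0.5,
                       background_depth = 0.1,
                       mito_depth = 30,
                       spike_circ_depth = 100,
                       spike_lin_depth = 0.5,
                       read_length = 150L,
                       insert_mean = 300,
                       insert_sd = 30,
                       error_rate = 0,
                       min_clip = 20L) {
  as.list(environment())
}

# contig layout implied by a design
design_seqlengths <- function(design) {
  sl <- c(design$chrom_sizes,
          setNames(design$mito_size, design$mito_contig),
          design$spike_size)
  vapply(sl, as.integer, integer(1))
}

# contigs excluded from nuclear CPR calling
design_aux_contigs <- function(design) {
  c(design$mito_contig, names(design$spike_size))
}

#' CPR parameters matched to a simulation design
#'
#' @param design a [sim_design()] list.
#' @param ... overrides passed to [cpr_params()].
#' @return [cpr_params()] list with the design's auxiliary contigs
#'   excluded and the mitochondrial contig registered.
#' @export
design_cpr_params <- function(design, ...) {
  cpr_params(exclude_contigs = design_aux_contigs(design),
             mito_contig = design$mito_contig, ...)
}

#' Generate the synthetic genome
#'
#' Random nuclear contigs plus the mitochondrial surrogate and the
#' circular/linear spike-in contigs, with i.i.d. bases at the designed
#' GC fraction. Deterministic for a fixed seed.
#'
#' @param design [sim_design()] list.
#' @param seed integer seed.
#' @return named [Biostrings::DNAStringSet].
#' @export
make_genome <- function(design, seed = 1L) {
  sl <- design_seqlengths(design)
  stopifnot(all(design$chrom_sizes >= 10000L), all(sl >= 1000L))
  set.seed(seed)
  p <- c(A = (1 - design$gc) / 2, C = design$gc / 2,
         G = design$gc / 2, T = (1 - design$gc) / 2)
  seqs <- vapply(sl, function(len) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(sl)))
}

#' Plant circles into the simulated population
#'
#' Places singleton circles uniformly and without overlap within each
#' cell, optionally a recurrent circle at one fixed locus carried by a
#' designed fraction of cells (with optional border jitter), and
#' multi-segment (complex) circles whose segments may come from
#' different contigs.
#'
#' @param design [sim_design()] list.
#' @param seed integer seed.
#' @return list of circle-truth records; each has `circle_id`, `cell`,
#'   `class` ("simple"/"complex"), `kind` ("singleton"/"recurrent"/
#'   "complex") and `segments` (data.frame chrom/start/end/strand,
#'   1-based closed, strand "+").
#' @export
plant_circles <- function(design, seed = 1L) {
  set.seed(seed)
  sl <- design$chrom_sizes
  cells <- sprintf("cell%03d", seq_len(design$n_cells))
  truth <- list()

  rec_locus <- NULL
  carriers <- character()
  if (design$recurrent_fraction > 0) {
    ctg <- names(sl)[which.max(sl)]
    mid <- sl[[ctg]] %/% 2L
    rec_locus <- c(ctg = ctg, start = mid - design$recurrent_length %/% 2L)
    n_car <- round(design$recurrent_fraction * design$n_cells)
    carriers <- cells[seq_len(n_car)]
  }

  draw_len <- function(n) {
    pmax(design$circle_len_min,
         round(rlnorm(n, design$circle_len_meanlog, design$circle_len_sdlog)))
  }

  add_placed <- function(placed, x) if (length(placed)) c(placed, x) else x
  si <- Seqinfo(names(sl), unname(vapply(sl, as.integer, integer(1))))

  for (cell in cells) {
    placed <- GRanges(seqinfo = si)
    if (!is.null(rec_locus) && cell %in% carriers) {
      len <- design$recurrent_length
      s <- as.integer(rec_locus[["start"]])
      e <- s + len - 1L
      if (design$recurrent_jitter > 0) {
        s <- s + as.integer(round(runif(1, -1, 1) * design$recurrent_jitter * len))
        e <- e + as.integer(round(runif(1, -1, 1) * design$recurrent_jitter * len))
        s <- max(1L, s); e <- min(sl[[rec_locus[["ctg"]]]], max(e, s + 199L))
      }
      seg <- data.frame(chrom = rec_locus[["ctg"]], start = s, end = e,
                        strand = "+", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- list(
        circle_id = paste0(cell, "_recurrent"), cell = cell,
        class = "simple", kind = "recurrent", segments = seg)
      placed <- add_placed(
        placed,
        GRanges(seg$chrom, IRanges(seg$start, seg$end), seqinfo = si))
    } else if (!is.null(rec_locus)) {
      # keep the locus free in non-carriers so absence is unambiguous
      placed <- add_placed(
        placed, GRanges(rec_locus[["ctg"]],
                        IRanges(as.integer(rec_locus[["start"]]),
                                width = design$recurrent_length),
                        seqinfo = si))
    }

    place_segment <- function(len) {
      for (try in 1:200) {
        ctg <- sample(names(sl), 1, prob = as.numeric(sl))
        if (sl[[ctg]] <= len + 2L) next
        s <- sample.int(sl[[ctg]] - len, 1)
        cand <- GRanges(ctg, IRanges(s, width = len), seqinfo = si)
        # keep a gap so neighboring circles stay separable
        if (length(placed) == 0 ||
            !any(overlapsAny(cand, placed, maxgap = 2000L))) return(cand)
      }
      stop("genome too small for requested non-overlapping placement")
    }

    for (k in seq_len(design$singletons_per_cell)) {
      len <- draw_len(1)
      cand <- place_segment(len)
      placed <- add_placed(placed, cand)
      truth[[length(truth) + 1L]] <- list(
        circle_id = sprintf("%s_s%03d", cell, k), cell = cell,
        class = "simple", kind = "singleton",
        segments = data.frame(chrom = as.character(seqnames(cand)),
                              start = start(cand), end = end(cand),
                              strand = "+", stringsAsFactors = FALSE))
    }

    for (k in seq_len(design$complex_per_cell)) {
      nseg <- sample(design$complex_segments, 1)
      segs <- do.call(rbind, lapply(seq_len(nseg), function(.) {
        len <- draw_len(1)
        cand <- place_segment(len)
        placed <<- add_placed(placed, cand)
        data.frame(chrom = as.character(seqnames(cand)),
                   start = start(cand), end = end(cand),
                   strand = "+", stringsAsFactors = FALSE)
      }))
      truth[[length(truth) + 1L]] <- list(
        circle_id = sprintf("%s_c%03d", cell, k), cell = cell,
        class = "complex", kind = "complex", segments = segs)
    }
  }
  truth
}

# concatenated sequence of a circle's ordered segments
circle_sequence <- function(segments, genome) {
  pieces <- vapply(seq_len(nrow(segments)), function(i) {
    as.character(Biostrings::subseq(genome[[segments$chrom[i]]],
                                    segments$start[i], segments$end[i]))
  }, character(1))
  paste(pieces, collapse = "")
}

# decompose circle-coordinate interval [a, a+len) (0-based, wrapping)
# into genomic blocks in read order
circle_blocks <- function(a, len, segments) {
  w <- segments$end - segments$start + 1L
  cum <- cumsum(w)
  L <- cum[length(cum)]
  seg_start <- c(0L, cum[-length(cum)])
  pos <- a %% L
  remaining <- len
  blocks <- list()
  while (remaining > 0L) {
    i <- findInterval(pos, seg_start)
    take <- min(remaining, cum[i] - pos)
    blocks[[length(blocks) + 1L]] <- data.frame(
      chrom = segments$chrom[i],
      gstart = segments$start[i] + (pos - seg_start[i]),
      len = take, stringsAsFactors = FALSE)
    pos <- (pos + take) %% L
    remaining <- remaining - take
  }
  do.call(rbind, blocks)
}

# soft-clip CIGAR for a block at template offset `off` of a read of
# length rl. CIGAR (like SEQ) is written in reference orientation per
# the SAM convention, so the clip sides are the same for both strands.
block_cigar <- function(off, len, rl) {
  left <- off
  right <- rl - left - len
  paste0(if (left > 0) paste0(left, "S"),
         len, "M",
         if (right > 0) paste0(right, "S"))
}

# substring of the circle sequence with wrap-around
circle_substr <- function(seqstr, a, len) {
  L <- nchar(seqstr)
  a <- a %% L
  if (a + len <= L) return(substr(seqstr, a + 1L, a + len))
  paste0(substr(seqstr, a + 1L, L), substr(seqstr, 1L, a + len - L))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  for (i in seq_along(seqs)) {
    n <- nchar(seqs[i])
    k <- rbinom(1, n, rate)
    if (k == 0) next
    at <- sample.int(n, k)
    for (p in at) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

# paired-end reads from one circular template -> alignment data.frame.
# Vectorized over the (majority of) reads that fit inside one donor
# segment; only junction-crossing reads take the per-read block path.
reads_from_circle <- function(segments, seqstr, depth, design, prefix,
                              mapq = 60L) {
  rl <- design$read_length
  L <- nchar(seqstr)
  n_pairs <- rpois(1, L * depth / (2 * rl))
  if (n_pairs == 0) return(NULL)
  a <- sample.int(L, n_pairs, replace = TRUE) - 1L
  flen <- pmin(L, pmax(2L * rl, as.integer(round(
    rnorm(n_pairs, design$insert_mean, design$insert_sd)))))
  flip <- runif(n_pairs) < 0.5

  w <- segments$end - segments$start + 1L
  cum <- cumsum(w)
  seg_start <- c(0L, cum[-length(cum)])

  # read-level vectors: fwd reads 1..n, rev reads n+1..2n (pair i, i+n)
  A <- c(a, (a + flen - rl) %% L)
  REV <- rep(c(FALSE, TRUE), each = n_pairs)
  IS_R1 <- c(!flip, flip)
  n_reads <- 2L * n_pairs
  seg_i <- findInterval(A, seg_start)
  single <- (A + rl) <= cum[seg_i]

  # per-read primary placement (filled for all reads)
  P_chrom <- character(n_reads); P_pos <- integer(n_reads)
  P_end <- integer(n_reads)
  rec_list <- vector("list", 2L)

  # single-block reads: one 150M record each
  si <- which(single)
  if (length(si)) {
    gi <- seg_i[si]
    pos <- segments$start[gi] + (A[si] - seg_start[gi])
    P_chrom[si] <- segments$chrom[gi]
    P_pos[si] <- pos
    P_end[si] <- pos + rl - 1L
    rec_list[[1L]] <- data.frame(
      ridx = si, chrom = segments$chrom[gi], pos = pos,
      cigar = paste0(rl, "M"), sa = NA_character_, is_primary = TRUE,
      stringsAsFactors = FALSE)
  }

  # junction-crossing reads: explicit block decomposition
  mi <- which(!single)
  if (length(mi)) {
    multi <- vector("list", length(mi))
    for (k in seq_along(mi)) {
      r <- mi[k]
      blocks <- circle_blocks(A[r], rl, segments)
      offs <- cumsum(c(0L, blocks$len))[seq_len(nrow(blocks))]
      keep <- blocks$len >= design$min_clip
      keep[which.max(blocks$len)] <- TRUE
      blocks <- blocks[keep, , drop = FALSE]
      offs <- offs[keep]
      nb <- nrow(blocks)
      primary_idx <- which.max(blocks$len)
      cigars <- vapply(seq_len(nb), function(j) {
        block_cigar(offs[j], blocks$len[j], rl)
      }, character(1))
      sa_items <- sprintf("%s,%d,%s,%s,%d,0;", blocks$chrom, blocks$gstart,
                          if (REV[r]) "-" else "+", cigars, mapq)
      sa <- vapply(seq_len(nb), function(j) {
        others <- setdiff(seq_len(nb), j)
        if (length(others) == 0) NA_character_ else
          paste(sa_items[others], collapse = "")
      }, character(1))
      P_chrom[r] <- blocks$chrom[primary_idx]
      P_pos[r] <- blocks$gstart[primary_idx]
      P_end[r] <- blocks$gstart[primary_idx] + blocks$len[primary_idx] - 1L
      multi[[k]] <- data.frame(
        ridx = r, chrom = blocks$chrom, pos = blocks$gstart,
        cigar = cigars, sa = sa,
        is_primary = seq_len(nb) == primary_idx,
        stringsAsFactors = FALSE)
    }
    rec_list[[2L]] <- do.call(rbind, multi)
  }
  recs <- do.call(rbind, rec_list)

  # read sequences; SEQ is stored in reference orientation (the SAM
  # convention), so reverse-strand records differ only by their flags
  SEQ <- character(n_reads)
  if (length(si)) SEQ[si] <- substring(seqstr, A[si] + 1L, A[si] + rl)
  for (r in mi) SEQ[r] <- circle_substr(seqstr, A[r], rl)
  SEQ <- apply_errors(SEQ, design$error_rate)

  # pair-level fields from each read's primary placement
  mate_ridx <- ifelse(seq_len(n_reads) <= n_pairs,
                      seq_len(n_reads) + n_pairs,
                      seq_len(n_reads) - n_pairs)
  same <- P_chrom[1:n_pairs] == P_chrom[(n_pairs + 1):n_reads]
  s1 <- P_pos[1:n_pairs]; e1 <- P_end[1:n_pairs]
  s2 <- P_pos[(n_pairs + 1):n_reads]; e2 <- P_end[(n_pairs + 1):n_reads]
  span <- ifelse(same, pmax(e1, e2) - pmin(s1, s2) + 1L, 0L)
  left_is_fwd <- ifelse(s1 <= s2, TRUE, FALSE)  # fwd read leftmost?
  proper <- same & left_is_fwd & span <= 1000L
  # TLEN: positive on the leftmost primary, negative on the other
  fwd_tlen <- ifelse(same, ifelse(left_is_fwd, span, -span), 0L)

  ridx <- recs$ridx
  pair_i <- ifelse(ridx <= n_pairs, ridx, ridx - n_pairs)
  is_fwd_read <- ridx <= n_pairs
  flag <- 1L +
    ifelse(proper[pair_i], 2L, 0L) +
    ifelse(REV[ridx], 16L, 0L) +
    ifelse(REV[mate_ridx[ridx]], 32L, 0L) +
    ifelse(IS_R1[ridx], 64L, 128L) +
    ifelse(recs$is_primary, 0L, 2048L)
  data.frame(
    read_id = sprintf("%s_p%06d", prefix, pair_i),
    flag = flag, chrom = recs$chrom, pos = recs$pos, mapq = mapq,
    cigar = recs$cigar,
    mate_chrom = P_chrom[mate_ridx[ridx]],
    mate_pos = P_pos[mate_ridx[ridx]],
    isize = ifelse(is_fwd_read, fwd_tlen[pair_i], -fwd_tlen[pair_i]),
    seq = SEQ[ridx], sa = recs$sa,
    stringsAsFactors = FALSE)
}

# concordant linear fragments over one contig -> alignment data.frame rows
linear_reads <- function(contig, contig_len, depth, design, prefix,
                         mapq = 60L, genome = NULL) {
  rl <- design$read_length
  n_pairs <- rpois(1, contig_len * depth / (2 * rl))
  if (n_pairs == 0) return(NULL)
  flen <- pmin(contig_len, pmax(2L * rl, as.integer(round(
    rnorm(n_pairs, design$insert_mean, design$insert_sd)))))
  s <- vapply(flen, function(fl) sample.int(contig_len - fl + 1L, 1),
              integer(1))
  e <- s + flen - 1L
  flip <- runif(n_pairs) < 0.5
  qn <- sprintf("%s_p%06d", prefix, seq_len(n_pairs))
  get_seq <- function(from, to) {
    if (is.null(genome)) return(NA_character_)
    apply_errors(as.character(Biostrings::subseq(genome[[contig]],
                                                 from, to)),
                 design$error_rate)
  }
  fwd_seq <- vapply(seq_len(n_pairs),
                    function(i) get_seq(s[i], s[i] + rl - 1L), "")
  rev_seq <- vapply(seq_len(n_pairs),
                    function(i) get_seq(e[i] - rl + 1L, e[i]), "")
  fwd <- data.frame(
    read_id = qn, flag = 1L + 2L + 32L + ifelse(flip, 128L, 64L),
    chrom = contig, pos = s, mapq = mapq, cigar = paste0(rl, "M"),
    mate_chrom = contig, mate_pos = e - rl + 1L, isize = flen,
    seq = fwd_seq, sa = NA_character_, stringsAsFactors = FALSE)
  rev <- data.frame(
    read_id = qn, flag = 1L + 2L + 16L + ifelse(flip, 64L, 128L),
    chrom = contig, pos = e - rl + 1L, mapq = mapq,
    cigar = paste0(rl, "M"),
    mate_chrom = contig, mate_pos = s, isize = -flen,
    seq = rev_seq, sa = NA_character_, stringsAsFactors = FALSE)
  rbind(fwd, rev)
}

#' Generate per-cell alignments from planted truth
#'
#' @param truth circle list from [plant_circles()].
#' @param genome DNAStringSet from [make_genome()].
#' @param design [sim_design()] list.
#' @param seed integer seed.
#' @return named list (one alignment data.frame per cell, coordinate
#'   sorted), with the per-circle amplification multipliers attached as
#'   attribute `depth_mult`.
#' @export
generate_alignments <- function(truth, genome, design, seed = 1L) {
  set.seed(seed)
  sl <- design_seqlengths(design)
  cells <- sprintf("cell%03d", seq_len(design$n_cells))
  mito_segs <- data.frame(chrom = design$mito_contig, start = 1L,
                          end = design$mito_size, strand = "+")
  mito_seq <- circle_sequence(mito_segs, genome)
  spc <- names(design$spike_size)[1]
  spl <- names(design$spike_size)[2]
  spc_segs <- data.frame(chrom = spc, start = 1L,
                         end = design$spike_size[[1]], strand = "+")
  spc_seq <- circle_sequence(spc_segs, genome)

  by_cell <- split(truth, vapply(truth, `[[`, "", "cell"))
  depth_mult <- list()
  out <- lapply(cells, function(cell) {
    parts <- list()
    for (circ in by_cell[[cell]] %||% list()) {
      mult <- rlnorm(1, 0, design$rca_sigma)
      depth_mult[[circ$circle_id]] <<- mult
      seqstr <- circle_sequence(circ$segments, genome)
      parts[[length(parts) + 1L]] <- reads_from_circle(
        circ$segments, seqstr, design$circle_depth * mult, design,
        prefix = circ$circle_id)
    }
    parts[[length(parts) + 1L]] <- reads_from_circle(
      mito_segs, mito_seq, design$mito_depth, design,
      prefix = paste0(cell, "_mt"))
    parts[[length(parts) + 1L]] <- reads_from_circle(
      spc_segs, spc_seq, design$spike_circ_depth, design,
      prefix = paste0(cell, "_spc"))
    parts[[length(parts) + 1L]] <- linear_reads(
      spl, design$spike_size[[2]], design$spike_lin_depth, design,
      prefix = paste0(cell, "_spl"), genome = genome)
    if (design$background_depth > 0) {
      for (ctg in names(design$chrom_sizes)) {
        parts[[length(parts) + 1L]] <- linear_reads(
          ctg, design$chrom_sizes[[ctg]], design$background_depth, design,
          prefix = paste0(cell, "_bg_", ctg), genome = genome)
      }
    }
    df <- do.call(rbind, parts)
    df <- df[order(match(df$chrom, names(sl)), df$pos), , drop = FALSE]
    rownames(df) <- NULL
    alignments(read_id = df$read_id, flag = df$flag, chrom = df$chrom,
               pos = df$pos, mapq = df$mapq, cigar = df$cigar,
               mate_chrom = df$mate_chrom, mate_pos = df$mate_pos,
               isize = df$isize, seq = df$seq, sa = df$sa)
  })
  names(out) <- cells
  attr(out, "depth_mult") <- unlist(depth_mult)
  out
}

# JSON-ready truth representation (0-based half-open segments)
truth_to_json <- function(truth) {
  lapply(truth, function(circ) {
    list(circle_id = circ$circle_id, cell = circ$cell,
         class = circ$class, kind = circ$kind,
         segments = lapply(seq_len(nrow(circ$segments)), function(i) {
           list(chrom = circ$segments$chrom[i],
                start = circ$segments$start[i] - 1L,
                end = circ$segments$end[i],
                strand = circ$segments$strand[i])
         }))
  })
}

#' Simulate a full population to disk
#'
#' Writes the genome FASTA (+ index), one coordinate-sorted SAM per
#' cell, the circle truth and design as JSON, and a manifest with md5
#' checksums of every file. Fully reproducible from (design, seed).
#'
#' @param design [sim_design()] list.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return invisibly, a list with the genome, truth, alignments and
#'   file paths.
#' @export
simulate_population <- function(design, seed = 1L, out_dir,
                                force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty: ", out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- make_genome(design, seed)
  truth <- plant_circles(design, seed + 1L)
  alns <- generate_alignments(truth, genome, design, seed + 2L)

  fa <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fa)
  Rsamtools::indexFa(fa)
  si <- Seqinfo(names(genome), width(genome))
  sam_paths <- vapply(names(alns), function(cell) {
    p <- file.path(out_dir, paste0(cell, ".sam"))
    write_sam(alns[[cell]], p, si)
    p
  }, character(1))
  jsonlite::write_json(truth_to_json(truth),
                       file.path(out_dir, "truth.json"), auto_unbox = TRUE)
  jsonlite::write_json(design, file.path(out_dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(fa, sam_paths,
             file.path(out_dir, c("truth.json", "design.json")))
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    n_records = c(NA, vapply(alns, nrow, integer(1)), NA, NA)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(list(genome = genome, truth = truth, alignments = alns,
                 fasta = fa, sam = sam_paths, seqinfo = si))
}
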