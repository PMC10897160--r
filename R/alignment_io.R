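## Alignment input/output and per-read operations.
##
## Alignments are held as a plain data.frame (one row per SAM record) with
## 1-based leftmost positions, mirroring the SAM fields plus decoded flag
## bits and the raw SA tag. All interval containers downstream are GRanges.

ALN_COLS <- c("read_id", "flag", "chrom", "pos", "mapq", "cigar",
              "is_paired", "is_read1", "is_mapped", "is_reverse",
              "is_secondary", "is_supplementary", "is_duplicate",
              "is_proper_pair", "mate_chrom", "mate_pos", "mate_is_reverse",
              "isize", "seq", "sa")

#' Construct an alignment table
#'
#' Builds the canonical per-record alignment data.frame used throughout
#' the package, decoding SAM flag bits. Mainly used by the reader and the
#' simulator; tests use it to build small fixtures in code.
#'
#' @param read_id,chrom,pos,mapq,cigar per-record SAM fields (`pos` is
#'   1-based leftmost).
#' @param flag integer SAM flag vector.
#' @param mate_chrom,mate_pos,isize mate placement; NA/0 when unpaired.
#' @param seq read sequence (or NA).
#' @param sa raw `SA:Z:` tag string ("chrom,pos,strand,CIGAR,mapQ,NM;..."),
#'   or NA when the read is not split.
#' @return data.frame with one row per record.
#' @export
alignments <- function(read_id, flag, chrom, pos, mapq, cigar,
                       mate_chrom = NA_character_, mate_pos = NA_integer_,
                       isize = 0L, seq = NA_character_, sa = NA_character_) {
  n <- length(read_id)
  flag <- as.integer(flag)
  data.frame(
    read_id = as.character(read_id), flag = flag,
    chrom = as.character(chrom), pos = as.integer(pos),
    mapq = as.integer(mapq), cigar = as.character(cigar),
    is_paired = bitwAnd(flag, 1L) > 0L,
    is_read1 = bitwAnd(flag, 64L) > 0L,
    is_mapped = bitwAnd(flag, 4L) == 0L,
    is_reverse = bitwAnd(flag, 16L) > 0L,
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_duplicate = bitwAnd(flag, 1024L) > 0L,
    is_proper_pair = bitwAnd(flag, 2L) > 0L,
    mate_chrom = rep_len(as.character(mate_chrom), n),
    mate_pos = rep_len(as.integer(mate_pos), n),
    mate_is_reverse = bitwAnd(flag, 32L) > 0L,
    isize = rep_len(as.integer(isize), n),
    seq = rep_len(as.character(seq), n),
    sa = rep_len(as.character(sa), n),
    stringsAsFactors = FALSE
  )
}

# reference span implied by a CIGAR (M/D/N/=/X), vectorized
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# leading / trailing soft+hard clip lengths, vectorized
cigar_clips <- function(cigar) {
  lead <- rep(0L, length(cigar))
  trail <- rep(0L, length(cigar))
  m <- regmatches(cigar, regexpr("^[0-9]+[SH]", cigar))
  has <- grepl("^[0-9]+[SH]", cigar)
  lead[has] <- as.integer(sub("[SH]$", "", m))
  m2 <- regmatches(cigar, regexpr("[0-9]+[SH]$", cigar))
  has2 <- grepl("[0-9]+[SH]$", cigar)
  trail[has2] <- as.integer(sub("[SH]$", "", m2))
  # a CIGAR that is pure clip at both ends with one number matches both
  list(lead = lead, trail = trail)
}

#' Parse an SA tag
#'
#' Decodes the supplementary-alignment descriptor grammar
#' `"chrom,pos,strand,CIGAR,mapQ,NM;"` (pos 1-based on disk). Returns
#' positions both 1-based (`pos`) and 0-based (`pos0`).
#'
#' @param sa a single SA tag string.
#' @return data.frame with columns chrom, pos, pos0, strand, cigar, mapq, nm
#'   (zero rows for NA/empty input).
#' @export
parse_sa_tag <- function(sa) {
  empty <- data.frame(chrom = character(), pos = integer(), pos0 = integer(),
                      strand = character(), cigar = character(),
                      mapq = integer(), nm = integer())
  if (length(sa) != 1 || is.na(sa) || !nzchar(sa)) return(empty)
  entries <- strsplit(sa, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0) return(empty)
  parts <- do.call(rbind, strsplit(entries, ",", fixed = TRUE))
  if (ncol(parts) < 5) stop("malformed SA tag: ", sa)
  nm <- if (ncol(parts) >= 6) as.integer(parts[, 6]) else NA_integer_
  pos <- as.integer(parts[, 2])
  data.frame(chrom = parts[, 1], pos = pos, pos0 = pos - 1L,
             strand = parts[, 3], cigar = parts[, 4],
             mapq = as.integer(parts[, 5]), nm = nm,
             stringsAsFactors = FALSE)
}

# Convert a SAM file to a sorted, indexed BAM in tempdir (or reuse .bam)
ensure_bam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!file.exists(paste0(path, ".bai"))) Rsamtools::indexBam(path)
    return(path)
  }
  if (!file.exists(path)) stop("alignment file not found: ", path)
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                          indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(bam, tempfile())
  Rsamtools::indexBam(sorted)
  sorted
}

#' Read alignments from SAM or BAM
#'
#' Reads every record (primary, secondary and supplementary) into the
#' package's alignment table, in coordinate order. SAM input is converted
#' to a temporary coordinate-sorted BAM first.
#'
#' @param path SAM or BAM file.
#' @param region optional GRanges of length 1; only records overlapping
#'   it are returned.
#' @param keep_seq keep read sequences (needed by the simulator
#'   round-trip tests; off by default to save memory).
#' @return alignment data.frame (see [alignments()]).
#' @export
read_alignments <- function(path, region = NULL, keep_seq = FALSE) {
  bam <- ensure_bam(path)
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize", if (keep_seq) "seq")
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = what, tag = "SA")
  } else {
    Rsamtools::ScanBamParam(what = what, tag = "SA", which = region)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  res <- if (length(res) == 0) NULL else res[[1]]
  n <- length(res$qname)
  sa <- res$tag$SA %||% rep(NA_character_, n)
  aln <- alignments(
    read_id = res$qname, flag = res$flag,
    chrom = as.character(res$rname), pos = res$pos,
    mapq = res$mapq, cigar = res$cigar,
    mate_chrom = as.character(res$mrnm), mate_pos = res$mpos,
    isize = ifelse(is.na(res$isize), 0L, res$isize),
    seq = if (keep_seq) as.character(res$seq) else NA_character_,
    sa = as.character(sa)
  )
  aln
}

#' Write an alignment table as SAM
#'
#' @param aln alignment data.frame.
#' @param path output `.sam` path.
#' @param seqinfo [GenomeInfoDb::Seqinfo] providing `@SQ` header lines.
#' @param sort_by_coord write records sorted by (chrom, pos).
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, seqinfo, sort_by_coord = TRUE) {
  sl <- seqlengths(seqinfo)
  header <- c(
    sprintf("@HD\tVN:1.6\tSO:%s",
            if (sort_by_coord) "coordinate" else "unsorted"),
    sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl)
  )
  if (sort_by_coord && nrow(aln) > 0) {
    aln <- aln[order(match(aln$chrom, names(sl)), aln$pos), , drop = FALSE]
  }
  rnext <- ifelse(is.na(aln$mate_chrom), "*",
                  ifelse(aln$mate_chrom == aln$chrom, "=", aln$mate_chrom))
  pnext <- ifelse(is.na(aln$mate_pos), 0L, aln$mate_pos)
  seqf <- ifelse(is.na(aln$seq), "*", aln$seq)
  qual <- ifelse(is.na(aln$seq), "*",
                 vapply(nchar(seqf), function(k) strrep("I", k), ""))
  qual[seqf == "*"] <- "*"
  lines <- paste(aln$read_id, aln$flag, aln$chrom, aln$pos, aln$mapq,
                 aln$cigar, rnext, pnext, aln$isize, seqf, qual,
                 sep = "\t")
  has_sa <- !is.na(aln$sa) & nzchar(aln$sa)
  lines[has_sa] <- paste0(lines[has_sa], "\tSA:Z:", aln$sa[has_sa])
  writeLines(c(header, lines), path)
  invisible(path)
}

# unclipped 5' position of each record (clip-aware duplicate key)
unclipped_five_prime <- function(aln) {
  clips <- cigar_clips(aln$cigar)
  rw <- cigar_ref_width(aln$cigar)
  ifelse(aln$is_reverse,
         aln$pos + rw - 1L + clips$trail,
         aln$pos - clips$lead)
}

#' Remove duplicate read pairs
#'
#' Groups primary records by the unclipped 5' positions and orientations
#' of both mates (orphans and unpaired reads by their own position) and
#' keeps exactly one read (pair) per group: the one with the highest
#' summed mapping quality, ties broken by the lexicographically smallest
#' read identifier. Supplementary/secondary records of discarded reads
#' are dropped with them. Clip-aware keying matters here because split
#' reads at circle junctions are soft-clipped and would otherwise
#' collide with each other.
#'
#' @param aln alignment data.frame (coordinate-sorted).
#' @return the deduplicated alignment data.frame.
#' @export
deduplicate <- function(aln) {
  if (nrow(aln) == 0) return(aln)
  prim <- !aln$is_secondary & !aln$is_supplementary & aln$is_mapped
  p <- aln[prim, , drop = FALSE]
  if (nrow(p) == 0) return(aln)
  dt <- data.table::data.table(
    read_id = p$read_id,
    chrom = p$chrom,
    u5 = unclipped_five_prime(p),
    strand = p$is_reverse,
    mapq = p$mapq
  )
  endkey <- dt[, paste0(chrom, ":", u5, ":", ifelse(strand, "-", "+"))]
  dt[, ek := endkey]
  # one row per read id: canonical (sorted) combination of its mate keys
  per_read <- dt[, .(
    key = paste(sort(ek), collapse = "|"),
    mapq_sum = sum(mapq)
  ), by = read_id]
  keep <- per_read[order(-mapq_sum, read_id), .SD[1], by = key]$read_id
  drop_ids <- setdiff(per_read$read_id, keep)
  aln[!(aln$read_id %in% drop_ids), , drop = FALSE]
}

#' Mapping rate of a cell
#'
#' Mapped primary records divided by the total read count (including
#' unmapped reads).
#'
#' @param aln alignment data.frame of one cell.
#' @param n_total_reads total number of reads including unmapped ones;
#'   defaults to the number of primary records in `aln`.
#' @return fraction in \[0, 1\].
#' @export
mapping_rate <- function(aln, n_total_reads = NULL) {
  prim <- !aln$is_secondary & !aln$is_supplementary
  mapped <- sum(prim & aln$is_mapped)
  if (is.null(n_total_reads)) n_total_reads <- sum(prim)
  if (n_total_reads == 0) stop("n_total_reads is zero")
  if (n_total_reads < mapped) stop("n_total_reads smaller than mapped count")
  mapped / n_total_reads
}

#' Extract chimeric (split and discordant) reads
#'
#' Split reads are primary records carrying at least one
#' supplementary-alignment descriptor; discordant pairs are
#' inter-chromosomal, orientation-anomalous (everted RF, or tandem
#' FF/RR) or long-insert pairs. Both classes require mapping quality
#' above `min_mapq`. Pairs matching the rolling-circle R2R1 artifact
#' signature (tandem orientation with read 2 starting upstream of
#' read 1) are removed from both sets by default.
#'
#' @param aln deduplicated alignment data.frame.
#' @param min_mapq minimum mapping quality (strict; default 20).
#' @param insert_threshold insert size above which a same-chromosome FR
#'   pair is called discordant (default 1000 bp).
#' @param drop_r2r1 remove R2R1 artifact pairs (default TRUE).
#' @return list with elements `split` (primary split records) and
#'   `discordant` (both mates of each discordant pair).
#' @export
extract_chimeric <- function(aln, min_mapq = 20L, insert_threshold = 1000L,
                             drop_r2r1 = TRUE) {
  prim <- aln[!aln$is_secondary & !aln$is_supplementary & aln$is_mapped, ,
              drop = FALSE]
  split_reads <- prim[!is.na(prim$sa) & nzchar(prim$sa) &
                        prim$mapq > min_mapq, , drop = FALSE]

  paired <- prim[prim$is_paired & !is.na(prim$mate_chrom), , drop = FALSE]
  dt <- data.table::data.table(
    read_id = paired$read_id, is_read1 = paired$is_read1,
    chrom = paired$chrom, pos = paired$pos,
    rev = paired$is_reverse, mapq = paired$mapq, isize = paired$isize,
    idx = seq_len(nrow(paired))
  )
  r1 <- dt[is_read1 == TRUE]
  r2 <- dt[is_read1 == FALSE]
  pairs <- merge(r1, r2, by = "read_id", suffixes = c("_1", "_2"))
  r2r1_ids <- character()
  disc_ids <- character()
  if (nrow(pairs) > 0) {
    pairs[, same_chrom := chrom_1 == chrom_2]
    pairs[, tandem := rev_1 == rev_2]
    left_rev <- with(pairs, ifelse(pos_1 <= pos_2, rev_1, rev_2))
    pairs[, everted := same_chrom & !tandem & left_rev]
    pairs[, long_insert := same_chrom & abs(isize_1) > insert_threshold]
    pairs[, qual_ok := mapq_1 > min_mapq & mapq_2 > min_mapq]
    pairs[, is_r2r1 := same_chrom & tandem & pos_2 < pos_1]
    pairs[, discordant := qual_ok & (!same_chrom | tandem | everted |
                                       long_insert)]
    if (drop_r2r1) {
      r2r1_ids <- pairs[is_r2r1 == TRUE, read_id]
      pairs <- pairs[is_r2r1 == FALSE]
    }
    disc_ids <- pairs[discordant == TRUE, read_id]
  }
  if (drop_r2r1 && length(r2r1_ids)) {
    split_reads <- split_reads[!(split_reads$read_id %in% r2r1_ids), ,
                               drop = FALSE]
  }
  discordant <- prim[prim$read_id %in% disc_ids, , drop = FALSE]
  list(split = split_reads, discordant = discordant)
}

# GRanges of primary mapped (optionally non-duplicate) records
aln_granges <- function(aln, seqinfo = NULL) {
  use <- !aln$is_secondary & !aln$is_supplementary & aln$is_mapped &
    !aln$is_duplicate
  a <- aln[use, , drop = FALSE]
  gr <- GRanges(a$chrom,
                IRanges(a$pos, width = cigar_ref_width(a$cigar)),
                strand = ifelse(a$is_reverse, "-", "+"))
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(seqinfo)
    seqinfo(gr) <- seqinfo
  }
  mcols(gr)$read_id <- a$read_id
  gr
}

#' Binned read coverage
#'
#' Counts, for every fixed-width genomic bin, the number of primary
#' non-duplicate records whose aligned reference span overlaps the bin
#' (a read spanning a bin boundary increments both bins).
#'
#' @param aln alignment data.frame.
#' @param seqinfo Seqinfo of the active genome.
#' @param bin_size bin width in bp (default 100).
#' @return an `ecc_coverage` object: list with `bin_size`, `seqlengths`
#'   and `counts`, a named list of per-contig integer vectors of length
#'   `ceiling(contig_length / bin_size)`.
#' @export
compute_coverage <- function(aln, seqinfo, bin_size = 100L) {
  stopifnot(bin_size >= 1)
  reads <- aln_granges(aln, seqinfo)
  coverage_from_granges(reads, seqinfo, bin_size)
}

# same contract as compute_coverage but from a read GRanges
coverage_from_granges <- function(reads, seqinfo, bin_size = 100L) {
  sl <- seqlengths(seqinfo)
  counts <- lapply(names(sl), function(ctg) {
    n_bins <- as.integer(ceiling(sl[[ctg]] / bin_size))
    r <- reads[as.character(seqnames(reads)) == ctg]
    v <- integer(n_bins)
    if (length(r) > 0) {
      tiles <- GRanges(ctg, IRanges(
        start = seq_len(n_bins) * bin_size - bin_size + 1L,
        end = pmin(seq_len(n_bins) * bin_size, sl[[ctg]])
      ))
      v <- countOverlaps(tiles, r, ignore.strand = TRUE)
    }
    v
  })
  names(counts) <- names(sl)
  structure(list(bin_size = as.integer(bin_size), seqlengths = sl,
                 counts = counts),
            class = "ecc_coverage")
}

# GRanges of the bins of one contig (used by peak calling)
coverage_bins <- function(cov, contig) {
  n <- length(cov$counts[[contig]])
  GRanges(contig, IRanges(
    start = seq_len(n) * cov$bin_size - cov$bin_size + 1L,
    end = pmin(seq_len(n) * cov$bin_size, cov$seqlengths[[contig]])
  ))
}
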