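## Circle-producing region (CPR) detection.
##
## After exonuclease digestion of linear DNA and rolling-circle
## amplification, genomic background coverage is close to zero, so circle
## templates stand out as contiguous runs of enriched bins. Peak calling
## here is a quantile-background run scan: a bin is "enriched" when its
## count reaches max(min_cov, enrichment_factor x background), where the
## background is a genome-wide quantile of the bin counts. Zero bins are
## included in the quantile: after digestion most of the genome is
## empty, and restricting to nonzero bins would let the circle bins
## themselves dominate the estimate whenever circles occupy a
## substantial footprint.

#' CPR detection parameters
#'
#' @param bin_size coverage bin width, bp.
#' @param min_cov minimum reads per bin for an enriched bin.
#' @param enrichment_factor multiple of the background a bin must reach.
#' @param background_quantile quantile of the bin counts (zeros
#'   included) used as the background level.
#' @param merge_gap maximum gap (bp) between enriched runs that are
#'   merged into one region.
#' @param edge_fraction fraction of the region maximum used when
#'   refining borders.
#' @param min_cpr_length minimum CPR length, bp.
#' @param min_mapq mapping-quality cutoff (strict) for chimeric reads.
#' @param insert_threshold discordant-pair insert-size cutoff, bp.
#' @param exclude_contigs contigs excluded from CPR calling (the
#'   mitochondrial and spike-in contigs; they are kept for QC and
#'   normalization).
#' @param mito_contig name of the mitochondrial contig.
#' @return named list of parameters.
#' @export
cpr_params <- function(bin_size = 100L, min_cov = 5L, enrichment_factor = 4,
                       background_quantile = 0.5, merge_gap = 1000L,
                       edge_fraction = 0.1, min_cpr_length = 200L,
                       min_mapq = 20L, insert_threshold = 1000L,
                       exclude_contigs = character(),
                       mito_contig = NA_character_) {
  list(bin_size = as.integer(bin_size), min_cov = min_cov,
       enrichment_factor = enrichment_factor,
       background_quantile = background_quantile,
       merge_gap = as.integer(merge_gap), edge_fraction = edge_fraction,
       min_cpr_length = as.integer(min_cpr_length),
       min_mapq = as.integer(min_mapq),
       insert_threshold = as.integer(insert_threshold),
       exclude_contigs = exclude_contigs, mito_contig = mito_contig)
}

#' Call enriched coverage runs
#'
#' Returns maximal runs of consecutive bins whose count reaches
#' `max(min_cov, enrichment_factor * background)`; the background is the
#' `background_quantile` quantile of the bin counts (zeros included)
#' across all contigs of the track.
#'
#' @param cov an `ecc_coverage` track.
#' @param min_cov,enrichment_factor,background_quantile see
#'   [cpr_params()].
#' @param contigs contigs to scan (default: all in the track).
#' @return GRanges of enriched regions (empty for all-zero coverage).
#' @export
call_peaks <- function(cov, min_cov = 5L, enrichment_factor = 4,
                       background_quantile = 0.5,
                       contigs = names(cov$counts)) {
  all_counts <- unlist(cov$counts[contigs], use.names = FALSE)
  if (!any(all_counts > 0)) return(GRanges())
  background <- as.numeric(quantile(all_counts, background_quantile))
  thr <- max(min_cov, enrichment_factor * background)
  res <- lapply(contigs, function(ctg) {
    v <- cov$counts[[ctg]]
    r <- rle(v >= thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(GRanges())
    GRanges(factor(ctg, levels = contigs), IRanges(
      start = (starts[keep] - 1L) * cov$bin_size + 1L,
      end = pmin(ends[keep] * cov$bin_size, cov$seqlengths[[ctg]])
    ))
  })
  res <- res[vapply(res, length, integer(1)) > 0]
  if (length(res) == 0) return(GRanges())
  sort(do.call(c, res))
}

#' Merge nearby regions
#'
#' Unions intervals on the same contig that overlap or lie within `gap`
#' bp of each other; output is sorted and non-overlapping.
#'
#' @param regions GRanges.
#' @param gap maximum gap in bp.
#' @return merged GRanges.
#' @export
merge_regions <- function(regions, gap = 1000L) {
  if (length(regions) == 0) return(regions)
  sort(reduce(regions, min.gapwidth = gap + 1L, ignore.strand = TRUE))
}

#' Refine region borders against coverage
#'
#' Each border is first pushed outward while the adjacent bin still
#' holds at least `edge_fraction` of the region's maximum bin count,
#' then pulled inward past edge bins that fall below that cutoff. A
#' region never shrinks past its coverage maximum.
#'
#' @param regions GRanges within the coverage extent.
#' @param cov `ecc_coverage` track.
#' @param edge_fraction fraction of the region maximum (default 0.1).
#' @return GRanges with refined borders.
#' @export
refine_borders <- function(regions, cov, edge_fraction = 0.1) {
  if (length(regions) == 0) return(regions)
  bs <- cov$bin_size
  out <- regions
  for (i in seq_along(regions)) {
    ctg <- as.character(seqnames(regions)[i])
    v <- cov$counts[[ctg]]
    nb <- length(v)
    b1 <- (start(regions)[i] - 1L) %/% bs + 1L
    b2 <- (end(regions)[i] - 1L) %/% bs + 1L
    peak <- max(v[b1:b2])
    if (peak <= 0) next
    cutoff <- edge_fraction * peak
    imax <- b1 - 1L + which.max(v[b1:b2])
    while (b1 > 1L && v[b1 - 1L] >= cutoff) b1 <- b1 - 1L
    while (b2 < nb && v[b2 + 1L] >= cutoff) b2 <- b2 + 1L
    while (b1 < imax && v[b1] < cutoff) b1 <- b1 + 1L
    while (b2 > imax && v[b2] < cutoff) b2 <- b2 - 1L
    start(out)[i] <- (b1 - 1L) * bs + 1L
    end(out)[i] <- min(b2 * bs, cov$seqlengths[[ctg]])
  }
  out
}

#' Detect circle-producing regions in one cell
#'
#' Full per-cell CPR calling: binned coverage on the nuclear contigs,
#' enriched-run calling, merging, border refinement, minimum-length
#' filter, then per-CPR coverage statistics and circle-supporting
#' (split + discordant) read counts. Junctions are attached separately
#' by [cluster_junctions()] / [classify_cpr_structure()].
#'
#' @param aln deduplicated alignment data.frame of one cell.
#' @param seqinfo Seqinfo of the active genome.
#' @param params list from [cpr_params()].
#' @return GRanges of CPRs with metadata columns `cpr_id`, `mean_cov`,
#'   `max_cov`, `n_reads`, `n_circle_reads`, `structure_class`.
#' @export
detect_cprs <- function(aln, seqinfo, params = cpr_params()) {
  if (nrow(aln) == 0) stop("empty alignment input")
  cov <- compute_coverage(aln, seqinfo, params$bin_size)
  contigs <- setdiff(names(cov$counts), params$exclude_contigs)
  peaks <- call_peaks(cov, params$min_cov, params$enrichment_factor,
                      params$background_quantile, contigs)
  merged <- merge_regions(peaks, params$merge_gap)
  refined <- refine_borders(merged, cov, params$edge_fraction)
  refined <- merge_regions(refined, 0L)
  cprs <- refined[width(refined) >= params$min_cpr_length]
  GenomeInfoDb::seqlevels(cprs) <- GenomeInfoDb::seqlevels(seqinfo)
  seqinfo(cprs) <- seqinfo
  annotate_cprs(cprs, aln, cov, params)
}

# populate CPR metadata (coverage stats and circle-supporting reads)
annotate_cprs <- function(cprs, aln, cov, params) {
  n <- length(cprs)
  if (n == 0) {
    mcols(cprs) <- DataFrame(cpr_id = character(), mean_cov = numeric(),
                             max_cov = numeric(), n_reads = integer(),
                             n_circle_reads = integer(),
                             structure_class = character())
    return(cprs)
  }
  bs <- cov$bin_size
  mean_cov <- max_cov <- numeric(n)
  for (i in seq_len(n)) {
    v <- cov$counts[[as.character(seqnames(cprs)[i])]]
    b1 <- (start(cprs)[i] - 1L) %/% bs + 1L
    b2 <- (end(cprs)[i] - 1L) %/% bs + 1L
    mean_cov[i] <- mean(v[b1:b2])
    max_cov[i] <- max(v[b1:b2])
  }
  reads <- aln_granges(aln)
  chim <- extract_chimeric(aln, params$min_mapq, params$insert_threshold)
  circle <- unique(rbind(chim$split, chim$discordant))
  n_circle <- integer(n)
  if (nrow(circle) > 0) {
    circle_gr <- GRanges(circle$chrom,
                         IRanges(circle$pos,
                                 width = cigar_ref_width(circle$cigar)))
    n_circle <- countOverlaps(cprs, circle_gr, ignore.strand = TRUE)
  }
  mcols(cprs) <- DataFrame(
    cpr_id = sprintf("CPR_%s_%d_%d", seqnames(cprs), start(cprs), end(cprs)),
    mean_cov = mean_cov, max_cov = max_cov,
    n_reads = countOverlaps(cprs, reads, ignore.strand = TRUE),
    n_circle_reads = n_circle,
    structure_class = rep("unclassified", n)
  )
  cprs
}

#' Write CPRs as BED6 plus a statistics TSV
#'
#' BED name is the CPR id and the score the circle-supporting read
#' count; the TSV carries all coverage statistics.
#'
#' @param cprs CPR GRanges from [detect_cprs()].
#' @param bed_path,tsv_path output paths (NULL to skip one of them).
#' @export
write_cprs <- function(cprs, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    gr <- cprs
    mcols(gr) <- DataFrame(name = cprs$cpr_id,
                           score = pmin(1000L, cprs$n_circle_reads))
    write_bed(gr, bed_path)
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(chrom = as.character(seqnames(cprs)),
                     start0 = start(cprs) - 1L, end = end(cprs),
                     as.data.frame(mcols(cprs)))
    write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
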