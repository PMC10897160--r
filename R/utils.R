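#' Weighted median
#'
#' Median of `x` with non-negative weights `w`, defined as the smallest
#' `x` at which the cumulative weight reaches half of the total. Used for
#' the representative breakend of a junction cluster, where stray split
#' positions should not drag the representative away from the mode.
#'
#' @param x numeric vector.
#' @param w numeric weights, same length as `x`.
#' @return scalar weighted median.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Build a Seqinfo from a FASTA file
#'
#' @param fasta path to an (indexed or indexable) FASTA file.
#' @return a [GenomeInfoDb::Seqinfo] with contig names and lengths.
#' @export
fasta_seqinfo <- function(fasta) {
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  idx <- Rsamtools::scanFaIndex(fasta)
  GenomeInfoDb::Seqinfo(as.character(seqnames(idx)), width(idx))
}

#' Read a BED file as GRanges
#'
#' Thin wrapper over [rtracklayer::import.bed()]; BED is 0-based
#' half-open on disk, the returned GRanges is 1-based closed.
#'
#' @param path BED3/BED6 file.
#' @return GRanges.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' Write GRanges as BED
#'
#' @param gr GRanges; `name` and `score` metadata columns are written
#'   when present.
#' @param path output file.
#' @export
write_bed <- function(gr, path) rtracklayer::export(gr, path, format = "BED")

#' Write junctions as BEDPE
#'
#' Ten-column BEDPE (0-based half-open on disk):
#' chrom1,start1,end1,chrom2,start2,end2,name,score,strand1,strand2 with
#' score = supporting read count.
#'
#' @param junctions data frame from [cluster_junctions()].
#' @param path output file.
#' @export
write_bedpe <- function(junctions, path) {
  if (nrow(junctions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom1 = junctions$chrom1, start1 = junctions$pos1 - 1L,
    end1 = junctions$pos1,
    chrom2 = junctions$chrom2, start2 = junctions$pos2 - 1L,
    end2 = junctions$pos2,
    name = if (!is.null(junctions$junction_id)) junctions$junction_id
           else sprintf("junction_%d", seq_len(nrow(junctions))),
    score = junctions$support,
    strand1 = junctions$strand1, strand2 = junctions$strand2
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# interval midpoints as a width-1 GRanges
midpoints <- function(gr) {
  GRanges(seqnames(gr),
          IRanges(start(gr) + (width(gr) - 1L) %/% 2L, width = 1L),
          seqinfo = seqinfo(gr))
}

# reciprocal overlap fraction matrix entries for matched hit pairs
reciprocal_overlap <- function(query, subject) {
  hits <- findOverlaps(query, subject)
  if (length(hits) == 0) {
    return(data.frame(query = integer(), subject = integer(), ro = numeric()))
  }
  q <- query[queryHits(hits)]
  s <- subject[subjectHits(hits)]
  inter <- pmin(end(q), end(s)) - pmax(start(q), start(s)) + 1L
  data.frame(query = queryHits(hits), subject = subjectHits(hits),
             ro = pmin(inter / width(q), inter / width(s)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
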