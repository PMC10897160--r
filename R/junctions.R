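## Chimeric junction calling from split reads.
##
## A split read aligns in two pieces (primary + supplementary) that meet
## at the circle's closure point. The clipped end of the primary
## alignment and the facing end of the supplementary alignment define a
## pair of breakends; recurrent breakend pairs are clustered by
## single linkage and reported as junctions.

#' Extract raw junction endpoints from split reads
#'
#' For each primary/supplementary pair: if the primary alignment is
#' right-clipped, its breakend sits on its last aligned base
#' (side "right"); the supplementary's breakend sits on the facing
#' side inferred from its own clipping. One raw junction is emitted per
#' supplementary descriptor, canonicalized so that breakend `a` is not
#' after `b` in genome order.
#'
#' @param split_reads primary split records (from [extract_chimeric()]).
#' @return data.frame with columns chrom1, pos1, side1, strand1, chrom2,
#'   pos2, side2, strand2, read_id (1-based positions).
#' @export
extract_junction_endpoints <- function(split_reads) {
  out <- vector("list", nrow(split_reads))
  for (i in seq_len(nrow(split_reads))) {
    r <- split_reads[i, ]
    sa <- parse_sa_tag(r$sa)
    if (nrow(sa) == 0) stop("record without supplementary descriptor: ",
                            r$read_id)
    clips <- cigar_clips(r$cigar)
    p_right <- clips$trail >= clips$lead
    p_pos <- if (p_right) r$pos + cigar_ref_width(r$cigar) - 1L else r$pos
    p_side <- if (p_right) "right" else "left"
    p_strand <- if (r$is_reverse) "-" else "+"
    rows <- lapply(seq_len(nrow(sa)), function(k) {
      s_clips <- cigar_clips(sa$cigar[k])
      s_left <- s_clips$lead >= s_clips$trail
      s_pos <- if (s_left) sa$pos[k] else
        sa$pos[k] + cigar_ref_width(sa$cigar[k]) - 1L
      data.frame(chrom1 = r$chrom, pos1 = p_pos, side1 = p_side,
                 strand1 = p_strand,
                 chrom2 = sa$chrom[k], pos2 = s_pos,
                 side2 = if (s_left) "left" else "right",
                 strand2 = sa$strand[k],
                 read_id = r$read_id, stringsAsFactors = FALSE)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  raw <- do.call(rbind, out)
  if (is.null(raw)) {
    raw <- data.frame(chrom1 = character(), pos1 = integer(),
                      side1 = character(), strand1 = character(),
                      chrom2 = character(), pos2 = integer(),
                      side2 = character(), strand2 = character(),
                      read_id = character())
  }
  canonicalize_junctions(raw)
}

#' Canonicalize raw junctions
#'
#' Orders the two breakends of each raw junction so that
#' (chrom1, pos1) <= (chrom2, pos2).
#'
#' @param raw data.frame as produced by [extract_junction_endpoints()].
#' @return the reordered data.frame.
#' @export
canonicalize_junctions <- function(raw) {
  if (nrow(raw) == 0) return(raw)
  swap <- raw$chrom2 < raw$chrom1 |
    (raw$chrom2 == raw$chrom1 & raw$pos2 < raw$pos1)
  tmp <- raw[swap, c("chrom1", "pos1", "side1", "strand1")]
  raw[swap, c("chrom1", "pos1", "side1", "strand1")] <-
    raw[swap, c("chrom2", "pos2", "side2", "strand2")]
  raw[swap, c("chrom2", "pos2", "side2", "strand2")] <- tmp
  raw
}

#' Cluster raw junctions into supported chimeric junctions
#'
#' Single-linkage clustering: two raw junctions are linked when their
#' first breakends lie within `window` bp of each other and so do their
#' second breakends (same contig pair). Clusters with fewer than
#' `min_support` reads are discarded. The representative breakends are
#' support-weighted medians of the member positions. Each retained
#' junction is assigned a span class relative to the CPR set.
#'
#' @param raw canonicalized raw junction data.frame.
#' @param cprs CPR GRanges (may be empty; used for span classes and CPR
#'   assignment).
#' @param window clustering window, bp (default 500).
#' @param min_support minimum reads per junction (default 2).
#' @param edge_window distance from a CPR border within which a breakend
#'   counts as sitting on the CPR extremity (default 500 bp).
#' @param distal_threshold intra-chromosomal separation beyond which a
#'   junction outside a single CPR is called distal (default 1 Mb).
#' @return data.frame with one row per junction: chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, support, span_class, cpr_id, junction_id.
#' @export
cluster_junctions <- function(raw, cprs = GRanges(), window = 500L,
                              min_support = 2L, edge_window = 500L,
                              distal_threshold = 1e6) {
  empty <- data.frame(chrom1 = character(), pos1 = numeric(),
                      strand1 = character(), chrom2 = character(),
                      pos2 = numeric(), strand2 = character(),
                      support = integer(), span_class = character(),
                      cpr_id = character(), junction_id = character())
  if (nrow(raw) == 0) return(empty)
  raw$grp <- paste(raw$chrom1, raw$chrom2, sep = "\r")
  res <- lapply(split(raw, raw$grp), function(g) {
    n <- nrow(g)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    o <- order(g$pos1)
    for (ii in seq_len(n - 1)) {
      if (n < 2) break
      i <- o[ii]
      for (jj in (ii + 1):n) {
        j <- o[jj]
        if (g$pos1[j] - g$pos1[i] > window) break
        if (abs(g$pos2[j] - g$pos2[i]) <= window) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    members <- split(seq_len(n), roots)
    rows <- lapply(members, function(idx) {
      data.frame(
        chrom1 = g$chrom1[idx[1]],
        pos1 = weighted_median(g$pos1[idx]),
        strand1 = names(which.max(table(g$strand1[idx]))),
        chrom2 = g$chrom2[idx[1]],
        pos2 = weighted_median(g$pos2[idx]),
        strand2 = names(which.max(table(g$strand2[idx]))),
        support = length(idx), stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  jx <- do.call(rbind, res)
  rownames(jx) <- NULL
  jx <- jx[jx$support >= min_support, , drop = FALSE]
  if (nrow(jx) == 0) return(empty)
  jx <- jx[order(jx$chrom1, jx$pos1, jx$chrom2, jx$pos2), , drop = FALSE]
  cls <- classify_junction_spans(jx, cprs, edge_window, distal_threshold)
  jx$span_class <- cls$span_class
  jx$cpr_id <- cls$cpr_id
  jx$junction_id <- sprintf("JX_%s_%d_%s_%d", jx$chrom1, round(jx$pos1),
                            jx$chrom2, round(jx$pos2))
  rownames(jx) <- NULL
  jx
}

# span class of each junction relative to the CPR catalog
classify_junction_spans <- function(jx, cprs, edge_window = 500L,
                                    distal_threshold = 1e6) {
  n <- nrow(jx)
  span <- character(n)
  cpr_id <- rep(NA_character_, n)
  a <- GRanges(jx$chrom1, IRanges(round(jx$pos1), width = 1L))
  b <- GRanges(jx$chrom2, IRanges(round(jx$pos2), width = 1L))
  for (i in seq_len(n)) {
    if (jx$chrom1[i] != jx$chrom2[i]) {
      span[i] <- "inter"
      next
    }
    in_same <- integer(0)
    if (length(cprs)) {
      ha <- subjectHits(findOverlaps(a[i], cprs, maxgap = edge_window,
                                     ignore.strand = TRUE))
      hb <- subjectHits(findOverlaps(b[i], cprs, maxgap = edge_window,
                                     ignore.strand = TRUE))
      in_same <- intersect(ha, hb)
    }
    if (length(in_same)) {
      k <- in_same[1]
      cpr_id[i] <- cprs$cpr_id[k]
      at_left <- abs(jx$pos1[i] - start(cprs)[k]) <= edge_window
      at_right <- abs(jx$pos2[i] - end(cprs)[k]) <= edge_window
      span[i] <- if (at_left && at_right) "edge" else "internal"
    } else if (abs(jx$pos2[i] - jx$pos1[i]) > distal_threshold) {
      span[i] <- "distal_intra"
    } else {
      span[i] <- "internal"
    }
  }
  list(span_class = span, cpr_id = cpr_id)
}

#' Classify the structure of a CPR
#'
#' A CPR with no junction is `unclassified`; it is `simple` when all its
#' junctions join its extremities (both breakends within `edge_window`
#' of the CPR borders) and there are at most `max_simple_junctions` of
#' them; any internal, distal or inter-chromosomal junction (or more
#' distinct junctions than that) makes it `complex`.
#'
#' @param cpr a length-1 CPR GRanges.
#' @param junctions junction data.frame assigned to this CPR (rows with
#'   `cpr_id` equal to the CPR's id, plus any junction with a breakend
#'   inside the CPR).
#' @param edge_window bp window around the CPR extremities (default 500).
#' @param max_simple_junctions maximum distinct junctions a simple CPR
#'   may carry (default 2).
#' @return one of "simple", "complex", "unclassified".
#' @export
classify_cpr_structure <- function(cpr, junctions, edge_window = 500L,
                                   max_simple_junctions = 2L) {
  if (is.null(junctions) || nrow(junctions) == 0) return("unclassified")
  if (nrow(junctions) > max_simple_junctions) return("complex")
  edge <- junctions$span_class == "edge" &
    !is.na(junctions$cpr_id) & junctions$cpr_id == cpr$cpr_id
  if (all(edge)) "simple" else "complex"
}

# attach span classes/structure to a CPR set given its junction table
attach_structure <- function(cprs, junctions, edge_window = 500L,
                             max_simple_junctions = 2L) {
  if (length(cprs) == 0) return(cprs)
  cls <- vapply(seq_along(cprs), function(i) {
    jx <- junctions[junction_touches_cpr(junctions, cprs[i]), , drop = FALSE]
    classify_cpr_structure(cprs[i], jx, edge_window, max_simple_junctions)
  }, character(1))
  cprs$structure_class <- cls
  cprs
}

# rows of `junctions` with at least one breakend inside the CPR
junction_touches_cpr <- function(junctions, cpr) {
  if (nrow(junctions) == 0) return(logical(0))
  ctg <- as.character(seqnames(cpr))
  s <- start(cpr); e <- end(cpr)
  (junctions$chrom1 == ctg & junctions$pos1 >= s & junctions$pos1 <= e) |
    (junctions$chrom2 == ctg & junctions$pos2 >= s & junctions$pos2 <= e)
}

#' Fractions of junctions by span class
#'
#' Splits junctions into local (edge-joining + internal), distal
#' intra-chromosomal, and inter-chromosomal fractions; the three sum
#' to 1.
#'
#' @param junctions junction data.frame from [cluster_junctions()].
#' @return named numeric vector (local, distal_intra, inter).
#' @export
junction_span_fractions <- function(junctions) {
  if (nrow(junctions) == 0) stop("no junctions")
  n <- nrow(junctions)
  c(local = sum(junctions$span_class %in% c("edge", "internal")) / n,
    distal_intra = sum(junctions$span_class == "distal_intra") / n,
    inter = sum(junctions$span_class == "inter") / n)
}
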