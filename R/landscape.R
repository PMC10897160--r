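## Downstream eccDNA landscape statistics.

#' Coverage autocorrelation over genomic distance
#'
#' Pearson correlation between the binned circle-read signal f(x) and
#' its shifted copy f(x + d), computed per contig and combined by
#' weighting with the number of overlapping bin pairs; r(0) = 1. A
#' shuffled baseline repeats the computation after random uniform
#' repositioning of the reads on their contig (seeded), destroying any
#' spatial structure while keeping the read count.
#'
#' @param reads GRanges of circle reads (deduplicated primaries).
#' @param seqinfo Seqinfo; contigs to analyze taken from `contigs`.
#' @param bin_size bin width, bp.
#' @param max_lag maximum genomic distance, bp.
#' @param n_shuffles number of shuffled baselines (default 1).
#' @param seed integer seed for the shuffles.
#' @param contigs contigs to use (default: all with reads).
#' @return data.frame with columns distance, r, and (when shuffled)
#'   r_shuffle (mean over shuffles).
#' @export
coverage_autocorrelation <- function(reads, seqinfo, bin_size = 1000L,
                                     max_lag = 100000L, n_shuffles = 1L,
                                     seed = 1L,
                                     contigs = NULL) {
  if (is.null(contigs)) {
    contigs <- intersect(names(seqlengths(seqinfo)),
                         unique(as.character(seqnames(reads))))
  }
  cov <- coverage_from_granges(reads, seqinfo, bin_size)
  r_obs <- autocorr_track(cov, max_lag, contigs)
  out <- data.frame(distance = r_obs$distance, r = r_obs$r)
  if (n_shuffles > 0) {
    set.seed(seed)
    sh <- replicate(n_shuffles, {
      shuf <- shuffle_reads(reads, seqinfo, contigs)
      autocorr_track(coverage_from_granges(shuf, seqinfo, bin_size),
                     max_lag, contigs)$r
    })
    out$r_shuffle <- rowMeans(matrix(sh, nrow = nrow(out)))
  }
  out
}

# weighted-combination autocorrelation of a binned track
autocorr_track <- function(cov, max_lag, contigs = names(cov$counts)) {
  max_lag_bins <- max_lag %/% cov$bin_size
  lens <- vapply(cov$counts[contigs], length, integer(1))
  if (all(lens < 2 * max_lag_bins)) {
    stop("contigs too short for the requested maximum lag")
  }
  vtot <- unlist(cov$counts[contigs], use.names = FALSE)
  if (sd(vtot) == 0) stop("zero-variance coverage signal")
  r <- vapply(0:max_lag_bins, function(lag) {
    num <- 0; wsum <- 0
    for (ctg in contigs) {
      v <- cov$counts[[ctg]]
      n <- length(v) - lag
      if (n < 3) next
      x <- v[seq_len(n)]; y <- v[seq_len(n) + lag]
      if (sd(x) == 0 || sd(y) == 0) next
      num <- num + cor(x, y) * n
      wsum <- wsum + n
    }
    if (wsum == 0) NA_real_ else num / wsum
  }, numeric(1))
  data.frame(distance = (0:max_lag_bins) * cov$bin_size, r = r)
}

# uniform repositioning of reads on their own contig
shuffle_reads <- function(reads, seqinfo, contigs) {
  reads <- reads[as.character(seqnames(reads)) %in% contigs]
  sl <- seqlengths(seqinfo)
  w <- width(reads)
  maxs <- sl[as.character(seqnames(reads))] - w + 1L
  new_start <- as.integer(floor(runif(length(reads)) * maxs)) + 1L
  GRanges(seqnames(reads), IRanges(new_start, width = w),
          seqinfo = seqinfo)
}

#' GC content of CPRs versus matched background
#'
#' Per-CPR GC fractions compared with length- and contig-matched random
#' intervals that avoid the CPRs, using a two-sided rank-sum test.
#'
#' @param cprs GRanges.
#' @param genome DNAStringSet (or FASTA path).
#' @param n_draws background intervals per CPR (default 1).
#' @param seed integer seed for the background placement.
#' @return list with `gc_in`, `gc_out` (vectors), `statistic`, `p`.
#' @export
gc_content_compare <- function(cprs, genome, n_draws = 1L, seed = 1L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  sl <- setNames(width(genome), names(genome))
  bad <- end(cprs) > sl[as.character(seqnames(cprs))]
  if (any(bad)) stop("CPRs exceed contig bounds")
  gc_of <- function(gr) {
    vapply(seq_along(gr), function(i) {
      s <- Biostrings::subseq(genome[[as.character(seqnames(gr)[i])]],
                              start(gr)[i], end(gr)[i])
      sum(Biostrings::letterFrequency(s, c("G", "C"))) / width(gr)[i]
    }, numeric(1))
  }
  gc_in <- gc_of(cprs)
  set.seed(seed)
  bg <- lapply(rep(seq_along(cprs), n_draws), function(i) {
    ctg <- as.character(seqnames(cprs)[i])
    w <- width(cprs)[i]
    for (try in 1:100) {
      s <- sample.int(sl[[ctg]] - w + 1L, 1)
      cand <- GRanges(ctg, IRanges(s, width = w))
      if (!any(overlapsAny(cand, cprs))) return(cand)
    }
    cand
  })
  bg <- do.call(c, bg)
  gc_out <- gc_of(bg)
  ht <- suppressWarnings(wilcox.test(gc_in, gc_out))
  list(gc_in = gc_in, gc_out = gc_out,
       statistic = unname(ht$statistic), p = ht$p.value)
}

#' Meta-gene profile of circle reads
#'
#' Scaled-region profile: each gene body is rescaled to `body_bins`
#' positions with fixed-width flanks on both sides; reads are assigned
#' by midpoint and minus-strand genes are reversed so transcription
#' always runs left to right.
#'
#' @param reads GRanges of circle reads.
#' @param genes stranded GRanges of gene bodies.
#' @param body_bins bins across the gene body (default 50).
#' @param flank_bp flank width in bp (default 2000).
#' @param flank_bins bins per flank (default 20).
#' @return list with `matrix` (genes x positions) and `profile`
#'   (column means). Genes shorter than `body_bins` bp are skipped with
#'   a message.
#' @export
metagene_profile <- function(reads, genes, body_bins = 50L,
                             flank_bp = 2000L, flank_bins = 20L) {
  ok <- width(genes) >= body_bins
  if (!all(ok)) {
    message("skipping ", sum(!ok), " gene(s) shorter than ", body_bins,
            " bp")
    genes <- genes[ok]
  }
  ncol_total <- 2L * flank_bins + body_bins
  mat <- matrix(0, nrow = length(genes), ncol = ncol_total)
  mid <- midpoints(reads)
  win <- suppressWarnings(trim(genes + flank_bp))
  hits <- findOverlaps(mid, win, ignore.strand = TRUE)
  flank_binw <- flank_bp / flank_bins
  for (h in seq_along(hits)) {
    i <- subjectHits(hits)[h]
    p <- start(mid)[queryHits(hits)[h]]
    gs <- start(genes)[i]; ge <- end(genes)[i]
    minus <- as.character(strand(genes)[i]) == "-"
    if (p < gs) {
      d <- gs - p  # upstream distance on + genes
      col <- if (!minus) flank_bins - ceiling(d / flank_binw) + 1L
             else flank_bins + body_bins + ceiling(d / flank_binw)
    } else if (p > ge) {
      d <- p - ge
      col <- if (!minus) flank_bins + body_bins + ceiling(d / flank_binw)
             else flank_bins - ceiling(d / flank_binw) + 1L
    } else {
      frac <- (p - gs) / (ge - gs + 1)
      b <- pmin(body_bins, floor(frac * body_bins) + 1L)
      col <- if (!minus) flank_bins + b
             else flank_bins + body_bins - b + 1L
    }
    if (col >= 1 && col <= ncol_total) mat[i, col] <- mat[i, col] + 1
  }
  list(matrix = mat, profile = colMeans(mat),
       columns = c(rep("upstream", flank_bins), rep("body", body_bins),
                   rep("downstream", flank_bins)))
}

#' CPR overlap with an annotation track
#'
#' Flags CPRs overlapping the features (>= 1 bp), computes the feature
#' fraction (circle reads inside feature-overlapping CPRs over all
#' circle reads in CPRs) and rank-sum-tests the frequency of
#' overlapping versus non-overlapping CPRs.
#'
#' @param cprs GRanges with `n_circle_reads` metadata; when a frequency
#'   column `f` (or `f_norm`) is present it is used for the group test.
#' @param features GRanges annotation track (e.g. enhancers).
#' @param cprs_by_cell optional list of per-cell CPR GRanges for
#'   per-cell overlap counts.
#' @return list with `overlaps` (logical per CPR), `feature_fraction`,
#'   `p` (NA when no frequency column), `per_cell_counts`.
#' @export
feature_overlap_stats <- function(cprs, features, cprs_by_cell = NULL) {
  if (length(features) == 0) stop("empty feature set")
  ov <- overlapsAny(cprs, features, ignore.strand = TRUE)
  reads <- cprs$n_circle_reads %||% rep(1L, length(cprs))
  frac <- if (sum(reads) == 0) 0 else sum(reads[ov]) / sum(reads)
  fcol <- if (!is.null(cprs$f_norm)) cprs$f_norm else cprs$f
  p <- NA_real_
  if (!is.null(fcol) && any(ov) && any(!ov)) {
    p <- suppressWarnings(wilcox.test(fcol[ov], fcol[!ov])$p.value)
  }
  per_cell <- NULL
  if (!is.null(cprs_by_cell)) {
    per_cell <- vapply(cprs_by_cell, function(g) {
      sum(overlapsAny(g, features, ignore.strand = TRUE))
    }, integer(1))
  }
  list(overlaps = ov, feature_fraction = frac, p = p,
       per_cell_counts = per_cell)
}

#' Co-occurrence of CPRs with an anchor region
#'
#' Pearson correlation, across cells, between each CPR's per-cell
#' presence (or abundance) vector and the anchor region's vector; the
#' anchor vector is the maximum over the CPR columns overlapping the
#' anchor interval. Zero-variance columns are excluded.
#'
#' @param mat cells x CPRs matrix (binary presence by default).
#' @param catalog GRanges of the CPR columns (same order).
#' @param anchor GRanges of length 1.
#' @param pcc_threshold selection threshold (default 0.5).
#' @return data.frame (cpr index, pcc, selected) for columns with
#'   defined correlation.
#' @export
cooccurrence <- function(mat, catalog, anchor, pcc_threshold = 0.5) {
  stopifnot(nrow(mat) >= 3, length(catalog) == ncol(mat))
  anchor_cols <- which(overlapsAny(catalog, anchor, ignore.strand = TRUE))
  if (length(anchor_cols) == 0) stop("anchor absent from the CPR catalog")
  avec <- if (length(anchor_cols) == 1) mat[, anchor_cols]
          else apply(mat[, anchor_cols, drop = FALSE], 1, max)
  if (sd(avec) == 0) stop("anchor vector has zero variance")
  pcc <- suppressWarnings(as.numeric(cor(mat, avec)))
  ok <- !is.na(pcc)
  data.frame(cpr = which(ok), pcc = pcc[ok],
             selected = pcc[ok] > pcc_threshold)
}

#' Correlation of eccDNA reads with gene expression
#'
#' Per-gene Pearson correlation across cells between log-transformed
#' normalized expression and log-transformed normalized eccDNA read
#' counts; genes with undefined correlation (zero variance) are
#' excluded.
#'
#' @param ecc cells x genes matrix of normalized eccDNA read counts.
#' @param expression cells x genes matrix of expression (e.g. TPM);
#'   shared cells are matched by row name.
#' @param pcc_threshold flagging threshold (default 0.6).
#' @return data.frame (gene, pcc, flagged).
#' @export
expression_correlation <- function(ecc, expression, pcc_threshold = 0.6) {
  shared <- intersect(rownames(ecc), rownames(expression))
  if (length(shared) < 3) stop("fewer than 3 shared cells")
  genes <- intersect(colnames(ecc), colnames(expression))
  e1 <- log1p(ecc[shared, genes, drop = FALSE])
  e2 <- log1p(expression[shared, genes, drop = FALSE])
  pcc <- vapply(genes, function(g) {
    suppressWarnings(cor(e1[, g], e2[, g]))
  }, numeric(1))
  ok <- !is.na(pcc)
  data.frame(gene = genes[ok], pcc = unname(pcc[ok]),
             flagged = unname(pcc[ok]) > pcc_threshold,
             stringsAsFactors = FALSE)
}

#' eccDNA density stratified by copy-number class
#'
#' For each cell and copy-number class: the number of CPR midpoints
#' falling into segments of that class, divided by the class territory
#' in units of 100 kb; classes are compared pairwise with two-sided
#' Welch t-tests.
#'
#' @param cprs_by_cell list of per-cell CPR GRanges.
#' @param cn_segments GRanges with an integer `cn` metadata column.
#' @return list with `density` (cells x classes matrix, per 100 kb),
#'   `territory_kb` and `tests` (data.frame class_a, class_b, p).
#' @export
cn_density <- function(cprs_by_cell, cn_segments) {
  stopifnot(!is.null(cn_segments$cn))
  classes <- sort(unique(cn_segments$cn))
  terr <- vapply(classes, function(k) {
    sum(width(reduce(cn_segments[cn_segments$cn == k])))
  }, numeric(1))
  keep <- terr > 0
  if (!all(keep)) {
    message("excluding ", sum(!keep), " zero-territory class(es)")
    classes <- classes[keep]; terr <- terr[keep]
  }
  dens <- vapply(cprs_by_cell, function(g) {
    mid <- midpoints(g)
    vapply(seq_along(classes), function(j) {
      segs <- cn_segments[cn_segments$cn == classes[j]]
      sum(overlapsAny(mid, segs, ignore.strand = TRUE)) /
        (terr[j] / 1e5)
    }, numeric(1))
  }, numeric(length(classes)))
  if (is.null(dim(dens))) {
    dens <- matrix(dens, nrow = 1, dimnames = list(NULL, names(dens)))
  }
  dens <- t(dens)
  colnames(dens) <- paste0("CN", classes)
  tests <- if (length(classes) < 2) {
    data.frame(class_a = integer(), class_b = integer(), p = numeric())
  } else {
    pairs <- utils::combn(seq_along(classes), 2)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(q) {
      i <- pairs[1, q]; j <- pairs[2, q]
      p <- tryCatch(t.test(dens[, i], dens[, j])$p.value,
                    error = function(e) NA_real_)
      data.frame(class_a = classes[i], class_b = classes[j], p = p)
    }))
  }
  list(density = dens, territory_kb = setNames(terr / 1000, colnames(dens)),
       tests = tests)
}

#' Euclidean distances between cells on a CPR class
#'
#' Pairwise Euclidean distances between per-cell normalized abundance
#' vectors restricted to the CPRs of one quadrant label (e.g. the HFHU
#' or LFLU set), typically applied to daughter-cell pairs.
#'
#' @param vectors cells x CPRs matrix of normalized abundances.
#' @param labels quadrant label per CPR column.
#' @param class label to restrict to (e.g. "HFHU").
#' @param pairs optional 2-column matrix/data.frame of cell-name pairs;
#'   when given, a per-pair distance vector is returned alongside.
#' @return list with `dist` (full symmetric matrix) and `pair_dist`.
#' @export
daughter_distance <- function(vectors, labels, class, pairs = NULL) {
  stopifnot(length(labels) == ncol(vectors))
  sub <- vectors[, labels == class, drop = FALSE]
  dm <- as.matrix(dist(sub))
  pd <- NULL
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    if (!all(pairs %in% rownames(dm))) stop("catalog mismatch: unknown cells")
    pd <- vapply(seq_len(nrow(pairs)), function(i) {
      dm[pairs[i, 1], pairs[i, 2]]
    }, numeric(1))
  }
  list(dist = dm, pair_dist = pd)
}
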