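## Population-level CPR classification.
##
## Every CPR called in the pooled (pseudo-bulk) sample is scored by how
## many cells carry an overlapping circle (frequency of occurrence) and
## how reproducibly its borders recur across cells (mean Jaccard
## uniformity). Both are normalized to the mitochondrial genome - a
## bona fide circle present in every cell - capped at 1, and combined
## into a uniformity score U = f_norm * J_norm. Thresholds f > 0.65 and
## U > 0.3 (strict) split CPRs into the HFHU/HFLU/LFHU/LFLU quadrants.

#' Build pseudo-bulk CPRs from pooled cells
#'
#' Pools the per-cell alignments (read ids are prefixed by cell to keep
#' pairs intact) and re-runs CPR calling with the same parameters used
#' per cell.
#'
#' @param aln_list named list of per-cell (deduplicated) alignment
#'   data.frames.
#' @param seqinfo Seqinfo of the active genome.
#' @param params [cpr_params()] list.
#' @return pseudo-bulk CPR GRanges.
#' @export
build_pseudobulk <- function(aln_list, seqinfo, params = cpr_params()) {
  if (length(aln_list) == 0) stop("empty cell pool")
  nm <- names(aln_list) %||% as.character(seq_along(aln_list))
  pooled <- do.call(rbind, lapply(seq_along(aln_list), function(i) {
    a <- aln_list[[i]]
    a$read_id <- paste0(nm[i], ":", a$read_id)
    a
  }))
  pooled <- pooled[order(pooled$chrom, pooled$pos), , drop = FALSE]
  detect_cprs(pooled, seqinfo, params)
}

#' Frequency of occurrence of a pseudo-bulk CPR
#'
#' f_raw = N_pos / N_tot, where N_pos counts cells in which at least one
#' CPR overlaps at least `min_overlap` of the pseudo-bulk CPR's length.
#'
#' @param pseudo_cpr length-1 GRanges.
#' @param cell_cprs list of per-cell CPR GRanges.
#' @param min_overlap minimum overlap as a fraction of the pseudo-bulk
#'   CPR length (default 0.1).
#' @return f_raw in \[0, 1\].
#' @export
cpr_frequency <- function(pseudo_cpr, cell_cprs, min_overlap = 0.1) {
  stopifnot(length(pseudo_cpr) == 1, length(cell_cprs) >= 1)
  pc <- as.character(seqnames(pseudo_cpr))
  ps <- start(pseudo_cpr); pe <- end(pseudo_cpr)
  need <- min_overlap * (pe - ps + 1)
  n_pos <- sum(vapply(cell_cprs, function(cprs) {
    if (length(cprs) == 0) return(FALSE)
    k <- as.character(seqnames(cprs)) == pc
    if (!any(k)) return(FALSE)
    ov <- pmin(end(cprs)[k], pe) - pmax(start(cprs)[k], ps) + 1L
    any(ov >= 1L & ov >= need)
  }, logical(1)))
  n_pos / length(cell_cprs)
}

#' Mean Jaccard uniformity of a pseudo-bulk CPR
#'
#' For each cell, the Jaccard index between the pseudo-bulk CPR and the
#' union of that cell's CPRs overlapping it (0 when none overlaps);
#' J_raw is the mean over all cells.
#'
#' @inheritParams cpr_frequency
#' @return J_raw in \[0, 1\].
#' @export
cpr_uniformity <- function(pseudo_cpr, cell_cprs) {
  stopifnot(length(pseudo_cpr) == 1, length(cell_cprs) >= 1)
  pc <- as.character(seqnames(pseudo_cpr))
  ps <- start(pseudo_cpr); pe <- end(pseudo_cpr)
  j <- vapply(cell_cprs, function(cprs) {
    if (length(cprs) == 0) return(0)
    k <- as.character(seqnames(cprs)) == pc &
      end(cprs) >= ps & start(cprs) <= pe
    if (!any(k)) return(0)
    a <- IRanges::reduce(IRanges(start(cprs)[k], end(cprs)[k]))
    inter <- sum(pmin(end(a), pe) - pmax(start(a), ps) + 1L)
    u <- sum(width(IRanges::reduce(c(a, IRanges(ps, pe)))))
    inter / u
  }, numeric(1))
  mean(j)
}

#' Normalize frequency and uniformity to the mitochondrial reference
#'
#' Divides by the mitochondrial frequency/Jaccard and caps values larger
#' than 1 at 1.
#'
#' @param f_raw,j_raw raw values.
#' @param f_mt,j_mt mitochondrial references; must be positive.
#' @return list with `f_norm` and `j_norm`.
#' @export
normalize_to_mito <- function(f_raw, j_raw, f_mt, j_mt) {
  if (f_mt <= 0 || j_mt <= 0) {
    stop("mitochondrial reference missing (f_mt or J_mt is zero)")
  }
  list(f_norm = pmin(1, f_raw / f_mt), j_norm = pmin(1, j_raw / j_mt))
}

#' Uniformity score
#'
#' U = f_norm * J_norm.
#'
#' @param f_norm,j_norm normalized frequency and Jaccard, in \[0, 1\].
#' @return U in \[0, 1\].
#' @export
uniformity_score <- function(f_norm, j_norm) f_norm * j_norm

#' Quadrant label of one CPR
#'
#' High frequency iff f > `f_threshold`, high uniformity iff
#' U > `u_threshold` (both strict).
#'
#' @param f_norm frequency used for the rule.
#' @param u uniformity score.
#' @param f_threshold,u_threshold thresholds (defaults 0.65 and 0.3).
#' @return one of "HFHU", "HFLU", "LFHU", "LFLU".
#' @export
classify_cpr <- function(f_norm, u, f_threshold = 0.65, u_threshold = 0.3) {
  hf <- f_norm > f_threshold
  hu <- u > u_threshold
  paste0(ifelse(hf, "HF", "LF"), ifelse(hu, "HU", "LU"))
}

#' Classify all pseudo-bulk CPRs of a population
#'
#' Computes, for every pseudo-bulk CPR, the raw frequency and mean
#' Jaccard across cells, the mitochondria-normalized values, the
#' uniformity score and the quadrant label. The mitochondrial reference
#' treats the whole mitochondrial contig as a pseudo-bulk CPR and each
#' cell's detected mitochondrial regions as that cell's circles.
#'
#' @param pseudo_cprs pseudo-bulk CPR GRanges (from [build_pseudobulk()]).
#' @param cell_cprs list of per-cell CPR GRanges (nuclear contigs).
#' @param cell_mito list of per-cell GRanges of detected regions on the
#'   mitochondrial contig.
#' @param mito_contig mitochondrial contig name.
#' @param seqinfo Seqinfo (provides the mitochondrial contig length).
#' @param min_overlap cell-positivity overlap fraction (default 0.1).
#' @param f_threshold,u_threshold quadrant thresholds.
#' @param use_normalized use f_norm (default) rather than f_raw in the
#'   quadrant rule.
#' @return data.frame with one row per pseudo-bulk CPR: cpr_id, chrom,
#'   start, end, n_pos, n_tot, f_raw, j_raw, f_mt, j_mt, f_norm, j_norm,
#'   u, label.
#' @export
classify_population <- function(pseudo_cprs, cell_cprs, cell_mito,
                                mito_contig, seqinfo, min_overlap = 0.1,
                                f_threshold = 0.65, u_threshold = 0.3,
                                use_normalized = TRUE) {
  n_tot <- length(cell_cprs)
  stopifnot(n_tot >= 1, length(cell_mito) == n_tot)
  mito_len <- seqlengths(seqinfo)[[mito_contig]]
  mito_pseudo <- GRanges(mito_contig, IRanges(1L, mito_len))
  f_mt <- cpr_frequency(mito_pseudo, cell_mito, min_overlap)
  j_mt <- cpr_uniformity(mito_pseudo, cell_mito)
  if (f_mt <= 0 || j_mt <= 0) {
    stop("mitochondrial reference missing (no mitochondrial signal ",
         "detected in the population)")
  }
  rows <- lapply(seq_along(pseudo_cprs), function(j) {
    pc <- pseudo_cprs[j]
    f_raw <- cpr_frequency(pc, cell_cprs, min_overlap)
    j_raw <- cpr_uniformity(pc, cell_cprs)
    norm <- normalize_to_mito(f_raw, j_raw, f_mt, j_mt)
    u <- uniformity_score(norm$f_norm, norm$j_norm)
    f_rule <- if (use_normalized) norm$f_norm else f_raw
    data.frame(
      cpr_id = pc$cpr_id, chrom = as.character(seqnames(pc)),
      start = start(pc), end = end(pc),
      n_pos = as.integer(round(f_raw * n_tot)), n_tot = n_tot,
      f_raw = f_raw, j_raw = j_raw, f_mt = f_mt, j_mt = j_mt,
      f_norm = norm$f_norm, j_norm = norm$j_norm, u = u,
      label = classify_cpr(f_rule, u, f_threshold, u_threshold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cpr_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_pos = integer(), n_tot = integer(),
                      f_raw = numeric(), j_raw = numeric(),
                      f_mt = numeric(), j_mt = numeric(),
                      f_norm = numeric(), j_norm = numeric(),
                      u = numeric(), label = character())
  }
  rownames(out) <- NULL
  out
}

#' Write classification records
#'
#' TSV with all per-CPR quantities, and optionally a BED file whose
#' item colors encode the quadrant label.
#'
#' @param records data.frame from [classify_population()].
#' @param tsv_path,bed_path output paths (NULL to skip).
#' @export
write_classification <- function(records, tsv_path, bed_path = NULL) {
  write.table(records, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bed_path)) {
    cols <- c(HFHU = "228,26,28", HFLU = "55,126,184",
              LFHU = "77,175,74", LFLU = "150,150,150")
    df <- data.frame(records$chrom, records$start - 1L, records$end,
                     paste0(records$cpr_id, "|", records$label),
                     0L, ".", records$start - 1L, records$end,
                     cols[records$label])
    write.table(df, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}
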